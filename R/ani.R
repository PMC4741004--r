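#' Fragment a genome into fixed-length windows
#'
#' The classic fragment-ANI convention: consecutive windows of `frag_len`
#' (default step = `frag_len`, i.e. non-overlapping tiling); a terminal
#' remainder shorter than `frag_len` is discarded, so with the default step
#' the fragment count is `floor(L / frag_len)`.
#'
#' @param genome A genome record (list with `id`, `sequence`) from
#'   [read_fasta()].
#' @param frag_len Fragment length in bp (>= 100; default 1020).
#' @param step Step between fragment starts (default `frag_len`).
#' @return A data.frame with `start`, `end` (0-based half-open) and `seq`.
#'   Empty (with a warning) if the genome is shorter than `frag_len`.
#' @export
fragment_genome <- function(genome, frag_len = 1020L, step = frag_len) {
  stopifnot(frag_len >= 100L, step >= 1L)
  L <- nchar(genome$sequence)
  if (L < frag_len) {
    warning("genome ", genome$id, " shorter than frag_len; no fragments")
    return(data.frame(start = integer(0), end = integer(0),
                      seq = character(0)))
  }
  starts <- seq(0L, L - frag_len, by = step)
  data.frame(
    start = starts, end = starts + frag_len,
    seq = substring(genome$sequence, starts + 1L, starts + frag_len),
    stringsAsFactors = FALSE)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# One-time exact k-mer index of a reference strand: hashed environment
# mapping each k-mer to its (1-based) start positions.
.kmer_index <- function(seq, k = 10L) {
  L <- nchar(seq)
  if (L < k) return(list(index = new.env(parent = emptyenv()), k = k, L = L))
  kmers <- substring(seq, 1:(L - k + 1L), k:L)
  index <- list2env(split(seq_len(L - k + 1L), kmers),
                    hash = TRUE, parent = emptyenv())
  list(index = index, k = k, L = L)
}

# Reference bundle for fragment mapping: forward/reverse sequences plus
# their k-mer indexes (built once per genome pair).
.ref_bundle <- function(ref_seq, k = 10L) {
  rev_seq <- .revcomp(ref_seq)
  list(fwd = ref_seq, rev = rev_seq,
       idx_fwd = .kmer_index(ref_seq, k), idx_rev = .kmer_index(rev_seq, k))
}

# Candidate placements of a fragment on the reference: seed k-mers sampled
# along the fragment vote for an implied fragment start (diagonal, binned
# within 30 bp so small jitter still pools votes).
.seed_candidates <- function(frag, ref, n_seeds = 24L) {
  k <- ref$idx_fwd$k
  L <- nchar(frag)
  if (L < k) return(NULL)
  offs <- unique(pmin(as.integer(seq(1L, L - k + 1L, length.out = n_seeds)),
                      L - k + 1L))
  kmers <- substring(frag, offs, offs + k - 1L)
  strands <- starts <- NULL
  for (s in c("+", "-")) {
    idx <- if (s == "+") ref$idx_fwd$index else ref$idx_rev$index
    for (i in seq_along(offs)) {
      hits <- idx[[kmers[i]]]
      if (!is.null(hits)) {
        starts <- c(starts, hits - offs[i])
        strands <- c(strands, rep(s, length(hits)))
      }
    }
  }
  if (is.null(starts)) return(NULL)
  bin <- paste(strands, round(starts / 30))
  counts <- table(bin)
  reps <- vapply(names(counts), function(b) {
    as.integer(round(stats::median(starts[bin == b])))
  }, integer(1))
  cand <- data.frame(
    strand = substr(names(counts), 1L, 1L),
    start = reps, count = as.integer(counts), stringsAsFactors = FALSE)
  cand[order(-cand$count, cand$strand, cand$start), , drop = FALSE]
}

# Glocal-align one fragment against the implied reference window (with
# margin); returns the alignment_result or NULL when no seed maps.
.map_fragment <- function(frag, ref, margin = 120L,
                          max_candidates = 3L, min_votes = 2L) {
  cand <- .seed_candidates(frag, ref)
  if (is.null(cand)) return(NULL)
  # a single agreeing k-mer is too weak a signal: spurious singleton hits
  # would glocal-align the fragment to an unrelated window and bias the
  # identity mean; such fragments are left unmapped instead
  cand <- cand[cand$count >= min_votes, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand <- head(cand, max_candidates)
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    ref_seq <- if (cand$strand[i] == "+") ref$fwd else ref$rev
    lo <- max(1L, cand$start[i] - margin)
    hi <- min(nchar(ref_seq), cand$start[i] + nchar(frag) + margin)
    if (hi - lo + 1L < nchar(frag) / 2) next
    res <- align_dna(frag, substr(ref_seq, lo, hi), mode = "glocal")
    # ties broken by higher identity, then lower reference coordinate
    if (is.null(best) || res$score > best$score ||
        (res$score == best$score &&
         (res$identity_pct > best$identity_pct))) {
      res$strand <- cand$strand[i]
      res$ref_window_start <- lo
      best <- res
    }
  }
  best
}

#' Compute average nucleotide identity between two genomes
#'
#' Fragment-based ANI: the query is cut into `frag_len` windows
#' ([fragment_genome()]); each fragment is mapped to its best-matching region
#' of the reference (both strands, exact-seed prefilter then glocal affine-gap
#' DP); fragments aligning with identity >= `min_frag_identity_pct` over at
#' least `min_frag_alignable_pct` of their length are "used". ANI is the mean
#' identity of used fragments and the aligned fraction is the percentage of
#' QUERY bases in used fragments — hence directional (asymmetric between the
#' two genomes).
#'
#' @param query,ref Genome records.
#' @param frag_len Fragment length (default 1020 bp).
#' @param min_frag_identity_pct Per-fragment identity floor (default 30).
#' @param min_frag_alignable_pct Per-fragment alignable-length floor
#'   (default 70).
#' @return An `ani_result` list: `query_id`, `ref_id`, `ani_pct`,
#'   `aligned_fraction_pct`, `n_fragments_used`, `n_fragments_total`. When no
#'   fragment passes, `ani_pct` is `NA` (undefined) rather than an error.
#' @export
compute_ani <- function(query, ref, frag_len = 1020L,
                        min_frag_identity_pct = 30,
                        min_frag_alignable_pct = 70) {
  frags <- fragment_genome(query, frag_len)
  bundle <- .ref_bundle(ref$sequence)
  used_ids <- numeric(0)
  used_bases <- 0L
  for (i in seq_len(nrow(frags))) {
    res <- .map_fragment(frags$seq[i], bundle)
    if (is.null(res)) next
    alignable_pct <- 100 * res$aligned_columns / nchar(frags$seq[i])
    if (!is.na(res$identity_pct) &&
        res$identity_pct >= min_frag_identity_pct &&
        alignable_pct >= min_frag_alignable_pct) {
      used_ids <- c(used_ids, res$identity_pct)
      used_bases <- used_bases + (frags$end[i] - frags$start[i])
    }
  }
  structure(list(
    query_id = query$id, ref_id = ref$id,
    ani_pct = if (length(used_ids)) mean(used_ids) else NA_real_,
    aligned_fraction_pct = 100 * used_bases / nchar(query$sequence),
    n_fragments_used = length(used_ids),
    n_fragments_total = nrow(frags)), class = "ani_result")
}

#' All-vs-all ANI matrix with aligned-fraction companion
#'
#' Every ordered pair of genomes is computed (rows are queries, columns
#' references); the diagonal is `NA`/omitted. The matrix is generally
#' asymmetric: the aligned fraction is defined on the query genome, so two
#' genomes of different size show different fractions in the two directions.
#'
#' @param genomes List of genome records with unique ids.
#' @param ... Passed to [compute_ani()].
#' @return An `ani_matrix` list: `labels`, `ani` (matrix), `aligned` (matrix).
#' @export
ani_matrix <- function(genomes, ...) {
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  ids <- vapply(genomes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate genome ids: ",
                               ids[duplicated(ids)][1L])
  n <- length(genomes)
  ani <- aligned <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- compute_ani(genomes[[i]], genomes[[j]], ...)
    ani[i, j] <- r$ani_pct
    aligned[i, j] <- r$aligned_fraction_pct
  }
  structure(list(labels = ids, ani = ani, aligned = aligned),
            class = "ani_matrix")
}

#' Classify two genomes as same/different species from ANI
#'
#' The operational bacterial species boundary sits in a 95-96 % ANI band:
#' below the band is a different species, above it the same, and values
#' inside the band are flagged borderline.
#'
#' @param ani_pct ANI percentage (0-100).
#' @param lower,upper Band bounds (defaults 95 and 96).
#' @return List with `same_species` (logical, `NA` when borderline) and
#'   `borderline` (logical).
#' @export
classify_species <- function(ani_pct, lower = 95, upper = 96) {
  stopifnot(ani_pct >= 0, ani_pct <= 100, lower <= upper)
  if (ani_pct < lower) {
    list(same_species = FALSE, borderline = FALSE)
  } else if (ani_pct > upper) {
    list(same_species = TRUE, borderline = FALSE)
  } else {
    list(same_species = NA, borderline = TRUE)
  }
}

#' Find high-identity regions shared by two genomes
#'
#' Scans genome `a` in fragments, maps each to genome `b`, keeps fragments at
#' identity >= `min_identity_pct`, and reports maximal runs of consecutive
#' passing fragments merged across gaps of up to `merge_gap` fragments.
#' Regions shorter than `min_len` are dropped.
#'
#' @param a,b Genome records.
#' @param min_identity_pct Per-fragment identity floor (default 90).
#' @param min_len Minimum region length in bp (>= 500).
#' @param merge_gap Number of consecutive failing fragments bridged when
#'   merging (default 0).
#' @param frag_len Fragment length (default 1020).
#' @return A data.frame with `a_start`, `a_end`, `b_start`, `b_end`
#'   (0-based half-open on each genome), `identity_pct` (mean over fragments),
#'   `length` (on `a`), `strand`.
#' @export
find_high_identity_regions <- function(a, b, min_identity_pct = 90,
                                       min_len = 5000L, merge_gap = 0L,
                                       frag_len = 1020L) {
  stopifnot(min_len >= 500L)
  frags <- fragment_genome(a, frag_len)
  bundle <- .ref_bundle(b$sequence)
  n <- nrow(frags)
  pass <- logical(n); ident <- rep(NA_real_, n)
  bstart <- bend <- rep(NA_integer_, n); strand <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- .map_fragment(frags$seq[i], bundle)
    if (is.null(res) || is.na(res$identity_pct)) next
    alignable_pct <- 100 * res$aligned_columns / nchar(frags$seq[i])
    if (res$identity_pct >= min_identity_pct && alignable_pct >= 70) {
      pass[i] <- TRUE
      ident[i] <- res$identity_pct
      s0 <- res$ref_window_start + res$subject_start - 2L  # 0-based
      e0 <- res$ref_window_start + res$subject_end - 1L
      if (res$strand == "-") {
        L <- nchar(b$sequence)
        tmp <- s0; s0 <- L - e0; e0 <- L - tmp
      }
      bstart[i] <- s0; bend[i] <- e0; strand[i] <- res$strand
    }
  }
  # merge runs of passing fragments bridged across <= merge_gap failures:
  # passing fragments whose index gap exceeds merge_gap + 1 start a new region
  regions <- list()
  idx <- which(pass)
  if (length(idx)) {
    grp <- cumsum(c(1L, diff(idx) > merge_gap + 1L))
    for (g in split(idx, grp)) {
      first <- g[1L]; last <- g[length(g)]
      reg_len <- frags$end[last] - frags$start[first]
      if (reg_len < min_len) next
      regions[[length(regions) + 1L]] <- data.frame(
        a_start = frags$start[first], a_end = frags$end[last],
        b_start = min(bstart[g]), b_end = max(bend[g]),
        identity_pct = mean(ident[g]), length = reg_len,
        strand = strand[g][1L])
    }
  }
  if (!length(regions)) {
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      identity_pct = numeric(0), length = integer(0),
                      strand = character(0)))
  }
  do.call(rbind, regions)
}
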