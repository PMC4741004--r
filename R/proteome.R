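#' All-vs-all protein comparison at identity/coverage thresholds
#'
#' Aligns every protein of `proteomeA` against every protein of `proteomeB`
#' (global affine-gap DP, BLOSUM62 by default) and keeps hits passing the
#' thresholds used throughout the pan/core analysis: identity over aligned
#' columns and coverage computed on the LONGER of the two proteins
#' (a symmetric-coverage mode, requiring the floor on both proteins, exists
#' but is off by default). Defaults are 30 % identity and 70 % coverage.
#'
#' @param proteomeA,proteomeB Lists of protein records (id, sequence); each
#'   record may carry a `genome_id`.
#' @param id_threshold_pct Identity floor, percent (default 30).
#' @param cov_threshold_pct Coverage floor on the longer protein (default 70).
#' @param matrix,gap_open,gap_extend Alignment parameters, see
#'   [align_protein()].
#' @param symmetric_coverage Require the coverage floor on both proteins.
#' @return data.frame of passing hits: `query_id`, `subject_id`,
#'   `identity_pct`, `coverage_longer_pct`, `score`.
#' @export
filtered_hits <- function(proteomeA, proteomeB,
                          id_threshold_pct = 30, cov_threshold_pct = 70,
                          matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          symmetric_coverage = FALSE) {
  if (!length(proteomeA) || !length(proteomeB)) stop("empty proteome")
  q_seqs <- vapply(proteomeA, `[[`, character(1), "sequence")
  q_ids <- vapply(proteomeA, `[[`, character(1), "id")
  rows <- list()
  for (sb in proteomeB) {
    res <- .align_protein_batch(q_seqs, sb$sequence, matrix = matrix,
                                gap_open = gap_open, gap_extend = gap_extend)
    for (i in seq_along(res)) {
      r <- res[[i]]
      len_q <- nchar(q_seqs[i]); len_s <- nchar(sb$sequence)
      cov_q <- r$query_coverage_pct; cov_s <- r$subject_coverage_pct
      cov_longer <- if (len_q >= len_s) cov_q else cov_s
      pass_cov <- if (symmetric_coverage) {
        min(cov_q, cov_s) >= cov_threshold_pct
      } else cov_longer >= cov_threshold_pct
      if (!is.na(r$identity_pct) && r$identity_pct >= id_threshold_pct &&
          pass_cov) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = q_ids[i], subject_id = sb$id,
          identity_pct = r$identity_pct,
          coverage_longer_pct = cov_longer, score = r$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity_pct = numeric(0),
                      coverage_longer_pct = numeric(0), score = numeric(0)))
  }
  do.call(rbind, rows)
}

# Best subject per query by score; ties by higher identity then lexicographic
# subject id.
.best_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$query_id, -hits$score, -hits$identity_pct,
               hits$subject_id)
  h <- hits[ord, ]
  h[!duplicated(h$query_id), ]
}

#' Reciprocal best hits between two hit tables
#'
#' A pair (a, b) is reciprocal-best when b is a's best-scoring subject in the
#' A-vs-B table and a is b's best-scoring subject in the B-vs-A table. "Best"
#' is by alignment score; ties are broken by higher identity, then
#' lexicographic subject id. Each protein appears in at most one pair.
#'
#' @param hitsAB,hitsBA Directional hit tables from [filtered_hits()] for the
#'   same proteome pair.
#' @return data.frame with `protein_a`, `protein_b`, `identity_pct`.
#' @export
reciprocal_best_hits <- function(hitsAB, hitsBA) {
  ab <- .best_hits(hitsAB)
  ba <- .best_hits(hitsBA)
  if (!nrow(ab) || !nrow(ba)) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      identity_pct = numeric(0)))
  }
  back <- setNames(ba$subject_id, ba$query_id)
  keep <- !is.na(back[ab$subject_id]) & back[ab$subject_id] == ab$query_id
  out <- data.frame(protein_a = ab$query_id[keep],
                    protein_b = ab$subject_id[keep],
                    identity_pct = ab$identity_pct[keep],
                    stringsAsFactors = FALSE)
  out[order(out$protein_a), , drop = FALSE]
}

#' Average amino-acid identity between two proteomes
#'
#' AAI = mean identity over reciprocal-best-hit protein pairs at the
#' pan/core thresholds (30 % identity, 70 % coverage of the longer protein).
#'
#' @param proteomeA,proteomeB Lists of protein records.
#' @param ... Passed to [filtered_hits()].
#' @return An `aai_result`: `genome_a`, `genome_b`, `aai_pct` (`NA` when no
#'   RBH pair exists), `n_rbh`.
#' @export
compute_aai <- function(proteomeA, proteomeB, ...) {
  hits_ab <- filtered_hits(proteomeA, proteomeB, ...)
  hits_ba <- filtered_hits(proteomeB, proteomeA, ...)
  rbh <- reciprocal_best_hits(hits_ab, hits_ba)
  ga <- proteomeA[[1L]]$genome_id %||% NA_character_
  gb <- proteomeB[[1L]]$genome_id %||% NA_character_
  structure(list(genome_a = ga, genome_b = gb,
                 aai_pct = if (nrow(rbh)) mean(rbh$identity_pct) else NA_real_,
                 n_rbh = nrow(rbh), rbh = rbh), class = "aai_result")
}

#' AAI matrix and distance matrix over a set of proteomes
#'
#' AAI is computed for every unordered pair using the mean of both alignment
#' directions; distances are `100 - AAI` with a zero diagonal, suitable for
#' dendrogram construction ([aai_dendrogram()]).
#'
#' @param proteomes Named list of proteomes (each a list of protein records).
#' @param ... Passed to [compute_aai()].
#' @return List with `aai` (symmetric matrix, diagonal 100) and `dist`
#'   (symmetric matrix, diagonal 0).
#' @export
aai_matrix_and_distance <- function(proteomes, ...) {
  n <- length(proteomes)
  ids <- names(proteomes)
  if (is.null(ids) || anyDuplicated(ids)) stop("proteomes must be uniquely named")
  aai <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- compute_aai(proteomes[[i]], proteomes[[j]], ...)
    if (is.na(r$aai_pct)) {
      stop("undefined AAI (no reciprocal best hits) for pair ",
           ids[i], " vs ", ids[j])
    }
    aai[i, j] <- aai[j, i] <- r$aai_pct
  }
  list(aai = aai, dist = 100 - aai)
}

#' Cluster proteins into gene families by single linkage
#'
#' Builds the passing-hit graph over the union of all proteomes — including
#' within-genome hits, so paralogs join one family — and returns its
#' connected components. Families partition the protein universe: proteins
#' with no passing hit form singleton families.
#'
#' @param proteomes Named list of proteomes.
#' @param ... Thresholds and alignment parameters for [filtered_hits()].
#' @return A `gene_families` object: data.frame with `family_id`, `genome_id`,
#'   `protein_id`.
#' @export
build_gene_families <- function(proteomes, ...) {
  ids <- names(proteomes)
  if (is.null(ids)) stop("proteomes must be named by genome id")
  # global protein universe with genome attribution
  univ <- do.call(rbind, lapply(ids, function(g) {
    data.frame(genome_id = g,
               protein_id = vapply(proteomes[[g]], `[[`, character(1), "id"),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(univ$protein_id)) {
    stop("protein ids must be unique across genomes")
  }
  edges <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j < i) next  # hits are scored symmetrically under global alignment
    h <- filtered_hits(proteomes[[i]], proteomes[[j]], ...)
    if (nrow(h)) edges[[length(edges) + 1L]] <- h[, c("query_id", "subject_id")]
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges)) do.call(rbind, edges) else
      data.frame(query_id = character(0), subject_id = character(0)),
    directed = FALSE, vertices = univ$protein_id)
  comp <- igraph::components(g)$membership
  fam <- data.frame(family_id = as.integer(comp[univ$protein_id]),
                    genome_id = univ$genome_id,
                    protein_id = univ$protein_id,
                    stringsAsFactors = FALSE)
  # renumber families deterministically by first protein id
  first <- tapply(fam$protein_id, fam$family_id, min)
  remap <- setNames(rank(first, ties.method = "first"), names(first))
  fam$family_id <- as.integer(remap[as.character(fam$family_id)])
  class(fam) <- c("gene_families", "data.frame")
  fam
}

#' Pan/core accumulation curve over an ordered genome set
#'
#' At step k, pan = number of families present in any of the first k genomes
#' and core = number present in all of them; pan is non-decreasing and core
#' non-increasing in k.
#'
#' @param families A `gene_families` data.frame from [build_gene_families()].
#' @param genome_order Character vector covering each genome exactly once.
#' @return data.frame with `step`, `genome_id`, `core`, `pan`.
#' @export
pan_core_curve <- function(families, genome_order) {
  genomes <- unique(families$genome_id)
  if (!setequal(genome_order, genomes) ||
      length(genome_order) != length(genomes)) {
    bad <- setdiff(genome_order, genomes)
    stop("genome_order must cover all genomes exactly once",
         if (length(bad)) paste0("; unknown: ", bad[1L]) else "")
  }
  fam_by_genome <- lapply(split(families$family_id, families$genome_id), unique)
  pan <- core <- integer(length(genome_order))
  pan_set <- core_set <- NULL
  for (k in seq_along(genome_order)) {
    fams <- fam_by_genome[[genome_order[k]]]
    if (k == 1L) { pan_set <- fams; core_set <- fams }
    else { pan_set <- union(pan_set, fams); core_set <- intersect(core_set, fams) }
    pan[k] <- length(pan_set); core[k] <- length(core_set)
  }
  structure(data.frame(step = seq_along(genome_order),
                       genome_id = genome_order, core = core, pan = pan,
                       stringsAsFactors = FALSE),
            class = c("pan_core_curve", "data.frame"))
}

#' Proteins exclusive to one genome
#'
#' Returns the proteins of `focal_genome` whose family contains no protein
#' from any other genome.
#'
#' @param families A `gene_families` data.frame.
#' @param focal_genome Genome id.
#' @return Character vector of protein ids (possibly empty).
#' @export
exclusive_genes <- function(families, focal_genome) {
  if (!focal_genome %in% families$genome_id) {
    stop("unknown focal genome: ", focal_genome)
  }
  span <- tapply(families$genome_id, families$family_id,
                 function(g) length(unique(g)) == 1L)
  own <- families$family_id[families$genome_id == focal_genome]
  excl_fams <- as.integer(names(span))[span]
  sort(families$protein_id[families$genome_id == focal_genome &
                             families$family_id %in% excl_fams])
}
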