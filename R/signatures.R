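#' Window-based GC content profile
#'
#' Per window, GC content = (G+C)/(A+C+G+T); `N` bases are excluded from both
#' numerator and denominator. Windows with no counted base report `NA`.
#'
#' @param genome A genome record.
#' @param window Window size in bp (>= 1).
#' @param step Step between window starts (default `window`).
#' @return A `window_profile` data.frame: `start`, `end` (0-based half-open),
#'   `value`.
#' @export
gc_profile <- function(genome, window = 10000L, step = window) {
  .window_profile(genome, window, step, function(counts) {
    tot <- sum(counts[c("A", "C", "G", "T")])
    if (tot == 0L) NA_real_ else (counts[["G"]] + counts[["C"]]) / tot
  })
}

#' Window-based GC skew profile
#'
#' Per window, skew = (G-C)/(G+C); windows with G+C = 0 report 0 (flagged via
#' the `degenerate` column). The sign of the skew typically flips at the
#' replication origin and terminus.
#'
#' @inheritParams gc_profile
#' @return A `window_profile` data.frame with `start`, `end`, `value`,
#'   `degenerate`.
#' @export
gc_skew_profile <- function(genome, window = 10000L, step = window) {
  p <- .window_profile(genome, window, step, function(counts) {
    gc <- counts[["G"]] + counts[["C"]]
    if (gc == 0L) NA_real_ else (counts[["G"]] - counts[["C"]]) / gc
  })
  p$degenerate <- is.na(p$value)
  p$value[p$degenerate] <- 0
  p
}

.window_profile <- function(genome, window, step, fun) {
  stopifnot(window >= 1L, step >= 1L)
  L <- nchar(genome$sequence)
  if (window > L) {
    warning("window larger than genome; using a single whole-genome window")
    window <- L
  }
  starts <- seq(0L, L - window, by = step)
  x <- Biostrings::DNAString(genome$sequence)
  vals <- vapply(starts, function(s) {
    counts <- Biostrings::letterFrequency(
      Biostrings::subseq(x, s + 1L, s + window), c("A", "C", "G", "T", "N"))
    names(counts) <- c("A", "C", "G", "T", "N")
    fun(counts)
  }, numeric(1))
  structure(data.frame(start = starts, end = starts + window, value = vals),
            class = c("window_profile", "data.frame"),
            genome_id = genome$id, window = window, step = step)
}

# Dinucleotide relative abundances rho(xy) = f(xy) / (f(x) f(y)), counted on
# both strands (sequence plus reverse complement) so the signature is
# invariant to strand choice.
.dinuc_rho <- function(seq) {
  x <- Biostrings::DNAString(seq)
  both <- list(x, Biostrings::reverseComplement(x))
  mono <- Reduce(`+`, lapply(both, Biostrings::letterFrequency,
                             letters = c("A", "C", "G", "T")))
  di <- Reduce(`+`, lapply(both, Biostrings::oligonucleotideFrequency,
                           width = 2L))
  di <- di[!grepl("N", names(di))]
  fmono <- mono / sum(mono)
  names(fmono) <- c("A", "C", "G", "T")
  fdi <- di / sum(di)
  rho <- vapply(names(fdi), function(xy) {
    a <- substr(xy, 1L, 1L); b <- substr(xy, 2L, 2L)
    denom <- fmono[[a]] * fmono[[b]]
    if (denom == 0) NA_real_ else fdi[[xy]] / denom
  }, numeric(1))
  rho
}

#' Dinucleotide composition-anomaly scan
#'
#' For each window, computes the dinucleotide relative-abundance signature
#' rho(xy) = f(xy)/(f(x) f(y)) on both strands and compares it with the
#' whole-genome signature: delta* = mean over the 16 dinucleotides of
#' |rho_window - rho_genome|. Windows with delta* above `threshold` are
#' flagged and contiguous flagged windows are merged into anomaly regions —
#' a simple composition signal for putative genomic islands.
#'
#' @param genome A genome record.
#' @param window Window size in bp (>= 1000; default 10000).
#' @param step Step (default `window`).
#' @param threshold delta* flag threshold (default 0.05).
#' @return A list with `profile` (data.frame `start`, `end`, `delta_star`,
#'   `flagged`) and `anomalies` (data.frame of merged flagged regions with
#'   mean delta*).
#' @export
dinucleotide_bias_scan <- function(genome, window = 10000L, step = window,
                                   threshold = 0.05) {
  stopifnot(window >= 1000L)
  L <- nchar(genome$sequence)
  if (window > L) stop("window larger than genome")
  rho_genome <- .dinuc_rho(genome$sequence)
  starts <- seq(0L, L - window, by = step)
  delta <- vapply(starts, function(s) {
    rho_w <- .dinuc_rho(substr(genome$sequence, s + 1L, s + window))
    mean(abs(rho_w - rho_genome), na.rm = TRUE)
  }, numeric(1))
  flagged <- delta > threshold
  profile <- data.frame(start = starts, end = starts + window,
                        delta_star = delta, flagged = flagged)
  anomalies <- data.frame(start = integer(0), end = integer(0),
                          delta_star = numeric(0))
  idx <- which(flagged)
  if (length(idx)) {
    grp <- cumsum(c(1L, diff(idx) > 1L))
    anomalies <- do.call(rbind, lapply(split(idx, grp), function(g) {
      data.frame(start = starts[g[1L]],
                 end = starts[g[length(g)]] + window,
                 delta_star = mean(delta[g]))
    }))
    rownames(anomalies) <- NULL
  }
  list(profile = profile, anomalies = anomalies)
}

# Six-frame ORF scan: returns data.frame of ORFs (start, end 0-based
# half-open on the forward strand, strand, protein) with length >= min_len_aa.
six_frame_orfs <- function(genome, min_len_aa = 60L) {
  L <- nchar(genome$sequence)
  fwd <- Biostrings::DNAString(genome$sequence)
  rev <- Biostrings::reverseComplement(fwd)
  out <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") fwd else rev
    for (off in 0:2) {
      s <- Biostrings::subseq(src, off + 1L,
                              off + 3L * ((length(src) - off) %/% 3L))
      if (length(s) < 3L) next
      aa <- as.character(Biostrings::translate(s, if.fuzzy.codon = "X"))
      # split on stops; record coordinates of each inter-stop stretch
      pieces <- strsplit(aa, "*", fixed = TRUE)[[1L]]
      pos <- 0L
      for (p in pieces) {
        if (nchar(p) >= min_len_aa) {
          aa_start <- pos  # 0-based within frame translation
          nt_start <- off + 3L * aa_start
          nt_end <- nt_start + 3L * nchar(p)
          if (strand == "-") {
            tmp <- nt_start; nt_start <- L - nt_end; nt_end <- L - tmp
          }
          out[[length(out) + 1L]] <- data.frame(
            start = nt_start, end = nt_end, strand = strand, protein = p,
            stringsAsFactors = FALSE)
        }
        pos <- pos + nchar(p) + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), protein = character(0)))
  }
  do.call(rbind, out)
}

#' Predict the replication origin near hemE
#'
#' In many alpha-proteobacteria oriC lies in the intergenic region adjacent
#' to *hemE* and is marked by clustered DnaA boxes plus an AT-rich duplex
#' unwinding element (DUE). This routine (1) locates the hemE homolog by best
#' protein alignment, against a supplied ORF table or a six-frame scan;
#' (2) scans a flanking span upstream of the hemE start on both strands for
#' 9-mers within `max_mismatches` of the DnaA-box consensus; (3) reports the
#' first run of >= `due_window` bp with AT fraction >= `due_at_min` as the
#' DUE.
#'
#' @param genome A genome record.
#' @param hemE_query A protein record for hemE (uroporphyrinogen
#'   decarboxylase) used to locate the anchor gene.
#' @param orf_set Optional data.frame of ORFs (`start`, `end`, `strand`,
#'   `protein`, optional `protein_id`); when omitted a six-frame scan is used.
#' @param box_consensus DnaA-box 9-mer (default the E. coli consensus
#'   `TTATCCACA`).
#' @param max_mismatches Mismatches allowed per box (default 1).
#' @param span Searched span upstream of the hemE start (default 1000 bp).
#' @param due_window Minimum DUE length (default 50 bp).
#' @param due_at_min Minimum AT fraction of the DUE (default 0.7).
#' @param min_identity_pct hemE match floor (default 40).
#' @return An `oric_prediction` list: `hemE` (start, end, strand,
#'   identity_pct), `intergenic_start`, `intergenic_end`, `boxes` (data.frame
#'   `position`, `strand`, `mismatches`, `matched_sequence`) and `due`
#'   (NULL, or list with start, end, at_fraction). Coordinates 0-based
#'   half-open on the forward strand.
#' @export
find_oric <- function(genome, hemE_query, orf_set = NULL,
                      box_consensus = "TTATCCACA", max_mismatches = 1L,
                      span = 1000L, due_window = 50L, due_at_min = 0.7,
                      min_identity_pct = 40) {
  if (is.null(orf_set)) orf_set <- six_frame_orfs(genome)
  if (!nrow(orf_set)) stop("no ORFs available to locate hemE")
  res <- .align_protein_batch(orf_set$protein, hemE_query$sequence)
  scores <- vapply(res, `[[`, numeric(1), "score")
  best <- list(i = which.max(scores), score = max(scores),
               identity = res[[which.max(scores)]]$identity_pct)
  if (best$identity < min_identity_pct) {
    stop(sprintf("no hemE homolog found (best identity %.1f%% < %.1f%%)",
                 best$identity, min_identity_pct))
  }
  hem <- orf_set[best$i, ]
  # six-frame ORFs run from the previous stop codon, which can precede the
  # gene start; refine the anchor to the aligned span of the query protein
  gl <- .align_protein_glocal(hemE_query$sequence, hem$protein)
  aa_off <- gl$subject_start - 1L
  if (hem$strand == "+") {
    hem$start <- hem$start + 3L * aa_off
  } else {
    hem$end <- hem$end - 3L * aa_off
  }
  L <- nchar(genome$sequence)
  # intergenic region upstream of the hemE start, strand-aware
  if (hem$strand == "+") {
    ig_start <- max(0L, hem$start - span); ig_end <- hem$start
  } else {
    ig_start <- hem$end; ig_end <- min(L, hem$end + span)
  }
  if (ig_end <= ig_start) stop("empty intergenic interval next to hemE")
  region <- substr(genome$sequence, ig_start + 1L, ig_end)
  x <- Biostrings::DNAString(region)
  boxes <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") box_consensus else .revcomp(box_consensus)
    m <- Biostrings::matchPattern(pat, x, max.mismatch = max_mismatches)
    if (length(m)) {
      st <- Biostrings::start(m)
      for (k in seq_along(st)) {
        seq9 <- as.character(m[[k]])
        mm <- sum(strsplit(seq9, "")[[1L]] != strsplit(pat, "")[[1L]])
        boxes[[length(boxes) + 1L]] <- data.frame(
          position = ig_start + st[k] - 1L, strand = strand,
          mismatches = mm,
          matched_sequence = if (strand == "+") seq9 else .revcomp(seq9),
          stringsAsFactors = FALSE)
      }
    }
  }
  boxes <- if (length(boxes)) {
    b <- do.call(rbind, boxes)
    b[order(b$position), , drop = FALSE]
  } else {
    warning("no DnaA boxes found in the intergenic region")
    data.frame(position = integer(0), strand = character(0),
               mismatches = integer(0), matched_sequence = character(0))
  }
  # DUE: first run of >= due_window bp at AT fraction >= due_at_min
  due <- NULL
  chars <- strsplit(region, "")[[1L]]
  at <- as.integer(chars %in% c("A", "T"))
  if (length(at) >= due_window) {
    cs <- c(0L, cumsum(at))
    nwin <- length(at) - due_window + 1L
    frac <- (cs[(due_window + 1L):(due_window + nwin)] - cs[1:nwin]) / due_window
    ok <- which(frac >= due_at_min)
    if (length(ok)) {
      # passing windows separated by < due_window belong to one AT-rich
      # element; report the first merged run
      grp <- cumsum(c(1L, diff(ok) >= due_window))
      g <- ok[grp == 1L]
      s <- g[1L]; e <- g[length(g)] + due_window - 1L
      due <- list(start = ig_start + s - 1L, end = ig_start + e,
                  at_fraction = (cs[e + 1L] - cs[s]) / (e - s + 1L))
    }
  }
  structure(list(
    hemE = list(start = hem$start, end = hem$end, strand = hem$strand,
                identity_pct = best$identity),
    intergenic_start = ig_start, intergenic_end = ig_end,
    boxes = boxes, due = due), class = "oric_prediction")
}

#' Serialize a window profile as TSV
#' @param profile A `window_profile` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
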