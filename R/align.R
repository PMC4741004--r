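#' Pairwise alignment kernel
#'
#' Exact affine-gap dynamic programming (Gotoh, compiled) reporting the
#' identity and coverage conventions used throughout the pipeline:
#'
#' * identity = matches / alignment columns in which neither side is a
#'   terminal gap (internal gaps count as non-matching columns), the closest
#'   convention to BLAST percent identity;
#' * coverage (per side) = aligned non-terminal-gap span / full sequence
#'   length.
#'
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @name pairwise-align
NULL

.aa_matrices <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
                  "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")

.aa_matrix_cache <- new.env(parent = emptyenv())

.get_aa_matrix <- function(name) {
  if (!name %in% .aa_matrices) {
    stop("unknown substitution matrix '", name, "'; available: ",
         paste(.aa_matrices, collapse = ", "))
  }
  if (!exists(name, envir = .aa_matrix_cache)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = .aa_matrix_cache)
  }
  get(name, envir = .aa_matrix_cache)
}

.dna_score_matrix <- function(match, mismatch) {
  m <- matrix(mismatch, 5, 5,
              dimnames = list(c("A", "C", "G", "T", "N"),
                              c("A", "C", "G", "T", "N")))
  diag(m) <- match
  m["N", "N"] <- mismatch  # N never matches, not even itself
  m
}

# core kernel call; returns score, aligned strings and (glocal) the matched
# subject interval, 1-based inclusive
.gotoh <- function(a, b, score_matrix, gap_open, gap_extend, glocal) {
  .gotoh_align_cpp(a, b, score_matrix,
                   paste(colnames(score_matrix), collapse = ""),
                   gap_open, gap_extend, glocal)
}

# identity/coverage metrics from a pair of aligned strings, trimming columns
# that are terminal gaps on either side
.alignment_result_from_strings <- function(pat_str, sub_str, len_a, len_b,
                                           score, subject_start = NA_integer_,
                                           subject_end = NA_integer_) {
  pat <- strsplit(pat_str, "")[[1L]]
  sub <- strsplit(sub_str, "")[[1L]]
  gap_p <- pat == "-"
  gap_s <- sub == "-"
  first_p <- which(!gap_p)[1L]; last_p <- max(which(!gap_p))
  first_s <- which(!gap_s)[1L]; last_s <- max(which(!gap_s))
  lo <- max(first_p, first_s); hi <- min(last_p, last_s)
  cols <- if (is.na(lo) || lo > hi) integer(0) else lo:hi
  matches <- sum(pat[cols] == sub[cols] & pat[cols] != "-")
  aligned_cols <- length(cols)
  structure(list(
    identity_pct = if (aligned_cols > 0L) 100 * matches / aligned_cols
                   else NA_real_,
    aligned_columns = aligned_cols,
    matches = matches,
    query_coverage_pct = 100 * sum(pat[cols] != "-") / len_a,
    subject_coverage_pct = 100 * sum(sub[cols] != "-") / len_b,
    score = score,
    subject_start = subject_start, subject_end = subject_end,
    aligned_a = pat_str, aligned_b = sub_str
  ), class = "alignment_result")
}

#' Align two DNA sequences with affine gaps
#'
#' @param a,b DNA strings (non-empty). `N` is scored as a mismatch.
#' @param match,mismatch Match reward and mismatch penalty (penalty given as a
#'   negative number). Defaults `+1/-1`; a BLASTn-like `+2/-3` preset is
#'   available via `preset = "blastn"`.
#' @param gap_open,gap_extend Affine gap parameters (positive costs).
#' @param mode `"global"` (Needleman-Wunsch) or `"glocal"` (the whole of `a`
#'   aligned to the best-matching region of `b`; terminal gaps in `b`
#'   unpenalized).
#' @param preset `"default"` or `"blastn"` (match +2, mismatch -3).
#' @return An `alignment_result` with identity, aligned columns, matches,
#'   per-side coverage and score; for glocal mode also the matched subject
#'   interval (`subject_start`, `subject_end`, 1-based inclusive).
#' @examples
#' align_dna("ACGT", "ACGA")$identity_pct  # 75
#' @export
align_dna <- function(a, b, match = 1, mismatch = -1,
                      gap_open = 5, gap_extend = 2,
                      mode = c("global", "glocal"),
                      preset = c("default", "blastn")) {
  mode <- match.arg(mode)
  preset <- match.arg(preset)
  if (preset == "blastn") { match <- 2; mismatch <- -3 }
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  r <- .gotoh(a, b, .dna_score_matrix(match, mismatch),
              gap_open, gap_extend, mode == "glocal")
  .alignment_result_from_strings(r$aligned_a, r$aligned_b,
                                 nchar(a), nchar(b), r$score,
                                 r$subject_start, r$subject_end)
}

#' Align two protein sequences with affine gaps
#'
#' Global (Needleman-Wunsch) alignment under a named substitution matrix.
#' Defaults follow BLASTp: BLOSUM62, gap open 11, gap extend 1.
#'
#' @param a,b Amino-acid strings.
#' @param matrix Substitution matrix name (e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap costs.
#' @return An `alignment_result`; see [align_dna()].
#' @export
align_protein <- function(a, b, matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  r <- .gotoh(a, b, .get_aa_matrix(matrix), gap_open, gap_extend, FALSE)
  .alignment_result_from_strings(r$aligned_a, r$aligned_b,
                                 nchar(a), nchar(b), r$score)
}

# many queries against one subject (kept for call-site symmetry)
.align_protein_batch <- function(queries, subject, matrix = "BLOSUM62",
                                 gap_open = 11, gap_extend = 1) {
  sm <- .get_aa_matrix(matrix)
  lapply(queries, function(q) {
    r <- .gotoh(q, subject, sm, gap_open, gap_extend, FALSE)
    .alignment_result_from_strings(r$aligned_a, r$aligned_b,
                                   nchar(q), nchar(subject), r$score)
  })
}

# glocal protein alignment (pattern global, subject local): used to locate a
# query protein inside a longer ORF translation
.align_protein_glocal <- function(a, b, matrix = "BLOSUM62",
                                  gap_open = 11, gap_extend = 1) {
  r <- .gotoh(a, b, .get_aa_matrix(matrix), gap_open, gap_extend, TRUE)
  .alignment_result_from_strings(r$aligned_a, r$aligned_b,
                                 nchar(a), nchar(b), r$score,
                                 r$subject_start, r$subject_end)
}
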