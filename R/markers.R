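#' Call streptomycin-resistance residues in an RpsL homolog
#'
#' Substitutions K42R or K87R in ribosomal protein S12 (RpsL, E. coli
#' numbering) confer streptomycin resistance. The query is globally aligned
#' to a reference RpsL whose positions 42 and 87 are validated lysines; the
#' reference columns are mapped through the alignment to query residues and
#' the verdict is:
#'
#' * `resistant` — arginine (R) at either mapped position;
#' * `indeterminate` — either position maps to a gap;
#' * `sensitive` — otherwise (a non-K, non-R residue is noted but does not
#'   trigger resistance, which is attributed specifically to arginine).
#'
#' @param query A protein record.
#' @param reference_rpsl A protein record with K at positions 42 and 87
#'   (1-based on the ungapped sequence). Defaults to the packaged synthetic
#'   reference (see [rpsl_reference()]).
#' @param positions Reference positions checked (default `c(42, 87)`).
#' @param min_identity_pct Homology floor; below it the query is rejected as
#'   not an RpsL homolog (default 40).
#' @return A `marker_call` list: `protein_id`, `residue_42`, `residue_87`,
#'   `verdict`, `identity_pct`, `aligned_positions` (named integer vector of
#'   1-based query positions, `NA` where gapped), `note`.
#' @export
rpsl_call <- function(query, reference_rpsl = rpsl_reference(),
                      positions = c(42L, 87L), min_identity_pct = 40) {
  ref_chars <- strsplit(reference_rpsl$sequence, "")[[1L]]
  if (any(ref_chars[positions] != "K")) {
    stop("reference RpsL must have K at positions ",
         paste(positions, collapse = " and "))
  }
  r <- align_protein(reference_rpsl$sequence, query$sequence)
  if (is.na(r$identity_pct) || r$identity_pct < min_identity_pct) {
    stop(sprintf("not an RpsL homolog (identity %.1f%% < %.1f%%)",
                 r$identity_pct, min_identity_pct))
  }
  ref_aln <- strsplit(r$aligned_a, "")[[1L]]
  qry_aln <- strsplit(r$aligned_b, "")[[1L]]
  ref_pos <- cumsum(ref_aln != "-")
  qry_pos <- cumsum(qry_aln != "-")
  mapped <- setNames(rep(NA_integer_, length(positions)),
                     as.character(positions))
  residues <- setNames(rep(NA_character_, length(positions)),
                       as.character(positions))
  for (k in seq_along(positions)) {
    col <- which(ref_pos == positions[k] & ref_aln != "-")[1L]
    if (!is.na(col) && qry_aln[col] != "-") {
      mapped[k] <- qry_pos[col]
      residues[k] <- qry_aln[col]
    }
  }
  verdict <- if (any(is.na(residues))) "indeterminate"
  else if (any(residues == "R")) "resistant"
  else "sensitive"
  note <- {
    odd <- !is.na(residues) & !residues %in% c("K", "R")
    if (any(odd)) {
      paste0("non-K/non-R residue at reference position ",
             paste(positions[odd], collapse = ","), " (",
             paste(residues[odd], collapse = ","), ")")
    } else NA_character_
  }
  structure(list(protein_id = query$id,
                 residue_42 = residues[[as.character(42L)]] %||% NA_character_,
                 residue_87 = residues[[as.character(87L)]] %||% NA_character_,
                 verdict = verdict, identity_pct = r$identity_pct,
                 aligned_positions = mapped, note = note),
            class = "marker_call")
}

#' Packaged RpsL reference
#'
#' Returns the packaged reference used for resistance calling. This is a
#' SYNTHETIC stand-in sequence (not the biological E. coli K-12 RpsL) with
#' validated lysines at positions 42 and 87 under E. coli-style numbering;
#' substitute any validated real reference via the `reference_rpsl` argument
#' of [rpsl_call()].
#'
#' @return A protein record.
#' @export
rpsl_reference <- function() {
  path <- system.file("extdata", "rpsl_reference_synthetic.faa",
                      package = "genotax")
  read_fasta(path, "protein")[[1L]]
}

#' Scan a proteome for its best RpsL homolog and call resistance
#'
#' Aligns every protein against the reference, picks the best-scoring
#' candidate above the homology floor and returns its [rpsl_call()].
#'
#' @param proteome List of protein records.
#' @param reference_rpsl Reference (see [rpsl_call()]).
#' @param min_identity_pct Homology floor (default 40).
#' @return A `marker_call`, or an error when no homolog qualifies.
#' @export
rpsl_scan <- function(proteome, reference_rpsl = rpsl_reference(),
                      min_identity_pct = 40) {
  seqs <- vapply(proteome, `[[`, character(1), "sequence")
  res <- .align_protein_batch(seqs, reference_rpsl$sequence)
  best <- which.max(vapply(res, `[[`, numeric(1), "score"))
  rpsl_call(proteome[[best]], reference_rpsl,
            min_identity_pct = min_identity_pct)
}
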