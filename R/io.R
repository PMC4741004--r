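#' Read sequences from a FASTA file
#'
#' Reads DNA or protein FASTA into a list of records. DNA sequences are
#' upper-cased on load and validated against the `{A,C,G,T,N}` alphabet;
#' proteins against the 20 amino-acid letters plus `X`. Record order is
#' preserved and ids must be unique.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A list of records; each is a list with `id`, `description`,
#'   `sequence` and `length`. For proteins a `genome_id` field is added,
#'   taken from the description token `genome=<id>` when present, else `NA`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 first", "acgt", "ACGT", ">g2", "GGCC"), tf)
#' recs <- read_fasta(tf, "dna")
#' vapply(recs, `[[`, integer(1), "length")
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  # read as raw strings so alphabet validation (with positions) is ours
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  seqs <- unname(toupper(as.character(set)))
  legal <- if (alphabet == "dna") "ACGTN" else "ACDEFGHIKLMNPQRSTVWYX"
  bad <- regexpr(sprintf("[^%s]", legal), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal %s character '%s' at position %d of record '%s'",
                 alphabet, substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  if (alphabet == "protein" && any(nchar(seqs) < 1L)) {
    stop("zero-length protein record")
  }
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    rec <- list(id = ids[i], description = desc[i], sequence = seqs[i],
                length = nchar(seqs[i]))
    if (alphabet == "protein") {
      gm <- regmatches(desc[i], regexpr("genome=\\S+", desc[i]))
      rec$genome_id <- if (length(gm)) sub("^genome=", "", gm) else NA_character_
    }
    out[[i]] <- rec
  }
  names(out) <- ids
  out
}

#' Write sequence records to FASTA
#'
#' @param records A list of records as returned by [read_fasta()], or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- mapply(function(id, s) list(id = id, description = "",
                                           sequence = s),
                      names(records), records, SIMPLIFY = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    hdr <- if (nzchar(rec$description %||% "")) {
      paste(rec$id, rec$description)
    } else rec$id
    writeLines(paste0(">", hdr), con)
    s <- rec$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a labelled matrix as TSV, optionally with a companion matrix
#'
#' Serializes an identity-style matrix in the layout used for ANI reports:
#' when a companion aligned-fraction matrix is supplied each cell is formatted
#' `"NN.NN [MM.MM]"`; otherwise plain `"NN.NN"`. Diagonal cells of square
#' matrices with identical row/column labels are written empty
#' (self-comparisons are omitted).
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param companion Optional numeric matrix of identical shape (e.g. aligned
#'   fractions) printed in brackets after each value.
#' @param digits Decimal places (default 2).
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(m, path, companion = NULL, digits = 2L) {
  stopifnot(is.matrix(m))
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("row/column labels must be unique")
  }
  if (!is.null(companion) && !identical(dim(companion), dim(m))) {
    stop("companion matrix shape does not match value matrix")
  }
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  cells <- matrix("", nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      diagonal <- !is.null(rownames(m)) && !is.null(colnames(m)) &&
        rownames(m)[i] == colnames(m)[j]
      if (diagonal) next
      if (is.na(m[i, j])) { cells[i, j] <- "NA"; next }
      cells[i, j] <- if (is.null(companion)) {
        fmt(m[i, j])
      } else {
        sprintf("%s [%s]", fmt(m[i, j]), fmt(companion[i, j]))
      }
    }
  }
  lines <- c(paste(c("", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], cells[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Re-parse a matrix written by [write_tsv_matrix()]
#'
#' @param path TSV path.
#' @return A list with `values` and (when bracketed companions are present)
#'   `companion`, both numeric matrices; empty diagonal cells become `NA`.
#' @export
read_tsv_matrix <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1L], "\t")[[1L]][-1L]
  body <- strsplit(lines[-1L], "\t")
  rlab <- vapply(body, `[`, character(1), 1L)
  vals <- comp <- matrix(NA_real_, length(rlab), length(header),
                         dimnames = list(rlab, header))
  has_comp <- FALSE
  for (i in seq_along(body)) {
    row <- body[[i]][-1L]
    length(row) <- length(header)
    for (j in seq_along(header)) {
      cell <- row[j]
      if (is.na(cell) || cell == "" ) next
      m <- regmatches(cell, regexec("^([-0-9.]+)(?: \\[([-0-9.]+)\\])?$", cell))[[1L]]
      vals[i, j] <- as.numeric(m[2L])
      if (length(m) >= 3L && nzchar(m[3L])) {
        comp[i, j] <- as.numeric(m[3L]); has_comp <- TRUE
      }
    }
  }
  out <- list(values = vals)
  if (has_comp) out$companion <- comp
  out
}

#' Report a part/whole percentage
#'
#' The rounding convention used in genome summary tables (e.g. coding
#' fraction = coding bases / genome size, or annotated fraction = annotated
#' genes / predicted genes).
#'
#' @param part,whole Numerator and denominator.
#' @param digits Decimal places (default 2).
#' @return Percentage rounded to `digits`.
#' @examples
#' report_fraction(4187393, 4679853)  # coding fraction, 89.47
#' @export
report_fraction <- function(part, whole, digits = 2L) {
  if (whole == 0) stop("whole must be non-zero")
  round(100 * part / whole, digits)
}

#' Create a region annotation
#'
#' Regions use 0-based half-open coordinates internally, so the reported
#' length is `end - start` — the same arithmetic as printed genome-region
#' tables (e.g. a region at 173,796–220,082 spans 46,286 bp).
#'
#' @param genome_id Chromosome/genome id.
#' @param start,end 0-based half-open interval, `0 <= start < end`.
#' @param label Feature name.
#' @param score Numeric score (default 0).
#' @return A `region_annotation` list.
#' @export
region_annotation <- function(genome_id, start, end, label = ".", score = 0) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid region: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  structure(list(genome_id = genome_id, start = start, end = end,
                 label = label, score = score,
                 length = end - start),
            class = "region_annotation")
}

#' Write regions to a BED file
#'
#' Standard 5-column BED (chrom, start, end, name, score), 0-based half-open.
#'
#' @param regions List of [region_annotation()] objects (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  if (length(regions) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  lines <- vapply(regions, function(r) {
    if (r$start >= r$end) stop("region with start >= end: ", r$label)
    sprintf("%s\t%d\t%d\t%s\t%s", r$genome_id, r$start, r$end, r$label,
            format(r$score, trim = TRUE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' @param path BED path.
#' @return List of [region_annotation()] objects.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1L]]
    region_annotation(f[1L], as.integer(f[2L]), as.integer(f[3L]),
                      if (length(f) >= 4L) f[4L] else ".",
                      if (length(f) >= 5L) as.numeric(f[5L]) else 0)
  })
}

#' Read an OD600 growth series from CSV
#'
#' Expects the header `time_h,od600`. Times must be strictly increasing and
#' OD values positive (inputs are expected blank-corrected).
#'
#' @param path CSV path.
#' @param condition Optional condition label attached to the series.
#' @return A `growth_series` list with `time`, `od600`, `condition`.
#' @export
read_growth_csv <- function(path, condition = NA_character_) {
  d <- read.csv(path)
  if (!all(c("time_h", "od600") %in% names(d))) {
    stop("growth CSV must have columns time_h,od600")
  }
  growth_series(d$time_h, d$od600, condition)
}

#' Construct a growth series
#' @param time Hours, strictly increasing.
#' @param od600 Optical densities, all > 0.
#' @param condition Optional label.
#' @return A `growth_series` list.
#' @export
growth_series <- function(time, od600, condition = NA_character_) {
  if (length(time) != length(od600)) stop("time and od600 lengths differ")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(od600 <= 0)) stop("non-positive OD600 value at row ",
                            which(od600 <= 0)[1L])
  structure(list(time = as.numeric(time), od600 = as.numeric(od600),
                 condition = condition), class = "growth_series")
}

#' Read a nitrate/nitrite chemistry series from CSV
#'
#' Expects the header `time_h,nitrate_mM,nitrite_mM`; concentrations must be
#' non-negative.
#'
#' @param path CSV path.
#' @return A `chem_series` list with `time`, `nitrate_mM`, `nitrite_mM`.
#' @export
read_chem_csv <- function(path) {
  d <- read.csv(path)
  need <- c("time_h", "nitrate_mM", "nitrite_mM")
  if (!all(need %in% names(d))) {
    stop("chemistry CSV must have columns ", paste(need, collapse = ","))
  }
  chem_series(d$time_h, d$nitrate_mM, d$nitrite_mM)
}

#' Construct a chemistry series
#' @param time Hours.
#' @param nitrate_mM,nitrite_mM Concentrations in mM, non-negative.
#' @return A `chem_series` list.
#' @export
chem_series <- function(time, nitrate_mM, nitrite_mM) {
  n <- length(time)
  if (length(nitrate_mM) != n || length(nitrite_mM) != n) {
    stop("chemistry columns must all have the same length")
  }
  if (any(nitrate_mM < 0) || any(nitrite_mM < 0)) {
    stop("negative concentration")
  }
  structure(list(time = as.numeric(time), nitrate_mM = as.numeric(nitrate_mM),
                 nitrite_mM = as.numeric(nitrite_mM)), class = "chem_series")
}
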