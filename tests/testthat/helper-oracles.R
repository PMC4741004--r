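# Independent oracles, written before the implementations they check.
# Conventions (shared with the package by design, not by code):
#   - affine gap of length L costs gap_open + L * gap_extend
#   - identity = matches / columns excluding terminal-gap columns

# Plain-R Gotoh dynamic programming, global mode; returns the optimal score.
oracle_dp_score <- function(a, b, score_fun, gap_open, gap_extend,
                            mode = c("global", "glocal")) {
  mode <- match.arg(mode)
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  # X: gap in b (a consumed), Y: gap in a (b consumed)
  M[1L, 1L] <- 0
  for (i in 2L:(n + 1L)) {
    X[i, 1L] <- -(gap_open + (i - 1L) * gap_extend)
  }
  if (mode == "global") {
    for (j in 2L:(m + 1L)) Y[1L, j] <- -(gap_open + (j - 1L) * gap_extend)
  } else {
    for (j in 2L:(m + 1L)) M[1L, j] <- 0  # free leading subject gap
  }
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- score_fun(av[i - 1L], bv[j - 1L])
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - gap_open - gap_extend,
                     X[i - 1L, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1L] - gap_open - gap_extend,
                     Y[i, j - 1L] - gap_extend)
    }
  }
  if (mode == "global") {
    max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  } else {
    max(M[n + 1L, ], X[n + 1L, ])  # free trailing subject gap
  }
}

oracle_dna_score_fun <- function(match = 1, mismatch = -1) {
  function(x, y) if (x == y && x != "N" && y != "N") match else mismatch
}

oracle_blosum62_fun <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- get("BLOSUM62", envir = e)
  function(x, y) B[x, y]
})

# Brute-force RBH/AAI oracle: full identity/score matrices via align_protein
# (score equivalence with plain DP is checked separately), thresholds and
# mutual-best selection done here from first principles.
oracle_rbh_aai <- function(proteomeA, proteomeB, id_min = 30, cov_min = 70) {
  na <- length(proteomeA); nb <- length(proteomeB)
  idm <- scm <- matrix(NA_real_, na, nb)
  pass <- matrix(FALSE, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    r <- align_protein(proteomeA[[i]]$sequence, proteomeB[[j]]$sequence)
    idm[i, j] <- r$identity_pct
    scm[i, j] <- r$score
    la <- nchar(proteomeA[[i]]$sequence); lb <- nchar(proteomeB[[j]]$sequence)
    cov_longer <- if (la >= lb) r$query_coverage_pct else r$subject_coverage_pct
    pass[i, j] <- r$identity_pct >= id_min && cov_longer >= cov_min
  }
  ids_a <- vapply(proteomeA, `[[`, character(1), "id")
  ids_b <- vapply(proteomeB, `[[`, character(1), "id")
  best_of <- function(scores, idents, labels, keep) {
    cand <- which(keep)
    if (!length(cand)) return(NA_integer_)
    o <- order(-scores[cand], -idents[cand], labels[cand])
    cand[o[1L]]
  }
  pairs <- list()
  for (i in seq_len(na)) {
    j <- best_of(scm[i, ], idm[i, ], ids_b, pass[i, ])
    if (is.na(j)) next
    i_back <- best_of(scm[, j], idm[, j], ids_a, pass[, j])
    if (!is.na(i_back) && i_back == i) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        protein_a = ids_a[i], protein_b = ids_b[j],
        identity_pct = idm[i, j], stringsAsFactors = FALSE)
    }
  }
  rbh <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(protein_a = character(0), protein_b = character(0),
               identity_pct = numeric(0))
  rbh <- rbh[order(rbh$protein_a), , drop = FALSE]
  rownames(rbh) <- NULL
  list(rbh = rbh,
       aai = if (nrow(rbh)) mean(rbh$identity_pct) else NA_real_)
}

# Per-window counting oracle for GC content / skew.
oracle_gc_windows <- function(seq, window, step, what = c("gc", "skew")) {
  what <- match.arg(what)
  chars <- strsplit(seq, "")[[1L]]
  starts <- seq(0L, nchar(seq) - window, by = step)
  vapply(starts, function(s) {
    w <- chars[(s + 1L):(s + window)]
    g <- sum(w == "G"); c_ <- sum(w == "C")
    acgt <- sum(w %in% c("A", "C", "G", "T"))
    if (what == "gc") {
      if (acgt == 0L) NA_real_ else (g + c_) / acgt
    } else {
      if (g + c_ == 0L) 0 else (g - c_) / (g + c_)
    }
  }, numeric(1))
}

# Brute-force p-distance.
oracle_p_distance <- function(rows) {
  n <- length(rows)
  m <- do.call(rbind, strsplit(rows, ""))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

# Random additive distance matrix from a random tree with known topology.
oracle_additive_case <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE,
                     tip.label = paste0("t", seq_len(n_taxa)))
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
    tr
  })
}

rand_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_protein_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
        collapse = "")
}

# substitute exactly k positions (never to the same letter)
mutate_str <- function(s, k, alphabet) {
  ch <- strsplit(s, "")[[1L]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(alphabet, ch[p]), 1L)
  paste(ch, collapse = "")
}

make_protein_record <- function(id, seq, genome_id = NA_character_) {
  list(id = id, genome_id = genome_id, sequence = seq, length = nchar(seq))
}

make_genome_record <- function(id, seq) {
  list(id = id, description = "", sequence = seq, length = nchar(seq))
}
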