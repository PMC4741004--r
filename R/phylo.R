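#' Multiple-alignment container
#'
#' Rows are sequences over a nucleotide-plus-gap alphabet; all rows must have
#' equal length. Stored as a character matrix (one column per site) with
#' labels as row names.
#'
#' @param labels Unique sequence labels.
#' @param sequences Character vector of equal-length (gapped) sequences.
#' @return A `multiple_alignment` (character matrix).
#' @export
multiple_alignment <- function(labels, sequences) {
  if (length(labels) != length(sequences)) stop("labels/sequences mismatch")
  if (anyDuplicated(labels)) stop("duplicate labels")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("all rows must have the same length")
  m <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(m) <- labels
  class(m) <- c("multiple_alignment", class(m))
  m
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("multiple_alignment: %d sequences x %d columns\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Pairwise p-distances from a multiple alignment
#'
#' `d(i, j)` = mismatches / compared sites. Gap columns are excluded per
#' `gap_mode`: `"pairwise-delete"` drops, for each pair, only the columns
#' where that pair has a gap; `"complete-delete"` drops every column
#' containing any gap before comparing.
#'
#' @param aln A [multiple_alignment()].
#' @param gap_mode `"pairwise-delete"` (default) or `"complete-delete"`.
#' @param model `"p"` (default) or `"JC69"` for the Jukes-Cantor correction
#'   `-3/4 log(1 - 4p/3)`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(aln, gap_mode = c("pairwise-delete", "complete-delete"),
                       model = c("p", "JC69")) {
  gap_mode <- match.arg(gap_mode)
  model <- match.arg(model)
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  m <- unclass(aln)
  if (gap_mode == "complete-delete") {
    keep <- colSums(m == "-") == 0L
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    nc <- sum(ok)
    if (nc == 0L) stop("zero comparable sites for pair ",
                       rownames(m)[i], " vs ", rownames(m)[j])
    p <- sum(m[i, ok] != m[j, ok]) / nc
    if (model == "JC69") {
      if (p >= 0.75) stop("p-distance too large for JC69 correction (pair ",
                          rownames(m)[i], " vs ", rownames(m)[j], ")")
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration, exact on additive matrices. Negative
#' branch lengths are clamped to zero with the deficit moved to the sister
#' edge. Ties in the Q criterion are broken deterministically by the
#' lexicographically lowest pair of subtree labels (each subtree is
#' represented by its smallest leaf label).
#'
#' @param D Symmetric numeric matrix with zero diagonal and row/column names,
#'   at least 3 taxa.
#' @return An unrooted `phylo` tree (ape) with branch lengths.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square")
  if (is.null(rownames(D))) stop("D must have labels")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labs <- rownames(D)
  # active nodes carry their Newick fragment and smallest-leaf representative
  nwk <- labs
  rep_lab <- labs
  d <- D
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.15g", x)
  while (length(active) > 3L) {
    r <- length(active)
    dm <- d[active, active, drop = FALSE]
    R <- rowSums(dm)
    best <- NULL
    for (ii in seq_len(r - 1L)) for (jj in (ii + 1L):r) {
      q <- (r - 2) * dm[ii, jj] - R[ii] - R[jj]
      key <- sort(c(rep_lab[active[ii]], rep_lab[active[jj]]))
      if (is.null(best) || q < best$q - 1e-12 ||
          (abs(q - best$q) <= 1e-12 &&
           (key[1L] < best$key[1L] ||
            (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
        best <- list(q = q, i = ii, j = jj, key = key)
      }
    }
    i <- active[best$i]; j <- active[best$j]
    dij <- d[i, j]
    bi <- dij / 2 + (R[best$i] - R[best$j]) / (2 * (r - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)
    # new node u
    u <- nrow(d) + 1L
    newd <- (d[i, active] + d[j, active] - dij) / 2
    d <- rbind(cbind(d, 0), 0)
    d[u, active] <- newd; d[active, u] <- newd; d[u, u] <- 0
    nwk <- c(nwk, sprintf("(%s:%s,%s:%s)", nwk[i], fmt(bi), nwk[j], fmt(bj)))
    rep_lab <- c(rep_lab, min(rep_lab[i], rep_lab[j]))
    active <- c(setdiff(active, c(i, j)), u)
  }
  a <- active[order(rep_lab[active])]
  d12 <- d[a[1L], a[2L]]; d13 <- d[a[1L], a[3L]]; d23 <- d[a[2L], a[3L]]
  b1 <- max((d12 + d13 - d23) / 2, 0)
  b2 <- max((d12 + d23 - d13) / 2, 0)
  b3 <- max((d13 + d23 - d12) / 2, 0)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    nwk[a[1L]], fmt(b1), nwk[a[2L]], fmt(b2), nwk[a[3L]], fmt(b3))
  ape::read.tree(text = newick)
}

# Canonical keys for the non-trivial bipartitions (internal edges) of an
# unrooted phylo tree: each key is the sorted tip set on the side NOT
# containing the alphabetically first tip, pasted with "|".
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  ntip <- length(tree$tip.label)
  keys <- character(0)
  node_of <- integer(0)
  # descendants of each internal node
  for (node in unique(tree$edge[, 2L][tree$edge[, 2L] > ntip])) {
    desc <- ape::extract.clade(tree, node)$tip.label
    side <- sort(desc)
    if (tips[1L] %in% side) side <- sort(setdiff(tips, side))
    if (length(side) < 2L || length(side) > ntip - 2L) next  # trivial split
    keys <- c(keys, paste(side, collapse = "|"))
    node_of <- c(node_of, node)
  }
  list(keys = keys, nodes = node_of)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' NJ tree on each replicate, and annotates each internal edge of the
#' full-data tree with the percentage of replicate trees containing the same
#' bipartition. Supports are stored as integer node labels.
#'
#' @param aln A [multiple_alignment()].
#' @param n_reps Number of replicates (default 1000).
#' @param seed Integer seed (required; resampling is the only randomness).
#' @param gap_mode,model Passed to [p_distance()].
#' @return A `phylo` tree (the full-data NJ tree) with `node.label` holding
#'   bootstrap percentages on internal nodes.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed,
                              gap_mode = "pairwise-delete", model = "p") {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (missing(seed)) stop("seed is required")
  if (ncol(aln) < 1L) stop("alignment has no columns")
  full <- neighbor_joining(p_distance(aln, gap_mode, model))
  bp <- tree_bipartitions(full)
  counts <- setNames(rep(0L, length(bp$keys)), bp$keys)
  cols <- with_seed(seed, matrix(sample.int(ncol(aln), ncol(aln) * n_reps,
                                            replace = TRUE),
                                 nrow = n_reps))
  for (r in seq_len(n_reps)) {
    res <- aln[, cols[r, ], drop = FALSE]
    class(res) <- class(aln)
    rt <- try(neighbor_joining(p_distance(res, gap_mode, model)),
              silent = TRUE)
    if (inherits(rt, "try-error")) next
    rk <- tree_bipartitions(rt)$keys
    hit <- bp$keys %in% rk
    counts[hit] <- counts[hit] + 1L
  }
  support <- as.integer(round(100 * counts / n_reps))
  ntip <- length(full$tip.label)
  node_lab <- rep("", full$Nnode)
  node_lab[bp$nodes - ntip] <- as.character(support)
  full$node.label <- node_lab
  full
}

#' Concatenate per-gene alignments into one supermatrix
#'
#' Rows are matched by label (not position); every block must contain every
#' label. Block boundaries are recorded in the `"blocks"` attribute as a
#' data.frame of `start`/`end` columns (1-based, inclusive).
#'
#' @param blocks Ordered list of [multiple_alignment()] objects; names used
#'   as block names when present.
#' @return A [multiple_alignment()] with `sum(columns)` sites.
#' @export
concatenate_alignments <- function(blocks) {
  if (!length(blocks)) stop("no blocks")
  labels <- sort(rownames(blocks[[1L]]))
  for (b in seq_along(blocks)) {
    missing_lab <- setdiff(labels, rownames(blocks[[b]]))
    extra <- setdiff(rownames(blocks[[b]]), labels)
    if (length(missing_lab) || length(extra)) {
      stop("label '", c(missing_lab, extra)[1L],
           "' not shared by block ", b)
    }
  }
  mats <- lapply(blocks, function(b) unclass(b)[labels, , drop = FALSE])
  out <- do.call(cbind, mats)
  ends <- cumsum(vapply(mats, ncol, integer(1)))
  starts <- c(1L, head(ends, -1L) + 1L)
  res <- multiple_alignment(labels, apply(out, 1L, paste, collapse = ""))
  attr(res, "blocks") <- data.frame(
    block = names(blocks) %||% paste0("block", seq_along(blocks)),
    start = starts, end = ends)
  res
}

#' AAI-based dendrogram
#'
#' Builds an NJ tree from an AAI distance matrix (`100 - AAI`). An outgroup
#' may be supplied for display rooting only; branch lengths are unchanged.
#'
#' @param dist_matrix Symmetric matrix of `100 - AAI` distances.
#' @param outgroup Optional tip label used to root the returned tree.
#' @return A `phylo` tree.
#' @export
aai_dendrogram <- function(dist_matrix, outgroup = NULL) {
  tree <- neighbor_joining(dist_matrix)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) stop("unknown outgroup: ", outgroup)
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  tree
}

#' Progressive (center-star) alignment of a small marker set
#'
#' A lightweight aligner for marker genes: the center sequence minimizing the
#' total alignment distance to all others is chosen, every other sequence is
#' globally aligned to it, and the pairwise alignments are merged by gap
#' propagation. Intended for small, closely related marker sets; for large or
#' highly divergent data supply a precomputed alignment instead.
#'
#' @param seqs Named character vector of unaligned DNA sequences.
#' @param match,mismatch,gap_open,gap_extend DNA scoring (see [align_dna()]).
#' @return A [multiple_alignment()].
#' @export
align_markers <- function(seqs, match = 1, mismatch = -1,
                          gap_open = 5, gap_extend = 2) {
  n <- length(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must be uniquely named")
  }
  if (n == 1L) return(multiple_alignment(names(seqs), unname(seqs)))
  score_mat <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- align_dna(seqs[[i]], seqs[[j]], match = match, mismatch = mismatch,
                   gap_open = gap_open, gap_extend = gap_extend)$score
    score_mat[i, j] <- score_mat[j, i] <- s
  }
  center <- which.max(rowSums(score_mat))
  aligned_center <- strsplit(seqs[[center]], "")[[1L]]
  rows <- list()
  rows[[names(seqs)[center]]] <- aligned_center
  for (i in seq_len(n)) {
    if (i == center) next
    pa <- align_dna(seqs[[i]], seqs[[center]], match = match,
                    mismatch = mismatch, gap_open = gap_open,
                    gap_extend = gap_extend)
    qi <- strsplit(pa$aligned_a, "")[[1L]]
    ci <- strsplit(pa$aligned_b, "")[[1L]]
    # merge: walk master center vs this center, inserting gaps on either side
    master <- rows[[names(seqs)[center]]]
    new_master <- character(0); new_rows <- lapply(rows, function(r) character(0))
    new_q <- character(0)
    a <- 1L; b <- 1L
    while (a <= length(master) || b <= length(ci)) {
      ma <- if (a <= length(master)) master[a] else NULL
      cb <- if (b <= length(ci)) ci[b] else NULL
      if (!is.null(ma) && ma == "-" && (is.null(cb) || cb != "-")) {
        # master-only gap column: pad the new sequence
        for (nm in names(rows)) new_rows[[nm]] <- c(new_rows[[nm]], rows[[nm]][a])
        new_master <- c(new_master, "-"); new_q <- c(new_q, "-"); a <- a + 1L
      } else if (!is.null(cb) && cb == "-" && (is.null(ma) || ma != "-")) {
        # gap inserted into center by this pairwise alignment: pad old rows
        for (nm in names(rows)) new_rows[[nm]] <- c(new_rows[[nm]], "-")
        new_master <- c(new_master, "-"); new_q <- c(new_q, qi[b]); b <- b + 1L
      } else {
        for (nm in names(rows)) new_rows[[nm]] <- c(new_rows[[nm]], rows[[nm]][a])
        new_master <- c(new_master, master[a]); new_q <- c(new_q, qi[b])
        a <- a + 1L; b <- b + 1L
      }
    }
    rows <- new_rows
    rows[[names(seqs)[center]]] <- new_master
    rows[[names(seqs)[i]]] <- new_q
  }
  rows <- rows[names(seqs)]
  multiple_alignment(names(seqs),
                     vapply(rows, paste, character(1), collapse = ""))
}

#' Write a tree to Newick
#'
#' Labels containing spaces are quoted; node labels (e.g. bootstrap
#' percentages) are preserved.
#'
#' @param tree A `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  t2 <- tree
  needs_quote <- grepl("\\s", t2$tip.label)
  t2$tip.label[needs_quote] <- sprintf("'%s'", t2$tip.label[needs_quote])
  ape::write.tree(t2, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return A `phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)
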