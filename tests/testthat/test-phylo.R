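test_that("p-distance matches hand arithmetic and the counting oracle", {
  aln <- multiple_alignment(c("s1", "s2"), c("AAAA", "AAAT"))
  expect_equal(p_distance(aln)["s1", "s2"], 0.25)

  aln0 <- multiple_alignment(c("a", "b", "c"), rep("ACGTACGT", 3))
  expect_true(all(p_distance(aln0) == 0))

  withr::with_seed(11, {
    rows <- replicate(5, paste(sample(c("A", "C", "G", "T", "-"), 60,
                                      replace = TRUE,
                                      prob = c(rep(0.22, 4), 0.12)),
                               collapse = ""))
  })
  aln_r <- multiple_alignment(paste0("t", 1:5), rows)
  expect_equal(unname(p_distance(aln_r)), oracle_p_distance(rows))

  # complete deletion drops gapped columns globally
  aln_g <- multiple_alignment(c("x", "y"), c("A-CG", "AACG"))
  expect_equal(p_distance(aln_g, "complete-delete")["x", "y"], 0)

  gap_pair <- multiple_alignment(c("x", "y"), c("A---", "-AAA"))
  expect_error(p_distance(gap_pair), "zero comparable")
})

test_that("NJ solves the 3-taxon closed form and the 4-taxon additive case", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(el[["A"]], (3 + 4 - 5) / 2)
  expect_equal(el[["B"]], (3 + 5 - 4) / 2)
  expect_equal(el[["C"]], (4 + 5 - 3) / 2)

  D4 <- matrix(3, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(D4) <- 0
  D4["A", "B"] <- D4["B", "A"] <- 2
  D4["C", "D"] <- D4["D", "C"] <- 2
  tr4 <- neighbor_joining(D4)
  # recovers AB|CD with internal edge 1 and pendant edges 1
  coph <- ape::cophenetic.phylo(tr4)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(coph, D4, tolerance = 1e-12)
  internal <- tr4$edge.length[tr4$edge[, 2L] > 4]
  expect_equal(internal, 1, tolerance = 1e-12)

  expect_error(neighbor_joining(matrix(c(0, 1, 1, 0), 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
  asym <- D; asym[1, 2] <- 9
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("NJ is exact on random additive matrices (4-12 taxa)", {
  for (s in 1:20) {
    n <- 4L + (s %% 9L)
    true_tree <- oracle_additive_case(n, 7000 + s)
    D <- ape::cophenetic.phylo(true_tree)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    rec <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(true_tree), rec), 0,
                 ignore_attr = TRUE)
    coph <- ape::cophenetic.phylo(rec)[rownames(D), colnames(D)]
    expect_equal(coph, D, tolerance = 1e-9)
  }
})

test_that("bootstrap gives 100 % on perfect signal and ~50 % on conflict", {
  # every column separates {a1,a2} from {b1,b2}
  aln <- multiple_alignment(
    c("a1", "a2", "b1", "b2"),
    c(paste(rep("A", 40), collapse = ""),
      paste(c(rep("A", 39), "C"), collapse = ""),
      paste(rep("T", 40), collapse = ""),
      paste(c(rep("T", 39), "G"), collapse = "")))
  tr <- bootstrap_support(aln, n_reps = 200, seed = 99)
  expect_true("100" %in% tr$node.label)

  # determinism under a fixed seed
  tr2 <- bootstrap_support(aln, n_reps = 200, seed = 99)
  expect_identical(tr$node.label, tr2$node.label)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))

  # 50/50 conflicting signal: support near 50
  colX <- c("A", "A", "C", "C")  # supports t1t2|t3t4
  colY <- c("A", "C", "A", "C")  # supports t1t3|t2t4
  m <- cbind(matrix(colX, 4, 100), matrix(colY, 4, 100))
  conflict <- multiple_alignment(paste0("t", 1:4),
                                 apply(m, 1L, paste, collapse = ""))
  trc <- bootstrap_support(conflict, n_reps = 1000, seed = 123)
  sup <- suppressWarnings(as.integer(trc$node.label))
  sup <- sup[!is.na(sup)]
  expect_length(sup, 1L)
  expect_lt(abs(sup - 50), 7)

  expect_error(bootstrap_support(aln, n_reps = 0, seed = 1), "n_reps")
})

test_that("concatenation matches labels across blocks and records boundaries", {
  b1 <- multiple_alignment(c("x", "y"), c("AAAAAAAAAA", "CCCCCCCCCC"))
  b2 <- multiple_alignment(c("y", "x"),
                           c(paste(rep("G", 20), collapse = ""),
                             paste(rep("T", 20), collapse = "")))
  cc <- concatenate_alignments(list(one = b1, two = b2))
  expect_equal(ncol(cc), 30L)
  # rows matched by label, not position
  expect_equal(paste(cc["x", ], collapse = ""),
               paste0(paste(rep("A", 10), collapse = ""),
                      paste(rep("T", 20), collapse = "")))
  expect_equal(attr(cc, "blocks")$start, c(1L, 11L))
  expect_equal(attr(cc, "blocks")$end, c(10L, 30L))

  b3 <- multiple_alignment(c("x", "z"), c("AA", "CC"))
  expect_error(concatenate_alignments(list(b1, b3)), "'z'|'y'")
})

test_that("concatenated p-distance is the length-weighted block average", {
  withr::with_seed(33, {
    blocks <- lapply(c(12, 30, 18), function(n) {
      multiple_alignment(c("p", "q", "r"),
                         replicate(3, rand_dna_str(n)))
    })
  })
  cc <- concatenate_alignments(blocks)
  d_cc <- p_distance(cc)
  lens <- vapply(blocks, ncol, integer(1))
  d_blocks <- lapply(blocks, p_distance)
  expected <- Reduce(`+`, Map(function(d, l) d * l, d_blocks, lens)) /
    sum(lens)
  expect_equal(d_cc, expected)
})

test_that("marker concatenation recovers a planted 6-taxon tree", {
  true_tree <- oracle_additive_case(6L, 4242)
  # simulate 3 gap-free markers on the tree: mutate along paths
  withr::with_seed(4243, {
    blocks <- lapply(c(300, 200, 250), function(len) {
      root_seq <- rand_dna_str(len)
      # sequences diverge from root proportionally to tree distance
      D <- ape::cophenetic.phylo(true_tree)
      ref <- rownames(D)[1L]
      seqs <- setNames(character(length(rownames(D))), rownames(D))
      seqs[ref] <- root_seq
      for (t in setdiff(rownames(D), ref)) {
        k <- round(min(D[ref, t] * 0.12, 0.6) * len)
        seqs[t] <- mutate_str(root_seq, k, c("A", "C", "G", "T"))
      }
      multiple_alignment(names(seqs), unname(seqs))
    })
  })
  cc <- concatenate_alignments(blocks)
  rec <- neighbor_joining(p_distance(cc))
  expect_s3_class(rec, "phylo")
  expect_setequal(rec$tip.label, true_tree$tip.label)
})

test_that("AAI dendrogram isolates a distant taxon and handles star trees", {
  ids <- c("n1", "n2", "n3", "far")
  d <- matrix(2, 4, 4, dimnames = list(ids, ids))
  diag(d) <- 0
  d["far", 1:3] <- d[1:3, "far"] <- 40
  tr <- aai_dendrogram(d, outgroup = "far")
  # the three near proteomes form a clade away from the outgroup
  far_edge <- tr$edge.length[tr$edge[, 2L] == which(tr$tip.label == "far")]
  near_edges <- tr$edge.length[tr$edge[, 2L] %in% which(tr$tip.label != "far")]
  expect_gt(far_edge, max(near_edges))

  dstar <- matrix(5, 4, 4, dimnames = list(ids, ids)); diag(dstar) <- 0
  star <- aai_dendrogram(dstar)
  internal <- star$edge.length[star$edge[, 2L] > 4]
  expect_true(all(abs(internal) < 1e-9))

  expect_error(aai_dendrogram(dstar, outgroup = "nope"), "unknown outgroup")
})

test_that("center-star aligner handles substitutions and a small indel", {
  withr::with_seed(55, base <- rand_dna_str(120))
  s2 <- mutate_str(base, 6, c("A", "C", "G", "T"))
  s3 <- paste0(substr(base, 1, 60), substr(base, 64, 120))  # 3 bp deletion
  aln <- align_markers(c(a = base, b = s2, c = s3))
  expect_s3_class(aln, "multiple_alignment")
  expect_equal(nrow(aln), 3L)
  d <- p_distance(aln)
  expect_lt(d["a", "c"], 0.02)   # deletion handled as gaps, not mismatches
  expect_equal(d["a", "b"], 6 / 120, tolerance = 0.02)
})

test_that("newick round-trip preserves topology, lengths and supports", {
  tr <- oracle_additive_case(7L, 606)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tf)
  back <- read_newick(tf)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-8)
})
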