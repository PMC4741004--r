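aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

toy_proteome <- function(prefix, seqs) {
  out <- lapply(seq_along(seqs), function(i) {
    make_protein_record(paste0(prefix, i), seqs[i], genome_id = prefix)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

test_that("filtered_hits applies 30/70 thresholds on the longer protein", {
  withr::with_seed(31, p <- toy_proteome("p", replicate(4, rand_protein_str(80))))
  self <- filtered_hits(p, p)
  diag_hits <- self[self$query_id == self$subject_id, ]
  expect_equal(nrow(diag_hits), 4L)
  expect_true(all(diag_hits$identity_pct == 100))

  # engineered pair at ~25 % identity: absent at threshold 30
  withr::with_seed(32, {
    base <- rand_protein_str(100)
    far <- mutate_str(base, 75, aa20)
  })
  a <- toy_proteome("a", base); b <- toy_proteome("b", far)
  expect_equal(nrow(filtered_hits(a, b)), 0L)
  # same pair passes once the identity floor drops below its true identity
  expect_equal(nrow(filtered_hits(a, b, id_threshold_pct = 20)), 1L)

  # coverage on the longer protein: 60-residue fragment of a 120-residue
  # protein aligns at 100 % identity but 50 % coverage -> rejected
  long <- rand_protein_str(120)
  frag <- substr(long, 1, 60)
  expect_equal(nrow(filtered_hits(toy_proteome("l", long),
                                  toy_proteome("f", frag))), 0L)
  expect_equal(nrow(filtered_hits(toy_proteome("l", long),
                                  toy_proteome("f", frag),
                                  cov_threshold_pct = 40)), 1L)
})

test_that("RBH matches hand enumeration and excludes one-sided bests", {
  # 2x2 toy from identities: (p1,q1)=80, (p1,q2)=55, (p2,q2)=90, (p2,q1)=40
  hitsAB <- data.frame(
    query_id = c("p1", "p1", "p2", "p2"),
    subject_id = c("q1", "q2", "q2", "q1"),
    identity_pct = c(80, 55, 90, 40),
    coverage_longer_pct = 100, score = c(80, 55, 90, 40))
  hitsBA <- data.frame(
    query_id = c("q1", "q2", "q2", "q1"),
    subject_id = c("p1", "p1", "p2", "p2"),
    identity_pct = c(80, 55, 90, 40),
    coverage_longer_pct = 100, score = c(80, 55, 90, 40))
  rbh <- reciprocal_best_hits(hitsAB, hitsBA)
  expect_equal(rbh$protein_a, c("p1", "p2"))
  expect_equal(rbh$protein_b, c("q1", "q2"))
  expect_equal(rbh$identity_pct, c(80, 90))

  # one-sided: p -> q best, but q's best is p2
  one_ab <- data.frame(query_id = "p1", subject_id = "q1",
                       identity_pct = 70, coverage_longer_pct = 100,
                       score = 70)
  one_ba <- data.frame(query_id = "q1", subject_id = "p2",
                       identity_pct = 75, coverage_longer_pct = 100,
                       score = 75)
  expect_equal(nrow(reciprocal_best_hits(one_ab, one_ba)), 0L)
})

test_that("pipeline RBH/AAI equals the brute-force oracle on toy batteries", {
  seeds <- 500 + 1:8
  for (s in seeds) {
    withr::with_seed(s, {
      base <- replicate(10, rand_protein_str(40))
      # related copies with varying divergence plus two unrelated proteins
      other <- c(vapply(base[1:8], function(x)
        mutate_str(x, sample(2:12, 1L), aa20), character(1)),
        replicate(2, rand_protein_str(40)))
    })
    A <- toy_proteome(sprintf("s%da", s), base)
    B <- toy_proteome(sprintf("s%db", s), other)
    oracle <- oracle_rbh_aai(A, B)
    got <- compute_aai(A, B)
    expect_equal(got$n_rbh, nrow(oracle$rbh))
    expect_equal(got$rbh$protein_a, oracle$rbh$protein_a)
    expect_equal(got$rbh$protein_b, oracle$rbh$protein_b)
    expect_equal(got$aai_pct, oracle$aai)
  }
})

test_that("AAI is 100 for identical proteomes and tracks planted divergence", {
  withr::with_seed(61, p <- toy_proteome("x", replicate(5, rand_protein_str(60))))
  self <- compute_aai(p, p)
  expect_equal(self$aai_pct, 100)
  expect_equal(self$n_rbh, 5L)

  sim <- fix_pancore()  # protein divergence 0.05 per genome
  r <- compute_aai(sim$proteomes$g1, sim$proteomes$ancestor)
  expect_lt(abs(r$aai_pct - 95), 1)
})

test_that("gene families are single-linkage components incl. paralogs", {
  # hand-built: G1={a1,b1,c1}, G2={a2,b2,d2}, G3={a3,e3}; hits only within
  # letter groups -> 5 families, letter-a family spans 3 genomes
  withr::with_seed(71, {
    fam_seed <- lapply(letters[1:5], function(x) rand_protein_str(60))
    names(fam_seed) <- letters[1:5]
  })
  mk <- function(genome, letters_in) {
    seqs <- vapply(letters_in, function(l)
      mutate_str(fam_seed[[l]], 3, aa20), character(1))
    toy_proteome_named <- lapply(seq_along(letters_in), function(i) {
      make_protein_record(paste0(letters_in[i], genome), seqs[i],
                          genome_id = paste0("G", genome))
    })
    names(toy_proteome_named) <-
      vapply(toy_proteome_named, `[[`, character(1), "id")
    toy_proteome_named
  }
  withr::with_seed(72, proteomes <- list(
    G1 = mk(1, c("a", "b", "c")),
    G2 = mk(2, c("a", "b", "d")),
    G3 = mk(3, c("a", "e"))))
  fam <- build_gene_families(proteomes)
  expect_equal(length(unique(fam$family_id)), 5L)
  a_fam <- fam$family_id[fam$protein_id == "a1"]
  expect_setequal(fam$genome_id[fam$family_id == a_fam],
                  c("G1", "G2", "G3"))

  # pan/core on the toy, order G1,G2,G3
  curve <- pan_core_curve(fam, c("G1", "G2", "G3"))
  expect_equal(curve$pan, c(3L, 4L, 5L))
  expect_equal(curve$core, c(3L, 2L, 1L))

  # exclusive genes
  expect_equal(exclusive_genes(fam, "G2"), "d2")
  expect_error(exclusive_genes(fam, "G9"), "unknown")
  expect_error(pan_core_curve(fam, c("G1", "G2")), "exactly once")
})

test_that("single linkage chains a~b, b~c into one family", {
  # a and c are both within 30 %/70 % of b but not of each other
  withr::with_seed(81, b <- rand_protein_str(90))
  a <- mutate_str(b, 36, aa20)   # ~60 % identity to b
  c_ <- local({
    res <- mutate_str(b, 36, aa20)
    res
  })
  proteome <- list(p1 = make_protein_record("p1", a, "G"),
                   p2 = make_protein_record("p2", b, "G"),
                   p3 = make_protein_record("p3", c_, "G"))
  fam <- build_gene_families(list(G = proteome))
  expect_equal(length(unique(fam$family_id)), 1L)
})

test_that("pan/core truth recovery and monotonicity on a simulated set", {
  sim <- fix_pancore()
  proteomes <- sim$proteomes[names(sim$genomes)]
  fam <- build_gene_families(proteomes)
  presence <- sim$truth$family_presence

  truth_counts <- function(order) {
    idx <- match(order, colnames(presence))
    pan <- core <- integer(length(idx))
    for (k in seq_along(idx)) {
      sub <- presence[, idx[1:k], drop = FALSE]
      pan[k] <- sum(rowSums(sub) > 0L)
      core[k] <- sum(rowSums(sub) == k)
    }
    list(pan = pan, core = core)
  }

  withr::with_seed(91, orders <- c(
    list(colnames(presence)),
    lapply(1:20, function(i) sample(colnames(presence)))))
  finals <- vapply(orders, function(ord) {
    curve <- pan_core_curve(fam, ord)
    tr <- truth_counts(ord)
    expect_equal(curve$pan, tr$pan)
    expect_equal(curve$core, tr$core)
    expect_true(all(diff(curve$pan) >= 0L))
    expect_true(all(diff(curve$core) <= 0L))
    c(curve$core[length(ord)], curve$pan[length(ord)])
  }, numeric(2))
  # order-invariance of the endpoints
  expect_equal(length(unique(finals[1L, ])), 1L)
  expect_equal(length(unique(finals[2L, ])), 1L)
})

test_that("exclusive genes match planted accessory families", {
  sim <- fix_pancore()
  proteomes <- sim$proteomes[names(sim$genomes)]
  fam <- build_gene_families(proteomes)
  presence <- sim$truth$family_presence
  for (g in colnames(presence)) {
    own_only <- which(presence[, g] & rowSums(presence) == 1L)
    expected <- if (length(own_only)) paste0(g, "_fam", own_only) else
      character(0)
    expect_setequal(exclusive_genes(fam, g), expected)
  }
})
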