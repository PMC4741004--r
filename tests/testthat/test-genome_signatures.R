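test_that("GC content and skew handle degenerate inputs and match oracles", {
  expect_equal(gc_profile(make_genome_record("g", "GGCC"), 4L)$value, 1)
  expect_equal(gc_profile(make_genome_record("g", "AATT"), 4L)$value, 0)
  expect_equal(gc_skew_profile(make_genome_record("g", "GGGG"), 4L)$value, 1)
  expect_equal(gc_skew_profile(make_genome_record("g", "CCCC"), 4L)$value, -1)

  sk <- gc_skew_profile(make_genome_record("g", "AATTAATT"), 4L)
  expect_equal(sk$value, c(0, 0))
  expect_true(all(sk$degenerate))

  # N excluded from GC statistics
  expect_equal(gc_profile(make_genome_record("g", "GCNN"), 4L)$value, 1)

  withr::with_seed(12, g <- make_genome_record("g", rand_dna_str(25000, 0.6)))
  for (w in c(1000L, 2500L)) {
    expect_equal(gc_profile(g, w)$value,
                 oracle_gc_windows(g$sequence, w, w, "gc"))
    expect_equal(gc_skew_profile(g, w)$value,
                 oracle_gc_windows(g$sequence, w, w, "skew"))
  }
  # overlapping windows
  expect_equal(gc_profile(g, 2000L, 500L)$value,
               oracle_gc_windows(g$sequence, 2000L, 500L, "gc"))

  expect_warning(p <- gc_profile(make_genome_record("g", "ACGT"), 10L),
                 "single whole-genome window")
  expect_equal(nrow(p), 1L)
})

test_that("delta* is zero for a self-window and strand-invariant", {
  withr::with_seed(13, g <- make_genome_record("g", rand_dna_str(20000, 0.66)))
  scan <- dinucleotide_bias_scan(g, window = nchar(g$sequence))
  expect_equal(scan$profile$delta_star, 0, tolerance = 1e-12)

  rc <- make_genome_record("rc", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(g$sequence))))
  s1 <- dinucleotide_bias_scan(g, 5000L)
  s2 <- dinucleotide_bias_scan(rc, 5000L)
  # both-strand counting: the window deltas are the same set, reversed
  expect_equal(s1$profile$delta_star, rev(s2$profile$delta_star),
               tolerance = 1e-12)
})

test_that("island scan flags a planted composition shift but not null data", {
  sim <- simulate_genome_set(genome_sim_params(
    n_genomes = 1L, genome_len = 200000L, n_core = 5L, n_accessory = 0L,
    nucleotide_divergence = 0.01,
    island_specs = list(list(length = 20000L, repeat_prob = 0.4)),
    seed = 77L))
  island <- sim$truth$islands[[1L]]
  scan <- dinucleotide_bias_scan(sim$genomes$g1, 10000L)
  expect_gt(nrow(scan$anomalies), 0L)
  top <- scan$anomalies[which.max(scan$anomalies$delta_star), ]
  expect_lt(top$start, island[["end"]])
  expect_gt(top$end, island[["start"]])

  null <- simulate_genome_set(genome_sim_params(
    n_genomes = 1L, genome_len = 200000L, n_core = 5L, n_accessory = 0L,
    nucleotide_divergence = 0, plant_oric = FALSE, seed = 78L))
  expect_equal(nrow(dinucleotide_bias_scan(null$genomes$g1, 10000L)$anomalies),
               0L)
})

test_that("oriC prediction recovers planted boxes and DUE via hemE anchor", {
  sim <- fix_smallset()
  truth <- sim$truth$oric
  g <- sim$genomes$g1
  hemE <- sim$proteomes$g1$g1_fam1
  orfs <- data.frame(start = truth$hemE[["start"]], end = truth$hemE[["end"]],
                     strand = "+", protein = hemE$sequence)
  pred <- find_oric(g, hemE, orf_set = orfs)
  expect_equal(pred$boxes$position, as.integer(truth$box_positions))
  expect_true(all(pred$boxes$mismatches == 0L))
  expect_true(all(pred$boxes$strand == "+"))
  # DUE: threshold-crossing boundaries are fuzzy within one due_window
  expect_lt(pred$due$start, truth$due[["end"]])
  expect_gt(pred$due$end, truth$due[["start"]])
  expect_lte(abs(pred$due$start - truth$due[["start"]]), 50L)
  expect_lte(abs(pred$due$end - truth$due[["end"]]), 50L)
  # the merged run spans threshold-crossing boundary windows, so its overall
  # AT fraction can sit marginally below the per-window floor
  expect_gte(pred$due$at_fraction, 0.65)
  # everything inside the intergenic interval
  expect_true(all(pred$boxes$position >= pred$intergenic_start))
  expect_true(all(pred$boxes$position + 9L <= pred$intergenic_end))

  # six-frame fallback locates hemE on the ancestor (no substitutions there)
  pred6 <- find_oric(sim$ancestor, sim$proteomes$ancestor$ancestor_fam1)
  expect_equal(pred6$boxes$position, as.integer(truth$box_positions))
})

test_that("box mismatch tolerance is a strict threshold", {
  sim <- fix_smallset()
  truth <- sim$truth$oric
  g <- sim$genomes$g1
  # mutate one planted box by one base
  seq <- g$sequence
  pos <- truth$box_positions[3L] + 1L  # 1-based start of box 3
  ch <- substr(seq, pos, pos)
  substr(seq, pos, pos) <- if (ch == "T") "G" else "T"
  g_mut <- make_genome_record("gm", seq)
  orfs <- data.frame(start = truth$hemE[["start"]], end = truth$hemE[["end"]],
                     strand = "+", protein = sim$proteomes$g1$g1_fam1$sequence)
  found1 <- find_oric(g_mut, sim$proteomes$g1$g1_fam1, orf_set = orfs,
                      max_mismatches = 1L)
  found0 <- find_oric(g_mut, sim$proteomes$g1$g1_fam1, orf_set = orfs,
                      max_mismatches = 0L)
  expect_true(truth$box_positions[3L] %in% found1$boxes$position)
  expect_false(truth$box_positions[3L] %in% found0$boxes$position)
  expect_equal(nrow(found0$boxes), 4L)

  # no hemE homolog -> error
  withr::with_seed(14, null_g <- make_genome_record("n", rand_dna_str(30000)))
  expect_error(find_oric(null_g, sim$proteomes$g1$g1_fam1),
               "no hemE homolog|no ORFs")
})
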