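# Shared, lazily built simulation fixtures (seeds fixed a priori).
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small genome set with all feature types planted
fix_smallset <- function() fixture("smallset", function() {
  simulate_genome_set(genome_sim_params(
    n_genomes = 3L, genome_len = 40000L, n_core = 8L, n_accessory = 4L,
    nucleotide_divergence = c(0.01, 0.03, 0.05),
    protein_divergence = 0.05,
    rpsl_variants = c("KK", "KR", "RR"),
    seed = 2016L))
})

# pan/core set: 4 genomes, known family presence
fix_pancore <- function() fixture("pancore", function() {
  simulate_genome_set(genome_sim_params(
    n_genomes = 4L, genome_len = 30000L, n_core = 10L, n_accessory = 8L,
    nucleotide_divergence = 0.02, protein_divergence = 0.05,
    plant_oric = FALSE, seed = 2017L))
})
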