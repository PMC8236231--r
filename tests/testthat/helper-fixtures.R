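# Shared fixtures. The study-scale synthetic run is expensive, so it is
# computed once per session and reused by every test that needs it.

.fixture_cache <- new.env(parent = emptyenv())

# small genome: quick to simulate, used by unit tests
small_sim_config <- function(seed = 11) {
  sim_config(
    seed = seed, n_chromosomes = 4, genes_per_chromosome = 160,
    family_sizes = c(A1 = 3, A4 = 3, A6 = 4),
    n_tandem_arrays = 1, n_segmental_blocks = 1, block_anchor_count = 5,
    decoy_fraction = 0.3, n_refs_per_subgroup = 2)
}

small_sim <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- simulate_genome(small_sim_config())
  }
  .fixture_cache$small
}

# study-scale run: default generator conditions, bootstrap trimmed to 200
# replicates (supports are not part of the recovery checks)
default_report <- function() {
  if (is.null(.fixture_cache$report)) {
    cfg <- genefam_config(simulate = sim_config(seed = 101),
                          replicates = 200, seed = 101)
    .fixture_cache$report <- suppressMessages(run_all(cfg))
  }
  .fixture_cache$report
}

pair_keys <- function(d) paste(d$id_a, d$id_b)

# minimal bundle carrying only gene rank geometry, for collinearity tests
rank_bundle <- function(genome_id, genes) {
  structure(list(genome_id = genome_id,
                 chromosomes = setNames(rep(1e6, length(unique(genes$chromosome))),
                                        unique(genes$chromosome)),
                 genes = genes, proteins = character(0)),
            class = "genome_bundle")
}

random_peptide <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}
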