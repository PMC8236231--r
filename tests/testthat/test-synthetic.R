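test_that("simulation is deterministic given the seed", {
  cfg <- small_sim_config(seed = 21)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$bundle$genes, b$bundle$genes)
  expect_identical(a$bundle$chrom_seqs, b$bundle$chrom_seqs)
  expect_identical(a$truth$family_members, b$truth$family_members)
  expect_identical(a$reference_panel, b$reference_panel)
})

test_that("no tandem arrays requested means no tandem truth", {
  cfg <- sim_config(seed = 31, n_chromosomes = 2, genes_per_chromosome = 120,
                    family_sizes = c(A1 = 2, A4 = 2), n_tandem_arrays = 0,
                    n_segmental_blocks = 0, decoy_fraction = 0)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth$tandem_pairs), 0)
  expect_equal(nrow(sim$truth$segmental_pairs), 0)
})

test_that("planted truth is consistent with the emitted gene ranks", {
  sim <- small_sim()
  genes <- sim$bundle$genes
  tp <- sim$truth$tandem_pairs
  for (i in seq_len(nrow(tp))) {
    ra <- genes$rank[genes$gene_id == tp$id_a[i]]
    rb <- genes$rank[genes$gene_id == tp$id_b[i]]
    expect_equal(abs(ra - rb) - 1L, tp$intervening[i])
  }
})

test_that("planted members pass the V14 check and decoys fail it", {
  sim <- small_sim()
  prof <- build_profile(sim$seed_alignment)
  fam <- sim$truth$family_members
  for (gid in fam$gene_id) {
    h <- scan_domain(sim$bundle$proteins[[gid]], prof, protein_id = gid)
    expect_equal(nrow(h), 1)
    expect_equal(h$residue14, "V")
    expect_equal(h$residue19 == "E",
                 fam$v_and_e[fam$gene_id == gid])
  }
  for (gid in sim$truth$v14_negative_decoys) {
    h <- scan_domain(sim$bundle$proteins[[gid]], prof, protein_id = gid)
    expect_true(nrow(h) == 0 || h$residue14[1] != "V")
  }
  for (gid in sim$truth$two_domain_decoys) {
    h <- scan_domain(sim$bundle$proteins[[gid]], prof, protein_id = gid)
    expect_gte(nrow(h), 2)
  }
})

test_that("bundle invariants hold for generated genomes", {
  sim <- small_sim()
  expect_silent(validate_bundle(sim$bundle))
})

test_that("intron phases planted in the GFF match structural recomputation", {
  sim <- small_sim()
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$bundle$genes, f, chrom_lengths = sim$bundle$chromosomes)
  gs <- gene_structure(read_gff3(f))
  m <- dplyr::inner_join(gs, sim$truth$intron_truth, by = "gene_id")
  expect_equal(nrow(m), nrow(sim$bundle$genes))
  expect_equal(m$phases.x, m$phases.y)
  expect_equal(m$n_exons.x, m$n_exons.y)
})

test_that("evolve_codon_pair hits its Ks target and keeps sequences sane", {
  anc <- paste(rep(c("GCT", "AAA", "GAA", "TTC", "GGT", "CAT", "ATT", "CTG",
                     "ATG", "CCA"), 30), collapse = "")
  expect_identical(evolve_codon_pair(anc, 0, 0.2, seed = 1)$cds_a, anc)
  expect_error(evolve_codon_pair(anc, 3.5, 0.2, seed = 1), "smaller Ks")

  est <- vapply(1:10, function(s) {
    pr <- evolve_codon_pair(anc, 0.2, 0.2, seed = s)
    ng86(pr$cds_a, pr$cds_b)$ks
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.2) / 0.2, 0.3)

  # stop codons are never introduced
  for (s in 1:100) {
    pr <- evolve_codon_pair(anc, 0.8, 0.5, seed = s)
    expect_no_error(translate_cds(paste0(pr$cds_a, "TAA")))
    expect_no_error(translate_cds(paste0(pr$cds_b, "TAA")))
  }
})

test_that("plant_motif writes the consensus and respects bounds", {
  p <- random_peptide(60)
  out <- plant_motif(p, "WQDFLNEST", 10, noise = 0)
  expect_equal(substr(out, 11, 19), "WQDFLNEST")
  expect_equal(substr(out, 1, 10), substr(p, 1, 10))
  expect_error(plant_motif(p, "WQDFLNEST", 58), "out of bounds")
  expect_error(plant_motif(p, "WQDFLNEST", 5, noise = 1), "noise")
})

test_that("the ortholog genome shares exactly the planted collinear runs", {
  sim <- small_sim()
  ort <- simulate_ortholog_genome(sim, seed = 77, n_blocks = 2,
                                  anchors_per_block = 6, n_chromosomes = 2,
                                  genes_per_chromosome = 60)
  expect_silent(validate_bundle(ort$bundle))
  pab <- find_homolog_pairs(sim$bundle, ort$bundle)
  bl <- detect_collinear(sim$bundle, ort$bundle, pairs = pab)
  fam <- sim$truth$family_members$gene_id
  expect_equal(ortholog_counts(bl, fam),
               length(ort$truth$family_orthologs))
})
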