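test_that("intron phases follow cumulative coding length in transcription order", {
  single <- tibble::tibble(gene_id = "g1", strand = "+",
                           exons = list(matrix(c(0L, 300L), 1)))
  gs <- gene_structure(single)
  expect_equal(gs$n_introns, 0L)
  expect_equal(gs$intron_phases[[1]], integer(0))

  # 100 coding bases before the intron -> phase 1
  two <- tibble::tibble(gene_id = "g2", strand = "+",
                        exons = list(matrix(c(0L, 100L, 200L, 300L), 2,
                                            byrow = TRUE)))
  expect_equal(gene_structure(two)$intron_phases[[1]], 1L)

  # minus strand: transcription-first exon is the genomically last one
  # (length 5), so the single intron has phase 5 mod 3 = 2
  minus <- tibble::tibble(gene_id = "g3", strand = "-",
                          exons = list(matrix(c(0L, 7L, 100L, 105L), 2,
                                              byrow = TRUE)))
  expect_equal(gene_structure(minus)$intron_phases[[1]], 2L)
})

test_that("ZOOPS EM recovers an exactly planted motif from background", {
  withr::with_seed(41, {
    motif <- "HQWKDYFLE"
    seqs <- setNames(vapply(1:20, function(i) {
      s <- random_peptide(80)
      plant_motif(s, motif, sample(0:(80 - 9), 1), noise = 0)
    }, character(1)), paste0("s", 1:20))
  })
  mots <- discover_motifs(seqs, widths = c(6, 9, 12), max_motifs = 1,
                          seed = 2)
  expect_equal(length(mots), 1)
  expect_equal(mots[[1]]$consensus, motif)
  expect_equal(mots[[1]]$width, 9)
  # pure background never reaches the llr of the planted motif
  withr::with_seed(43, {
    null_llr <- vapply(1:5, function(k) {
      bg <- setNames(vapply(1:20, function(i) random_peptide(80),
                            character(1)), paste0("n", 1:20))
      m0 <- discover_motifs(bg, widths = c(6, 9, 12), max_motifs = 1,
                            seed = k, llr_floor = -Inf)
      if (length(m0) == 0) 0 else m0[[1]]$llr
    }, numeric(1))
  })
  expect_true(all(null_llr < mots[[1]]$llr))
})

test_that("the EM objective is non-decreasing within a fit", {
  withr::with_seed(47, {
    seqs <- setNames(vapply(1:12, function(i) {
      plant_motif(random_peptide(60), "WQDFLN", sample(0:54, 1), noise = 0.1)
    }, character(1)), paste0("s", 1:12))
  })
  mots <- discover_motifs(seqs, widths = 6, max_motifs = 1, seed = 1)
  expect_gte(length(mots), 1)
  tr <- mots[[1]]$ll_trace
  expect_true(all(diff(tr) > -1e-6))
})

test_that("ZOOPS allows at most one occurrence per sequence", {
  withr::with_seed(53, {
    seqs <- setNames(vapply(1:15, function(i) {
      s <- random_peptide(90)
      s <- plant_motif(s, "HQWKDYFLE", 5, noise = 0)
      plant_motif(s, "HQWKDYFLE", 60, noise = 0)   # two copies planted
    }, character(1)), paste0("s", 1:15))
  })
  mots <- discover_motifs(seqs, widths = 9, max_motifs = 2, seed = 3)
  occ <- dplyr::bind_rows(lapply(mots, function(m) m$sites))
  dup <- occ |> dplyr::count(motif_id, protein_id) |> dplyr::filter(n > 1)
  expect_equal(nrow(dup), 0)
})

test_that("max_motifs = 0 yields an empty result", {
  expect_equal(discover_motifs(c(a = "MKVLLE", b = "MKVLLE"),
                               max_motifs = 0, seed = 1), list())
})

test_that("scan_motif reports the best window once, or nothing", {
  withr::with_seed(59, {
    seqs <- setNames(vapply(1:15, function(i) {
      plant_motif(random_peptide(70), "HQWKDYFLE", sample(0:61, 1), noise = 0)
    }, character(1)), paste0("s", 1:15))
  })
  mots <- discover_motifs(seqs, widths = 9, max_motifs = 1, seed = 4)
  m <- mots[[1]]
  hit <- scan_motif(paste0(random_peptide(20), m$consensus,
                           random_peptide(10)), m, protein_id = "x")
  expect_equal(hit$offset, 20L)
  expect_equal(nrow(scan_motif(random_peptide(5), m)), 0)   # shorter than w
  # planted sites are found back with high recall
  found <- vapply(names(seqs), function(id) {
    nrow(scan_motif(seqs[[id]], m, protein_id = id)) == 1
  }, logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("presence matrix is binary, deterministic and complete", {
  fake <- list(structure(list(motif_id = "motif_1"), class = "motif_model"),
               structure(list(motif_id = "motif_2"), class = "motif_model"))
  occ0 <- tibble::tibble(motif_id = character(), protein_id = character(),
                         offset = integer(), site_score = numeric())
  pm0 <- presence_matrix(c("g2", "g1"), fake, occ0)
  expect_equal(rownames(pm0), c("g1", "g2"))
  expect_true(all(pm0 == 0))
  occ1 <- tibble::tibble(motif_id = "motif_2", protein_id = "g1",
                         offset = 0L, site_score = 5)
  pm1 <- presence_matrix(c("g1", "g2"), fake, occ1)
  expect_equal(sum(pm1), 1L)
  expect_equal(pm1["g1", "motif_2"], 1L)
})

test_that("a subgroup-specific planted motif appears only in that subgroup", {
  rep <- default_report()
  sim <- rep$sim
  spec <- sim$truth$motif_sites
  fam <- sim$truth$family_members
  # M2 is planted in subgroup A1 only
  m2_cons <- unique(spec$consensus[spec$motif == "M2"])
  hit <- vapply(rep$motifs, function(m) m$consensus == m2_cons, logical(1))
  expect_true(any(hit))
  m2 <- rep$motifs[[which(hit)[1]]]
  occ <- rep$motif_occurrences |> dplyr::filter(motif_id == m2$motif_id)
  carriers <- fam$subgroup[match(occ$protein_id, fam$gene_id)]
  expect_true(all(carriers == "A1"))
  expect_setequal(occ$protein_id, fam$gene_id[fam$subgroup == "A1"])
})
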