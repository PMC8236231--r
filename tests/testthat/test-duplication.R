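test_that("the tandem rule counts intervening loci as rank difference minus one", {
  genes <- tibble::tibble(
    gene_id = c("f1", "f2", "f3", "f4", "g5"),
    chromosome = c("c1", "c1", "c1", "c1", "c2"),
    rank = c(7L, 8L, 10L, 16L, 0L))
  t1 <- detect_tandem(c("f1", "f2"), genes)
  expect_equal(t1$intervening, 0L)
  t2 <- detect_tandem(c("f3", "f4"), genes)   # ranks 10 and 16 -> 5 loci
  expect_equal(nrow(t2), 1)
  expect_equal(t2$intervening, 5L)
  genes$rank[genes$gene_id == "f4"] <- 17L    # 6 intervening -> not tandem
  expect_equal(nrow(detect_tandem(c("f3", "f4"), genes)), 0)
  # different chromosomes never pair
  expect_equal(nrow(detect_tandem(c("f1", "g5"), genes)), 0)
})

test_that("collinear chaining respects monotonicity, gaps and minimum anchors", {
  mk_genes <- function(chrom, ids, ranks) {
    tibble::tibble(gene_id = ids, chromosome = chrom, rank = ranks)
  }
  ga <- mk_genes("a1", paste0("A", 1:10), 0:9)
  gb <- mk_genes("b1", paste0("B", 1:10), 0:9)
  ba <- rank_bundle("GA", ga)
  bb <- rank_bundle("GB", gb)
  pairs <- tibble::tibble(id_a = paste0("A", 1:6), id_b = paste0("B", 1:6),
                          bitscore = 100, evalue = 0)
  bl <- detect_collinear(ba, bb, pairs = pairs, min_anchors = 5, max_gap = 25)
  expect_equal(length(unique(bl$block_id)), 1)
  expect_equal(nrow(bl), 6)
  expect_equal(unique(bl$orientation), "same")

  # inverted block
  inv <- tibble::tibble(id_a = paste0("A", 1:6), id_b = paste0("B", 6:1),
                        bitscore = 100, evalue = 0)
  bli <- detect_collinear(ba, bb, pairs = inv, min_anchors = 5, max_gap = 25)
  expect_equal(unique(bli$orientation), "inverted")
  expect_equal(nrow(bli), 6)

  # anchors scattered beyond max_gap never chain
  ga2 <- mk_genes("a1", paste0("A", 1:6), seq(0L, 150L, 30L))
  far <- detect_collinear(rank_bundle("GA", ga2), bb, pairs = pairs,
                          min_anchors = 5, max_gap = 25)
  expect_equal(nrow(far), 0)

  # fewer than min_anchors -> nothing
  few <- detect_collinear(ba, bb, pairs = pairs[1:4, ], min_anchors = 5)
  expect_equal(nrow(few), 0)
})

test_that("tandem takes priority over segmental in classification", {
  tandem <- tibble::tibble(id_a = "f1", id_b = "f2", chromosome = "c1",
                           intervening = 0L)
  blocks <- tibble::tibble(block_id = "block_1", genome_a = "G", genome_b = "G",
                           chr_a = "c1", chr_b = "c2", orientation = "same",
                           id_a = c("f1", "f3"), id_b = c("f2", "f4"),
                           rank_a = c(1L, 2L), rank_b = c(5L, 6L))
  cls <- classify_duplicates(c("f1", "f2", "f3", "f4"), tandem, blocks)
  expect_equal(cls$dup_type[cls$id_a == "f1"], "tandem")
  expect_equal(cls$dup_type[cls$id_a == "f3"], "segmental")
  expect_equal(nrow(cls), 2)
})

test_that("codon alignment expands residues to codons and gaps to ---", {
  ca <- codon_align("MK", "MK", "ATGAAA", "ATGAAG")
  expect_equal(ca$codon_a, "ATGAAA")
  expect_equal(ca$codon_b, "ATGAAG")
  # protein gap -> gap codon; terminal stop stripped
  cb <- codon_align("MK-", "MKV", "ATGAAATAA", "ATGAAAGTT")
  expect_equal(cb$codon_a, "ATGAAA---")
  expect_equal(cb$codon_b, "ATGAAAGTT")
  expect_error(codon_align("MKV", "MK-", "ATGAAA", "ATGAAA"),
               "does not match CDS for a")
})

test_that("NG86 reproduces the fourfold-degenerate worked example", {
  r <- ng86("GTTGTT", "GTAGTT")
  expect_equal(r$S, 2)
  expect_equal(r$N, 4)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$ks, 3 / 4 * log(3), tolerance = 1e-12)
  expect_equal(r$ka, 0)
  ident <- ng86("ATGAAA", "ATGAAA")
  expect_equal(ident$ka, 0)
  expect_equal(ident$ks, 0)
  expect_true(is.na(ident$omega))
})

test_that("NG86 is symmetric and conserves sites", {
  withr::with_seed(61, {
    cods <- c("GCT", "AAA", "GAA", "TTC", "GGT", "CAT", "ATT", "CTG", "ATG",
              "CCA", "TCA", "ACG", "GTT", "TGG", "TAC")
    for (i in 1:10) {
      a <- paste(sample(cods, 30, replace = TRUE), collapse = "")
      pr <- evolve_codon_pair(a, 0.4, 0.5, seed = i)
      r1 <- ng86(pr$cds_a, pr$cds_b)
      r2 <- ng86(pr$cds_b, pr$cds_a)
      expect_equal(r1$ka, r2$ka, tolerance = 1e-12)
      expect_equal(r1$ks, r2$ks, tolerance = 1e-12)
      expect_equal(r1$S + r1$N, 3 * r1$n_codons, tolerance = 1e-9)
    }
  })
})

test_that("NG86 matches the brute-force pathway oracle on random alignments", {
  withr::with_seed(67, {
    sense <- setdiff(names(Biostrings::GENETIC_CODE),
                     c("TAA", "TAG", "TGA"))
    for (i in 1:25) {
      a <- paste(sample(sense, 12, replace = TRUE), collapse = "")
      b <- paste(sample(sense, 12, replace = TRUE), collapse = "")
      o <- tryCatch(oracle_ng86(a, b), error = function(e) NULL)
      r <- tryCatch(ng86(a, b), error = function(e) NULL)
      # saturated draws are undefined for both routes alike
      expect_equal(is.null(o), is.null(r))
      if (is.null(o) || is.null(r)) next
      expect_equal(r$ka, unname(o["ka"]), tolerance = 1e-9)
      expect_equal(r$ks, unname(o["ks"]), tolerance = 1e-9)
      expect_equal(r$S, unname(o["S"]), tolerance = 1e-9)
      expect_equal(r$Sd, unname(o["Sd"]), tolerance = 1e-9)
    }
  })
})

test_that("saturated proportions raise the Jukes-Cantor error", {
  expect_error(ng86("GTTGTAGTCGTG", "GTAGTCGTGGTT"), "3/4")
})

test_that("divergence time is the linear clock formula in MYA", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.1312), 10)
  ks <- seq(0.05, 1, 0.05)
  expect_true(all(diff(divergence_time(ks)) > 0))
  expect_error(divergence_time(-0.1), "negative")
})

test_that("dated duplicate pairs recover targets within simulation noise", {
  sim <- small_sim()
  b <- sim$bundle
  fam <- sort(sim$truth$family_members$gene_id)
  tandem <- detect_tandem(fam, b$genes)
  blocks <- detect_collinear(b, pairs = find_homolog_pairs(b))
  cls <- classify_duplicates(fam, tandem, blocks)
  expect_setequal(pair_keys(cls),
                  c(pair_keys(sim$truth$tandem_pairs),
                    pair_keys(sim$truth$segmental_pairs)))
  dated <- date_duplicates(cls, b)
  expect_true(all(dated$ks >= 0))
  expect_true(all(dated$t_mya == divergence_time(dated$ks)))
  m <- dplyr::inner_join(dated, sim$truth$pair_targets,
                         by = c("id_a", "id_b"))
  expect_equal(nrow(m), nrow(dated))
  # purifying simulations: omega clearly below 1
  expect_lt(stats::median(m$omega), 1)
})

test_that("ortholog counting counts distinct family genes in anchors", {
  expect_equal(ortholog_counts(tibble::tibble(id_a = character()), "f1"), 0)
  bl <- tibble::tibble(id_a = c("f1", "f2", "f1", "x9"),
                       id_b = c("o1", "o2", "o3", "o4"))
  expect_equal(ortholog_counts(bl, c("f1", "f2", "f3")), 2)
})
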