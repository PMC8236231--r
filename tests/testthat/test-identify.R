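test_that("profile log-odds follow the pseudocounted formula", {
  # unanimous column: with pseudocount -> 0 the score tends to log2(1/bg)
  aln <- c(a = "VAV", b = "VCV", c = "VAV", d = "VDV")
  prof <- build_profile(aln, pseudocount = 1e-9)
  bg <- prof$background[["V"]]
  expect_equal(unname(prof$log_odds[1, "V"]), unname(log2(1 / bg)),
               tolerance = 1e-6)
  # consensus residue scores highest in every column for identical input
  same <- build_profile(c(x = "MKV", y = "MKV", z = "MKV"))
  expect_equal(profile_consensus(same), "MKV")
  expect_error(build_profile(c(only = "MKV")), "at least 2")
})

test_that("gap-dominated columns are dropped with a warning", {
  aln <- c(a = "M-KV", b = "M-RV", c = "MW-V")
  expect_warning(prof <- build_profile(aln), "gap-dominated")
  expect_equal(prof$n_columns, 3)
  expect_equal(prof$kept_columns, c(1, 3, 4))
})

test_that("scanning finds a gap-free self-match over the consensus", {
  prof <- build_profile(read_fasta(ap2_seed_alignment_path()))
  cons <- profile_consensus(prof)
  protein <- paste0(random_peptide(25), cons, random_peptide(30))
  h <- scan_domain(protein, prof)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 25)
  expect_equal(h$end, 25 + nchar(cons))
  ctr <- h$col_to_residue[[1]]
  expect_false(any(ctr == "-"))
  expect_equal(paste(ctr, collapse = ""), cons)
  expect_equal(h$residue14, "V")
  expect_equal(h$residue19, "E")
})

test_that("the reported AP2 region of a potato DREB protein is one clean hit", {
  prof <- build_profile(read_fasta(ap2_seed_alignment_path()))
  ex <- read_fasta(system.file("extdata", "ap2_domain_examples.fasta",
                               package = "genefamr"))
  dom <- ex$residues[ex$id == "StDREB3_domain"]
  protein <- paste0(random_peptide(59), dom, random_peptide(40))
  h <- scan_domain(protein, prof, protein_id = "StDREB3")
  expect_equal(nrow(h), 1)
  # the hit covers the domain region (within a few flanking residues)
  expect_lte(abs(h$start - 59), 5)
  expect_gte(h$end, 59 + nchar(dom) - 5)
  expect_equal(h$residue14, "V")
  expect_equal(h$residue19, "E")
})

test_that("shuffled proteins of the same composition do not hit", {
  prof <- build_profile(read_fasta(ap2_seed_alignment_path()))
  cons <- profile_consensus(prof)
  base <- paste0(random_peptide(120), cons, random_peptide(120))
  hits <- 0L
  withr::with_seed(42, {
    for (i in 1:100) {
      shuf <- paste(sample(strsplit(base, "")[[1]]), collapse = "")
      if (nrow(scan_domain(shuf, prof)) > 0) hits <- hits + 1L
    }
  })
  expect_lte(hits, 1L)
})

test_that("candidate search keeps homologs and rejects unrelated proteins", {
  q <- c(query1 = random_peptide(250))
  hit <- candidate_search(q, c(t1 = q[[1]]), evalue_cutoff = 1e-5)
  expect_equal(hit$target_id, "t1")

  rejected <- 0L
  withr::with_seed(7, {
    for (s in 1:50) {
      t <- c(tr = random_peptide(300))
      r <- candidate_search(q, t, evalue_cutoff = 1e-5)
      if (nrow(r) == 0) rejected <- rejected + 1L
    }
  })
  expect_gte(rejected, 49L)
})

test_that("the V14/E19 filter partitions and conserves counts", {
  mk_hit <- function(r14, r19, n = 1) {
    tibble::tibble(protein_id = "p", start = 0L, end = 54L, score = 100,
                   residue14 = r14, residue19 = r19,
                   col_to_residue = list(NULL))[rep(1, n), ]
  }
  hits <- list(
    good_ve = mk_hit("V", "E"),
    good_v = mk_hit("V", "Q"),
    bad_a14 = mk_hit("A", "E"),
    two_domains = mk_hit("V", "E", n = 2),
    nothing = mk_hit("V", "E", n = 1)[0, ]
  )
  flt <- filter_dreb(hits)
  expect_setequal(flt$accepted, c("good_ve", "good_v"))
  expect_equal(flt$v_and_e, "good_ve")
  expect_equal(flt$v_only, "good_v")
  expect_equal(flt$rejected$reason[flt$rejected$protein_id == "bad_a14"],
               "not_V14")
  expect_equal(flt$rejected$reason[flt$rejected$protein_id == "two_domains"],
               "multiple_domains")
  expect_equal(flt$rejected$reason[flt$rejected$protein_id == "nothing"],
               "no_domain")
  expect_equal(length(flt$accepted) + nrow(flt$rejected), length(hits))
})

test_that("molecular weight matches a direct mass-table sum", {
  g <- physchem("G")
  expect_equal(g$mw, 57.0519 + 18.01524, tolerance = 1e-6)
  expect_equal(g$length, 1L)
  pep <- "ACDEFGHIKLMNPQRSTVWY"
  masses <- c(71.0788, 103.1388, 115.0886, 129.1155, 147.1766, 57.0519,
              137.1411, 113.1594, 128.1741, 113.1594, 131.1926, 114.1038,
              97.1167, 128.1307, 156.1875, 87.0782, 101.1051, 99.1326,
              186.2132, 163.1760)
  expect_equal(physchem(pep)$mw, sum(masses) + 18.01524, tolerance = 1e-6)
  expect_error(physchem("MKX"), "non-standard residue")
})

test_that("the isoelectric point zeroes the net charge and orders sensibly", {
  charge_at <- function(pep, pH) {
    counts <- table(factor(strsplit(pep, "")[[1]],
                           levels = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
    counts <- setNames(as.numeric(counts), names(counts))
    pos <- c(1, counts[c("K", "R", "H")])
    pos_pka <- c(7.5, 10, 12, 5.98)
    neg <- c(1, counts[c("D", "E", "C", "Y")])
    neg_pka <- c(3.55, 4.05, 4.45, 9, 10)
    sum(pos / (1 + 10^(pH - pos_pka))) - sum(neg / (1 + 10^(neg_pka - pH)))
  }
  withr::with_seed(3, {
    for (i in 1:100) {
      pep <- random_peptide(sample(5:80, 1))
      pi <- physchem(pep)$pi
      expect_lt(abs(charge_at(pep, pi)), 1e-3)
    }
  })
  expect_gt(physchem("KKKKK")$pi, physchem("DDDDD")$pi)
})

test_that("identification recovers the planted family exactly", {
  sim <- small_sim()
  prof <- build_profile(sim$seed_alignment)
  proteome <- tibble::tibble(id = names(sim$bundle$proteins),
                             description = "",
                             residues = unname(sim$bundle$proteins))
  res <- identify_family(proteome, sim$reference_panel, prof)
  fam <- sort(sim$truth$family_members$gene_id)
  expect_setequal(res$accepted, fam)
  expect_true(all(sim$truth$v14_negative_decoys %in%
                  res$rejected$protein_id))
  expect_equal(length(res$accepted) + nrow(res$rejected), nrow(res$table))
})
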