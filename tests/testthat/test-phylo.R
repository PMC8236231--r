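test_that("center-star alignment handles identical and near-identical input", {
  ident <- align_family(c(x = "MKVLL", y = "MKVLL", z = "MKVLL"))
  expect_equal(unique(ident$aligned), "MKVLL")
  msa <- align_family(c(x = "MKV", y = "MRV", z = "MKV"))
  expect_equal(unique(nchar(msa$aligned)), 3L)
  m <- do.call(rbind, strsplit(msa$aligned, ""))
  expect_setequal(m[, 2], c("K", "R", "K"))
  expect_error(align_family(c(a = "MK", b = "MR")), "at least 3")
})

test_that("alignment length is at least the longest input sequence", {
  withr::with_seed(5, {
    seqs <- setNames(vapply(1:6, function(i) random_peptide(sample(30:60, 1)),
                            character(1)), paste0("s", 1:6))
    msa <- align_family(seqs)
    expect_gte(unique(nchar(msa$aligned)), max(nchar(seqs)))
    # every sequence is recoverable by dropping gaps
    degap <- gsub("-", "", msa$aligned, fixed = TRUE)
    expect_equal(degap, unname(seqs[msa$id]))
  })
})

test_that("Poisson distance implements pairwise deletion and -ln(1-p)", {
  pair <- c(a = paste(rep("A", 10), collapse = ""),
            b = paste(c(rep("A", 9), "C"), collapse = ""))
  d <- poisson_distance(pair)
  expect_equal(d["a", "b"], -log(0.9))
  expect_equal(d["a", "a"], 0)
  # gapped columns are ignored per pair
  gapped <- c(a = "AAAA--", b = "AA--CC", c = "AAAACC")
  d2 <- poisson_distance(gapped)
  expect_equal(d2["a", "c"], 0)          # shared columns all match
  disjoint <- c(a = "AA--", b = "--CC", c = "AACC")
  expect_error(poisson_distance(disjoint), "no shared ungapped columns")
  sat <- c(a = "AAAA", b = "CCCC", c = "AAAA")
  expect_error(poisson_distance(sat), "saturated")
})

test_that("3-taxon neighbor joining matches the closed form", {
  dm <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  pl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(pl[c("a", "b", "c")]), c(0, 2, 4))
})

test_that("4-taxon additive matrices are solved exactly (exhaustive oracle)", {
  withr::with_seed(9, {
    for (i in 1:20) {
      ra <- random_additive_matrix(4)
      best <- oracle_nj4(ra$dm)
      expect_lt(best$resid, 1e-8)
      tr <- nj_tree(ra$dm)
      # same split: the oracle's first pair must be a cherry in the NJ tree
      d2 <- ape::cophenetic.phylo(tr)[rownames(ra$dm), colnames(ra$dm)]
      expect_equal(d2, ra$dm, tolerance = 1e-8)
    }
  })
})

test_that("NJ recovers random additive trees up to 8 taxa exactly", {
  withr::with_seed(13, {
    for (i in 1:40) {
      n <- sample(4:8, 1)
      ra <- random_additive_matrix(n)
      tr <- nj_tree(ra$dm)
      expect_equal(ape::dist.topo(ape::unroot(ra$tree), tr), 0,
                   ignore_attr = TRUE)
      d2 <- ape::cophenetic.phylo(tr)[rownames(ra$dm), colnames(ra$dm)]
      expect_equal(d2, ra$dm, tolerance = 1e-8)
    }
  })
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  withr::with_seed(17, {
    for (i in 1:10) {
      n <- 7
      ra <- random_additive_matrix(n)
      noisy <- ra$dm + matrix(runif(n * n, 0, 0.01), n, n)
      noisy <- (noisy + t(noisy)) / 2
      diag(noisy) <- 0
      ours <- nj_tree(noisy)
      theirs <- ape::nj(as.dist(noisy))
      expect_equal(ape::dist.topo(ours, ape::unroot(theirs)), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("bootstrap on an invariant alignment gives full support", {
  msa <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "AAAAAAAAAA",
           d = "AAAAAAAAAA")
  # no variable columns: every replicate reproduces the same (star-ish) tree
  bs <- bootstrap_supports(msa, n_replicates = 20, seed = 1)
  expect_true(all(bs$supports$percent == 100))
})

test_that("single-replicate supports are 0 or 100", {
  withr::with_seed(23, {
    base <- random_peptide(60)
    seqs <- setNames(vapply(1:6, function(i) {
      v <- strsplit(base, "")[[1]]
      idx <- sample(60, 12)
      v[idx] <- sample(c("A", "C", "D", "E", "K"), 12, replace = TRUE)
      paste(v, collapse = "")
    }, character(1)), paste0("s", 1:6))
  })
  bs <- bootstrap_supports(seqs, n_replicates = 1, seed = 5)
  expect_true(all(bs$supports$percent %in% c(0, 100)))
})

test_that("two planted clades earn high bootstrap support", {
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), k)
    v[idx] <- sample(c("A", "C", "D", "E", "K", "R", "S", "T"), k,
                     replace = TRUE)
    paste(v, collapse = "")
  }
  withr::with_seed(1, {
    base1 <- random_peptide(80)
    base2 <- mut(base1, 30)   # clades separated but far from saturation
    seqs <- c(p1 = mut(base1, 3), p2 = mut(base1, 3), p3 = mut(base1, 3),
              q1 = mut(base2, 3), q2 = mut(base2, 3), q3 = mut(base2, 3))
  })
  bs <- bootstrap_supports(seqs, n_replicates = 100, seed = 1)
  split_key <- paste(sort(c("q1", "q2", "q3")), collapse = "|")
  expect_gte(bs$supports$percent[bs$supports$bipartition == split_key], 95)
})

test_that("bootstrap supports are invariant under sequence reordering", {
  withr::with_seed(29, {
    base <- random_peptide(50)
    seqs <- setNames(vapply(1:6, function(i) {
      v <- strsplit(base, "")[[1]]
      idx <- sample(50, 10)
      v[idx] <- sample(c("A", "C", "D", "E", "K"), 10, replace = TRUE)
      paste(v, collapse = "")
    }, character(1)), paste0("s", 1:6))
  })
  a <- bootstrap_supports(seqs, n_replicates = 50, seed = 3)
  b <- bootstrap_supports(seqs[c(4, 2, 6, 1, 5, 3)], n_replicates = 50,
                          seed = 3)
  expect_equal(dplyr::arrange(a$supports, bipartition),
               dplyr::arrange(b$supports, bipartition))
})

test_that("subgroup assignment uses clades first, then nearest reference", {
  tr <- ape::read.tree(text = "((q1:0.1,refA3:0.1):0.5,(refA1:0.2,(q2:0.05,refA2:0.3):0.1):0.4,refA4:1);")
  labs <- c(refA1 = "A1", refA2 = "A2", refA3 = "A3", refA4 = "A4")
  asg <- assign_subgroups(tr, labs)
  expect_equal(asg$subgroup[asg$gene_id == "q1"], "A3")
  expect_equal(asg$method[asg$gene_id == "q1"], "clade")
  # q2's smallest reference-containing side holds refA2 only -> clade A2
  expect_equal(asg$subgroup[asg$gene_id == "q2"], "A2")

  # force the nearest-reference fallback: every side holding q1 and a
  # reference mixes two labels, so the patristically closest reference wins
  tr2 <- ape::read.tree(text = "((refA1:0.9,refA2:0.1):0.3,q1:0.2,(refA3:0.5,refA4:0.5):0.4);")
  asg2 <- assign_subgroups(tr2, labs)
  expect_equal(asg2$subgroup[asg2$gene_id == "q1"], "A2")
  expect_equal(asg2$method[asg2$gene_id == "q1"], "nearest")
  # every non-reference tip gets exactly one label
  expect_equal(nrow(asg2), 1)
})

test_that("subgroups of the synthetic family are recovered from the tree", {
  sim <- small_sim()
  fam <- sim$truth$family_members
  prots <- c(sim$bundle$proteins[fam$gene_id],
             setNames(sim$reference_panel$residues, sim$reference_panel$id))
  msa <- align_family(prots)
  tree <- nj_tree(poisson_distance(msa))
  asg <- assign_subgroups(tree, sim$ref_labels)
  m <- dplyr::inner_join(asg, fam, by = "gene_id")
  expect_gte(mean(m$subgroup.x == m$subgroup.y), 0.95)
})
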