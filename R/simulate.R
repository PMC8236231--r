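# Synthetic genomes with planted ground truth. The generator emulates the
# study system: a multi-chromosome genome whose annotated genes include a
# multi-subgroup transcription-factor family carrying a single 54-column
# AP2-like domain (valine at domain column 14; glutamate at column 19 for a
# set fraction), decoy proteins that must fail the conservation filter,
# tandem arrays and segmental collinear blocks evolved to target Ks and
# omega, planted ungapped protein motifs, and intron structures with known
# splicing phases.

# fixed protein architecture of simulated family members (residues)
SIM_FLANK_N <- 40L
SIM_DOMAIN <- 54L
SIM_FLANK_C <- 60L   # inherited (subgroup-informative) C-terminal flank
SIM_VARSEG <- 70L    # per-gene random segment carrying planted motifs

#' Default planted motif specifications
#'
#' Three ungapped motifs: one shared by every family member and two
#' subgroup-specific ones, widths inside the 6-50 search range.
#'
#' @return Tibble with `motif`, `width`, `consensus`, `subgroups` (list).
#' @export
default_motif_specs <- function() {
  tibble(
    motif = c("M1", "M2", "M3"),
    width = c(15L, 9L, 21L),
    consensus = c("WQDFLNESTPRKIAG", "DDEMSGWHY", "NPQHSIQKQGFDDNYGLMEST"),
    subgroups = list(c("A1", "A2", "A3", "A4", "A5", "A6"), "A1", "A6")
  )
}

#' Simulation configuration
#'
#' Defaults mirror the scale of the study system: 12 chromosomes, a
#' 66-member family split 11/8/2/18/8/19 across subgroups A1-A6, 10 tandem
#' arrays, 8 segmental blocks, and a 40/66 fraction of members carrying the
#' glutamate at domain column 19.
#'
#' @param seed Master seed; the whole genome is deterministic given it.
#' @param n_chromosomes,genes_per_chromosome Genome shape.
#' @param family_sizes Named integer vector of subgroup sizes (A1..A6).
#' @param n_tandem_arrays Planted tandem duplicate pairs (0-5 intervening loci).
#' @param n_segmental_blocks Planted within-genome collinear blocks, each
#'   carrying one family duplicate pair.
#' @param block_anchor_count Anchors per planted block (>= 5).
#' @param target_ks_list Target synonymous divergences for planted pairs.
#' @param target_omega Target Ka/Ks for planted pairs.
#' @param motif_specs Tibble as [default_motif_specs()]; widths must be 6-50.
#' @param motif_noise Per-column corruption probability of planted motifs.
#' @param e19_fraction Fraction of family members with E at domain column 19.
#' @param decoy_fraction Decoys (no-domain / two-domain / non-V14) as a
#'   fraction of family size.
#' @param n_refs_per_subgroup Labelled reference proteins per subgroup.
#' @param intron_probs Named probabilities for 0/1/3 introns per gene.
#' @param subgroup_divergence Synonymous divergence root -> subgroup ancestor.
#' @param member_divergence Synonymous divergence ancestor -> member.
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(seed = 101,
                       n_chromosomes = 12,
                       genes_per_chromosome = 250,
                       family_sizes = c(A1 = 11, A2 = 8, A3 = 2,
                                        A4 = 18, A5 = 8, A6 = 19),
                       n_tandem_arrays = 10,
                       n_segmental_blocks = 8,
                       block_anchor_count = 6,
                       target_ks_list = c(0.1, 0.3, 0.6),
                       target_omega = 0.2,
                       motif_specs = default_motif_specs(),
                       motif_noise = 0.05,
                       e19_fraction = 40 / 66,
                       decoy_fraction = 0.15,
                       n_refs_per_subgroup = 3,
                       intron_probs = c(`0` = 0.86, `1` = 0.12, `3` = 0.02),
                       subgroup_divergence = 0.45,
                       member_divergence = 0.15) {
  stopifnot(n_chromosomes >= 1, genes_per_chromosome >= 2,
            all(family_sizes >= 0), n_tandem_arrays >= 0,
            n_segmental_blocks >= 0, block_anchor_count >= 2,
            all(target_ks_list > 0), target_omega > 0,
            e19_fraction >= 0, e19_fraction <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1)
  if (any(motif_specs$width < 6 | motif_specs$width > 50)) {
    abort("motif widths must lie in [6, 50]")
  }
  if (any(motif_specs$width != nchar(motif_specs$consensus))) {
    abort("motif consensus length must equal its width")
  }
  n_fam <- sum(family_sizes)
  if (2 * (n_tandem_arrays + n_segmental_blocks) > n_fam) {
    abort("planted pairs need more family members than family_sizes allows")
  }
  need <- n_fam + round(decoy_fraction * n_fam) +
    2 * n_segmental_blocks * (block_anchor_count - 1)
  if (need > n_chromosomes * genes_per_chromosome) {
    abort("planted family larger than available gene loci")
  }
  structure(
    list(seed = seed, n_chromosomes = n_chromosomes,
         genes_per_chromosome = genes_per_chromosome,
         family_sizes = family_sizes, n_tandem_arrays = n_tandem_arrays,
         n_segmental_blocks = n_segmental_blocks,
         block_anchor_count = block_anchor_count,
         target_ks_list = target_ks_list, target_omega = target_omega,
         motif_specs = motif_specs, motif_noise = motif_noise,
         e19_fraction = e19_fraction, decoy_fraction = decoy_fraction,
         n_refs_per_subgroup = n_refs_per_subgroup,
         intron_probs = intron_probs,
         subgroup_divergence = subgroup_divergence,
         member_divergence = member_divergence),
    class = "sim_config")
}

random_protein <- function(n) {
  paste0v(sample(AA_STANDARD, n, replace = TRUE, prob = AA_BACKGROUND))
}

random_dna <- function(n) paste0v(sample(BASES, n, replace = TRUE))

#' Path to the packaged synthetic AP2-domain seed alignment
#' @return File path of the aligned FASTA shipped with the package.
#' @export
ap2_seed_alignment_path <- function() {
  system.file("extdata", "ap2_seed_alignment_synthetic.fasta",
              package = "genefamr")
}

# Minimum rank separation between family genes that are not a planted pair.
# 26 exceeds both the tandem rule (5 intervening loci) and the collinearity
# chain gap (25 ranks), so unrelated family loci can neither look tandem nor
# link into a collinear chain: the planted duplication truth is unambiguous.
# This mimics real genomes, where family loci are separated by hundreds of
# annotated genes.
SIM_FAMILY_SPACING <- 26L

#' Simulate a genome with a planted gene family and known truth
#'
#' Deterministic given `cfg$seed`. Returns the genome bundle, the planted
#' truth (family membership and subgroups, non-V14 decoys, tandem pairs with
#' intervening-locus counts, segmental pairs with block ids, pair Ks/omega
#' targets, motif sites, intron phases), the labelled reference panel, and
#' the packaged seed alignment.
#'
#' @param cfg A `sim_config`.
#' @return List with `bundle`, `truth`, `reference_panel` (tibble with
#'   `subgroup` column), `ref_labels` (named vector), `seed_alignment`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seed_aln <- read_fasta(ap2_seed_alignment_path())
  withr::with_seed(cfg$seed, simulate_genome_impl(cfg, seed_aln))
}

simulate_genome_impl <- function(cfg, seed_aln) {
  gc_tab <- genetic_code()
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  G <- cfg$genes_per_chromosome
  subgroups <- names(cfg$family_sizes)

  # domain consensus = per-column majority of the seed alignment
  aln_mat <- do.call(rbind, strsplit(seed_aln$residues, "", fixed = TRUE))
  dom_cons <- apply(aln_mat, 2, function(col) {
    names(sort(table(col[col != "-"]), decreasing = TRUE))[1]
  })
  stopifnot(length(dom_cons) == SIM_DOMAIN)

  # Random protein segments destined for family proteins are screened so
  # that no window resembles a planted motif consensus (at most two matching
  # columns per motif-width window): the motif truth holds by construction.
  max_window_matches <- function(pc, cons) {
    cc <- chars(cons)
    w <- length(cc)
    L <- length(pc)
    if (L < w) return(0L)
    m <- L - w + 1L
    cnt <- integer(m)
    for (t in seq_len(w)) cnt <- cnt + (pc[t:(t + m - 1L)] == cc[t])
    max(cnt)
  }
  screened_protein <- function(n) {
    specs_ <- cfg$motif_specs
    repeat {
      p <- random_protein(n)
      pc <- chars(p)
      ok <- TRUE
      for (r in seq_len(nrow(specs_))) {
        thr <- max(3L, ceiling(specs_$width[r] / 3))
        if (max_window_matches(pc, specs_$consensus[r]) >= thr) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(p)
    }
  }

  # --- ancestral sequences ---------------------------------------------------
  root_prot <- paste0(screened_protein(SIM_FLANK_N), paste0v(dom_cons),
                      screened_protein(SIM_FLANK_C))
  root_core <- reverse_translate(root_prot)
  anc <- lapply(setNames(subgroups, subgroups), function(sg) {
    evolve_cds(root_core, cfg$subgroup_divergence, cfg$target_omega)
  })

  # Motifs are planted at per-gene random offsets inside the variable
  # segment, kept 12 residues apart and 3 residues off the segment start:
  # discovered motifs may extend a few columns beyond a planted window, and
  # the margins keep such extensions from masking into a neighboring motif.
  specs <- cfg$motif_specs
  subgroup_specs <- lapply(setNames(subgroups, subgroups), function(sg) {
    specs[vapply(specs$subgroups, function(s) sg %in% s, logical(1)), ]
  })
  sample_offsets <- function(widths) {
    if (3 + sum(widths) + 12 * max(length(widths) - 1, 0) > SIM_VARSEG) {
      abort("variable segment too short for the motif layout")
    }
    for (try in 1:500) {
      offs <- vapply(widths, function(w) sample(3:(SIM_VARSEG - w), 1),
                     integer(1))
      ok <- TRUE
      if (length(offs) > 1) {
        o <- order(offs)
        gaps <- offs[o][-1] - (offs[o][-length(offs)] + widths[o][-length(offs)])
        ok <- all(gaps >= 12)
      }
      if (ok) return(offs)
    }
    # deterministic fallback: packed layout
    3L + cumsum(c(0L, head(widths, -1) + 12L))
  }

  # --- placement plan --------------------------------------------------------
  occ <- matrix(FALSE, cfg$n_chromosomes, G, dimnames = list(chroms, NULL))
  famslot <- setNames(rep(list(integer(0)), length(chroms)), chroms)
  plan_rows <- list()
  # family-exclusion windows around planted blocks (block span +- max_gap):
  # no family gene other than a block's own pair may sit where it could chain
  # onto the block's anchors
  fam_excl <- setNames(rep(list(matrix(numeric(0), 0, 2)), length(chroms)),
                       chroms)
  add_row_ <- function(chrom, slot, kind, subgroup = NA_character_,
                       pair_key = NA_character_, pair_member = NA_integer_,
                       tandem_gap = NA_integer_, block_id = NA_character_) {
    plan_rows[[length(plan_rows) + 1]] <<- tibble(
      chromosome = chrom, slot = slot, kind = kind, subgroup = subgroup,
      pair_key = pair_key, pair_member = pair_member,
      tandem_gap = tandem_gap, block_id = block_id)
    occ[chrom, slot + 1L] <<- TRUE
    # decoys are root-derived homologs: they obey the same spacing rules as
    # family genes so they cannot bridge family loci into spurious chains
    if (kind %in% c("family", "decoy_v14", "decoy_2dom", "decoy_nodom")) {
      famslot[[chrom]] <<- c(famslot[[chrom]], slot)
    }
  }
  fam_ok <- function(chrom, slot, ignore = integer(0)) {
    ex <- setdiff(famslot[[chrom]], ignore)
    length(ex) == 0 || all(abs(ex - slot) >= SIM_FAMILY_SPACING)
  }
  in_excl <- function(chrom, slot) {
    w <- fam_excl[[chrom]]
    nrow(w) > 0 && any(slot >= w[, 1] & slot <= w[, 2])
  }

  remaining <- cfg$family_sizes
  pick_sg_pair <- function() {
    ok <- names(remaining)[remaining >= 2]
    if (length(ok) == 0) abort("family sizes too small for planted pairs")
    sg <- if (length(ok) == 1) ok else
      sample(ok, 1, prob = remaining[ok])
    remaining[sg] <<- remaining[sg] - 2
    sg
  }
  free_fam_slots <- function(chrom) {
    s <- which(!occ[chrom, ]) - 1L
    s <- s[vapply(s, function(x) fam_ok(chrom, x), logical(1))]
    s[!vapply(s, function(x) in_excl(chrom, x), logical(1))]
  }

  # segmental blocks: block_anchor_count collinear anchors on two distinct
  # chromosomes, exactly one anchor being a family duplicate pair
  for (b in seq_len(cfg$n_segmental_blocks)) {
    sg <- pick_sg_pair()
    key <- sprintf("S%02d", b)
    m <- cfg$block_anchor_count
    placed <- FALSE
    for (try in 1:5000) {
      pr <- sample(chroms, 2)
      cA <- pr[1]; cB <- pr[2]
      gapsA <- sample(1:3, m - 1, replace = TRUE)
      gapsB <- sample(1:3, m - 1, replace = TRUE)
      if (G - sum(gapsA) - 1L < 0 || G - sum(gapsB) - 1L < 0) next
      sA <- sample(0:(G - sum(gapsA) - 1L), 1)
      sB <- sample(0:(G - sum(gapsB) - 1L), 1)
      ranksA <- sA + c(0L, cumsum(gapsA))
      ranksB <- sB + c(0L, cumsum(gapsB))
      orient <- sample(c("same", "inverted"), 1)
      ranksB_assign <- if (orient == "inverted") rev(ranksB) else ranksB
      if (any(occ[cA, ranksA + 1L]) || any(occ[cB, ranksB_assign + 1L])) next
      winA <- c(min(ranksA) - 25L, max(ranksA) + 25L)
      winB <- c(min(ranksB) - 25L, max(ranksB) + 25L)
      if (any(famslot[[cA]] >= winA[1] & famslot[[cA]] <= winA[2])) next
      if (any(famslot[[cB]] >= winB[1] & famslot[[cB]] <= winB[2])) next
      if (any(vapply(ranksA, function(x) in_excl(cA, x), logical(1)))) next
      if (any(vapply(ranksB_assign, function(x) in_excl(cB, x),
                     logical(1)))) next
      fa <- sample(m, 1)
      for (i in seq_len(m)) {
        if (i == fa) {
          add_row_(cA, ranksA[i], "family", sg, key, 1L, block_id = key)
          add_row_(cB, ranksB_assign[i], "family", sg, key, 2L,
                   block_id = key)
        } else {
          bkey <- sprintf("%s_a%d", key, i)
          add_row_(cA, ranksA[i], "bg_anchor", pair_key = bkey,
                   pair_member = 1L, block_id = key)
          add_row_(cB, ranksB_assign[i], "bg_anchor", pair_key = bkey,
                   pair_member = 2L, block_id = key)
        }
      }
      fam_excl[[cA]] <- rbind(fam_excl[[cA]], winA)
      fam_excl[[cB]] <- rbind(fam_excl[[cB]], winB)
      placed <- TRUE
      break
    }
    if (!placed) abort("could not place a segmental block: too few free loci")
  }

  # tandem arrays: two family genes, 0-5 intervening background loci
  for (a in seq_len(cfg$n_tandem_arrays)) {
    sg <- pick_sg_pair()
    key <- sprintf("T%02d", a)
    placed <- FALSE
    for (chrom in sample(chroms)) {
      gap <- sample(0:5, 1)
      for (s in sample(0:(G - gap - 2L))) {
        cells <- s:(s + gap + 1L)
        if (any(occ[chrom, cells + 1L])) next
        if (!fam_ok(chrom, s) || !fam_ok(chrom, s + gap + 1L)) next
        if (in_excl(chrom, s) || in_excl(chrom, s + gap + 1L)) next
        add_row_(chrom, s, "family", sg, key, 1L, tandem_gap = gap)
        add_row_(chrom, s + gap + 1L, "family", sg, key, 2L,
                 tandem_gap = gap)
        for (mid in setdiff(cells, c(s, s + gap + 1L))) {
          add_row_(chrom, mid, "background")
        }
        placed <- TRUE
        break
      }
      if (placed) break
    }
    if (!placed) abort("could not place a tandem array: too few free loci")
  }

  # Remaining family members as singles. Within a chromosome the slot that
  # packs tightest against existing family loci (distance closest to the
  # spacing minimum) is preferred, so capacity is not squandered.
  for (sg in subgroups) {
    for (k in seq_len(remaining[[sg]])) {
      placed <- FALSE
      for (chrom in sample(chroms)) {
        slots <- free_fam_slots(chrom)
        if (length(slots) == 0) next
        ex <- famslot[[chrom]]
        s <- if (length(ex) == 0) {
          if (length(slots) == 1) slots else sample(slots, 1)
        } else {
          dmin <- vapply(slots, function(x) min(abs(ex - x)), numeric(1))
          slots[which.min(dmin)]
        }
        add_row_(chrom, s, "family", sg)
        placed <- TRUE
        break
      }
      if (!placed) abort("could not place a family gene: too few free loci")
    }
  }

  # decoys
  n_fam <- sum(cfg$family_sizes)
  n_decoy <- round(cfg$decoy_fraction * n_fam)
  decoy_kinds <- rep(c("decoy_v14", "decoy_2dom", "decoy_nodom"),
                     length.out = n_decoy)
  for (dk in decoy_kinds) {
    placed <- FALSE
    for (chrom in sample(chroms)) {
      slots <- free_fam_slots(chrom)
      if (length(slots) == 0) next
      s <- if (length(slots) == 1) slots else sample(slots, 1)
      add_row_(chrom, s, dk)
      placed <- TRUE
      break
    }
    if (!placed) abort("could not place a decoy gene: too few free loci")
  }

  # background fill
  for (chrom in chroms) {
    for (s in which(!occ[chrom, ]) - 1L) add_row_(chrom, s, "background")
  }
  plan <- bind_rows(plan_rows) |> arrange(.data$chromosome, .data$slot)

  # --- sequence generation ---------------------------------------------------
  omega <- cfg$target_omega
  enforce_domain <- function(cds, e19) {
    cod <- split_codons(cds)
    cod[SIM_FLANK_N + 14L] <- "GTG"
    if (e19) cod[SIM_FLANK_N + 19L] <- "GAA"
    else if (gc_tab[[cod[SIM_FLANK_N + 19L]]] == "E") {
      cod[SIM_FLANK_N + 19L] <- "CAA"
    }
    paste0v(cod)
  }
  new_member_base <- function(sg) {
    core <- evolve_cds(anc[[sg]], cfg$member_divergence, omega)
    paste0(core, reverse_translate(screened_protein(SIM_VARSEG)))
  }
  # Evolutionary drift can recreate a near-copy of a motif consensus in a
  # non-carrier region; break any such window (>= the screening threshold of
  # matching columns) by substituting one matching residue, leaving planted
  # sites and the diagnostic domain columns 14/19 untouched.
  protected_cols <- SIM_FLANK_N + c(14L, 19L)
  cleanup_foreign_windows <- function(prot, planted_mask) {
    pc <- chars(prot)
    for (round in 1:200) {
      viol <- NULL
      for (r in seq_len(nrow(specs))) {
        cc <- chars(specs$consensus[r])
        w <- length(cc)
        thr <- max(3L, ceiling(w / 3))
        m <- length(pc) - w + 1L
        if (m < 1L) next
        cnt <- integer(m)
        for (t in seq_len(w)) cnt <- cnt + (pc[t:(t + m - 1L)] == cc[t])
        bad <- which(cnt >= thr)
        bad <- bad[!vapply(bad, function(o) {
          any(planted_mask[o:(o + w - 1L)])
        }, logical(1))]
        if (length(bad) > 0) {
          viol <- list(o = bad[1], cc = cc, w = w)
          break
        }
      }
      if (is.null(viol)) break
      idx <- viol$o:(viol$o + viol$w - 1L)
      hits <- idx[pc[idx] == viol$cc[idx - viol$o + 1L]]
      hits <- setdiff(hits, protected_cols)
      i <- hits[sample.int(length(hits), 1)]
      pc[i] <- sample(setdiff(AA_STANDARD, pc[i]), 1)
    }
    paste0v(pc)
  }
  finish_member <- function(cds, sg, e19) {
    cds <- enforce_domain(cds, e19)
    prot <- translate_cds(cds)
    lay <- subgroup_specs[[sg]]
    sites <- list()
    planted_mask <- rep(FALSE, nchar(prot))
    if (nrow(lay) > 0) {
      offs <- sample_offsets(lay$width)
      for (r in seq_len(nrow(lay))) {
        off <- SIM_FLANK_N + SIM_DOMAIN + SIM_FLANK_C + offs[r]
        prot <- plant_motif(prot, lay$consensus[r], off, cfg$motif_noise)
        planted_mask[(off + 1):(off + lay$width[r])] <- TRUE
        sites[[r]] <- tibble(motif = lay$motif[r], offset = off,
                             width = lay$width[r],
                             consensus = lay$consensus[r])
      }
    }
    prot <- cleanup_foreign_windows(prot, planted_mask)
    cds <- apply_protein_edits(cds, prot)
    list(cds = cds, sites = bind_rows(sites))
  }

  # e19 assignment: exact global count over family rows
  fam_rows <- which(plan$kind == "family")
  n_e19 <- round(cfg$e19_fraction * length(fam_rows))
  e19_rows <- sample(fam_rows, n_e19)
  plan$e19 <- FALSE
  plan$e19[e19_rows] <- TRUE

  # family pair CDSs (shared recent ancestor evolved to a target Ks)
  pair_cds <- list()
  pair_targets <- list()
  fam_pairs <- plan |> filter(.data$kind == "family", !is.na(.data$pair_key))
  for (key in unique(fam_pairs$pair_key)) {
    sg <- fam_pairs$subgroup[fam_pairs$pair_key == key][1]
    ks <- sample(cfg$target_ks_list, 1)
    pr <- evolve_codon_pair(new_member_base(sg), ks, omega,
                            seed = sample.int(.Machine$integer.max - 1, 1))
    pair_cds[[key]] <- pr
    pair_targets[[key]] <- tibble(pair_key = key, target_ks = ks,
                                  target_omega = omega)
  }
  bg_pairs <- plan |> filter(.data$kind == "bg_anchor")
  for (key in unique(bg_pairs$pair_key)) {
    anc_bg <- reverse_translate(random_protein(250))
    pair_cds[[key]] <- evolve_codon_pair(
      anc_bg, 0.4, 0.3, seed = sample.int(.Machine$integer.max - 1, 1))
  }

  motif_sites <- list()
  gene_cds <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    cds <- switch(row$kind,
      family = {
        base <- if (!is.na(row$pair_key)) {
          pair_cds[[row$pair_key]][[if (row$pair_member == 1) "cds_a" else "cds_b"]]
        } else new_member_base(row$subgroup)
        fin <- finish_member(base, row$subgroup, row$e19)
        if (nrow(fin$sites) > 0) {
          motif_sites[[length(motif_sites) + 1]] <-
            fin$sites |> mutate(plan_row = i)
        }
        fin$cds
      },
      bg_anchor = {
        pair_cds[[row$pair_key]][[if (row$pair_member == 1) "cds_a" else "cds_b"]]
      },
      decoy_v14 = {
        core <- evolve_cds(root_core, cfg$subgroup_divergence, omega)
        cod <- split_codons(core)
        cod[SIM_FLANK_N + 14L] <- "GCG"   # alanine at the diagnostic column
        paste0(paste0v(cod), reverse_translate(random_protein(SIM_VARSEG)))
      },
      decoy_2dom = {
        core <- evolve_cds(root_core, cfg$subgroup_divergence, omega)
        cod <- split_codons(core)
        dom <- cod[(SIM_FLANK_N + 1L):(SIM_FLANK_N + SIM_DOMAIN)]
        dom2 <- split_codons(evolve_cds(paste0v(dom), 0.2, omega))
        paste0v(c(cod, split_codons(reverse_translate(random_protein(12))),
                  dom2,
                  split_codons(reverse_translate(random_protein(30)))))
      },
      decoy_nodom = {
        core <- evolve_cds(root_core, cfg$subgroup_divergence, omega)
        cod <- split_codons(core)
        paste0v(c(cod[seq_len(SIM_FLANK_N)],
                  cod[(SIM_FLANK_N + SIM_DOMAIN + 1L):length(cod)],
                  split_codons(reverse_translate(random_protein(SIM_VARSEG)))))
      },
      background = reverse_translate(random_protein(sample(150:400, 1)))
    )
    gene_cds[i] <- paste0(cds, "TAA")
  }

  # --- genome assembly -------------------------------------------------------
  n_intr_opts <- as.integer(names(cfg$intron_probs))
  genes_out <- list()
  chrom_seqs <- character(0)
  chrom_lens <- numeric(0)
  intron_truth <- list()
  plan$gene_id <- NA_character_
  for (chrom in chroms) {
    rows_i <- which(plan$chromosome == chrom)
    rows_i <- rows_i[order(plan$slot[rows_i])]
    parts <- list()
    pos <- 0L
    for (ri in rows_i) {
      slot <- plan$slot[ri]
      gid <- sprintf("%s_g%03d", chrom, slot + 1L)
      plan$gene_id[ri] <- gid
      spacer <- sample(150:400, 1)
      parts[[length(parts) + 1]] <- random_dna(spacer)
      pos <- pos + spacer

      cds <- gene_cds[ri]
      len <- nchar(cds)
      n_intr <- sample(n_intr_opts, 1, prob = cfg$intron_probs)
      n_intr <- min(n_intr, max(0L, len %/% 80L))
      if (n_intr > 0) {
        repeat {
          cuts <- sort(sample(30:(len - 30L), n_intr))
          if (n_intr == 1 || min(diff(cuts)) >= 20L) break
        }
      } else cuts <- integer(0)
      exon_lens <- diff(c(0L, cuts, len))
      introns <- vapply(seq_len(n_intr), function(k) {
        ilen <- sample(60:200, 1)
        paste0("GT", random_dna(ilen - 4L), "AG")
      }, character(1))

      # pre-mRNA: exon/intron interleaved in transcription order
      ex_seq <- substring(cds, c(0L, cuts) + 1L, c(cuts, len))
      pre_parts <- character(0)
      for (k in seq_along(ex_seq)) {
        pre_parts <- c(pre_parts, ex_seq[k],
                       if (k <= length(introns)) introns[k])
      }
      pre <- paste0v(pre_parts)
      Lp <- nchar(pre)
      ilens <- nchar(introns)
      ex_start_pre <- c(0L, cuts) + c(0L, cumsum(ilens))
      ex_end_pre <- ex_start_pre + exon_lens
      strand <- sample(c("+", "-"), 1)
      if (strand == "+") {
        locus <- pre
        ex <- cbind(pos + ex_start_pre, pos + ex_end_pre)
      } else {
        locus <- revcomp(pre)
        ex <- cbind(pos + Lp - ex_end_pre, pos + Lp - ex_start_pre)
        ex <- ex[order(ex[, 1]), , drop = FALSE]
      }
      parts[[length(parts) + 1]] <- locus
      genes_out[[length(genes_out) + 1]] <- tibble(
        gene_id = gid, chromosome = chrom, start = pos, end = pos + Lp,
        strand = strand, exons = list(ex), cds = cds)
      intron_truth[[length(intron_truth) + 1]] <- tibble(
        gene_id = gid, n_exons = length(exon_lens),
        phases = paste(cuts %% 3L, collapse = ","))
      pos <- pos + Lp
    }
    tailsp <- sample(200:500, 1)
    parts[[length(parts) + 1]] <- random_dna(tailsp)
    pos <- pos + tailsp
    chrom_seqs[[chrom]] <- paste0v(unlist(parts))
    chrom_lens[[chrom]] <- pos
  }
  genes <- bind_rows(genes_out) |> add_gene_ranks()
  proteins <- setNames(vapply(genes$cds, translate_cds, character(1)),
                       genes$gene_id)
  bundle <- genome_bundle("simulated_genome", chrom_lens, genes, proteins,
                          chrom_seqs = chrom_seqs)

  # --- reference panel -------------------------------------------------------
  refs <- list()
  for (sg in subgroups) {
    for (k in seq_len(cfg$n_refs_per_subgroup)) {
      fin <- finish_member(new_member_base(sg), sg, e19 = TRUE)
      refs[[length(refs) + 1]] <- tibble(
        id = sprintf("REF_%s_%d", sg, k), description = sg,
        residues = translate_cds(fin$cds))
    }
  }
  reference_panel <- bind_rows(refs)
  ref_labels <- setNames(reference_panel$description, reference_panel$id)

  # --- truth tables ----------------------------------------------------------
  fam_tbl <- plan |> filter(.data$kind == "family") |>
    transmute(gene_id = .data$gene_id, subgroup = .data$subgroup,
              v_and_e = .data$e19)
  pair_tbl <- function(keys) {
    out <- lapply(keys, function(key) {
      sub <- plan |> filter(.data$pair_key == key, .data$kind == "family") |>
        arrange(.data$pair_member)
      bind_cols(canonical_pair(sub$gene_id[1], sub$gene_id[2]),
                tibble(pair_key = key))
    })
    bind_rows(out)
  }
  tkeys <- unique(plan$pair_key[!is.na(plan$pair_key) &
                                grepl("^T", plan$pair_key) &
                                plan$kind == "family"])
  skeys <- unique(plan$pair_key[!is.na(plan$pair_key) &
                                grepl("^S", plan$pair_key) &
                                plan$kind == "family"])
  tandem_pairs <- if (length(tkeys) > 0) {
    pair_tbl(tkeys) |>
      left_join(plan |> filter(.data$kind == "family",
                               .data$pair_member == 1) |>
                  select(pair_key = "pair_key", intervening = "tandem_gap"),
                by = "pair_key") |> select(-"pair_key")
  } else tibble(id_a = character(), id_b = character(),
                intervening = integer())
  segmental_pairs <- if (length(skeys) > 0) {
    pair_tbl(skeys) |> rename(block_id = "pair_key")
  } else tibble(id_a = character(), id_b = character(),
                block_id = character())
  pair_targets_tbl <- if (length(pair_targets) > 0) {
    bind_rows(pair_targets) |>
      inner_join(pair_tbl(c(tkeys, skeys)), by = "pair_key") |>
      select("id_a", "id_b", "target_ks", "target_omega")
  } else tibble(id_a = character(), id_b = character(),
                target_ks = numeric(), target_omega = numeric())
  motif_sites_tbl <- if (length(motif_sites) > 0) {
    bind_rows(motif_sites) |>
      mutate(gene_id = plan$gene_id[.data$plan_row]) |>
      select("motif", "gene_id", "offset", "width", "consensus")
  } else tibble(motif = character(), gene_id = character(),
                offset = integer(), width = integer(), consensus = character())

  truth <- list(
    family_members = fam_tbl,
    v14_negative_decoys = plan$gene_id[plan$kind == "decoy_v14"],
    two_domain_decoys = plan$gene_id[plan$kind == "decoy_2dom"],
    no_domain_decoys = plan$gene_id[plan$kind == "decoy_nodom"],
    tandem_pairs = tandem_pairs,
    segmental_pairs = segmental_pairs,
    pair_targets = pair_targets_tbl,
    motif_sites = motif_sites_tbl,
    intron_truth = bind_rows(intron_truth),
    plan = plan
  )
  list(bundle = bundle, truth = truth, reference_panel = reference_panel,
       ref_labels = ref_labels, seed_alignment = seed_aln)
}

#' Simulate an ortholog genome sharing collinear blocks with a genome
#'
#' Selected runs of consecutive genes from genome A are copied, evolved to a
#' target synonymous divergence, and placed as collinear runs (occasionally
#' inverted) on the chromosomes of a new genome B whose remaining genes are
#' unrelated background. Segments are chosen so that every family gene whose
#' subgroup occurs in a segment is either inside the segment or more than
#' `max_gap` ranks away, keeping the planted ortholog truth unambiguous.
#'
#' @param sim Result of [simulate_genome()].
#' @param seed Integer seed.
#' @param n_blocks Number of shared blocks.
#' @param anchors_per_block Genes per block.
#' @param ortholog_ks Target synonymous divergence of ortholog pairs.
#' @param omega Ka/Ks for ortholog evolution.
#' @param n_chromosomes,genes_per_chromosome Genome B shape.
#' @param max_gap Rank-gap margin used for the unambiguity rule.
#' @return List with `bundle` (genome B), `truth` (list with `blocks` tibble
#'   of `block_id`, `id_a`, `id_b` and `family_orthologs`).
#' @export
simulate_ortholog_genome <- function(sim, seed = 202, n_blocks = 6,
                                     anchors_per_block = 8,
                                     ortholog_ks = 0.6, omega = 0.2,
                                     n_chromosomes = 5,
                                     genes_per_chromosome = 250,
                                     max_gap = 25) {
  bundle <- sim$bundle
  fam <- sim$truth$family_members
  homolog_like <- c(fam$gene_id, sim$truth$v14_negative_decoys,
                    sim$truth$two_domain_decoys, sim$truth$no_domain_decoys)
  genes <- bundle$genes
  plan <- sim$truth$plan
  block_ids <- plan$gene_id[!is.na(plan$block_id)]
  block_ranks <- lapply(setNames(unique(genes$chromosome),
                                 unique(genes$chromosome)), function(ch) {
    genes$rank[genes$gene_id %in% block_ids & genes$chromosome == ch]
  })
  withr::with_seed(seed, {
    chromsA <- unique(genes$chromosome)
    segs <- list()
    used <- list()
    for (b in seq_len(n_blocks)) {
      placed <- FALSE
      for (try in 1:5000) {
        fgene <- fam$gene_id[sample.int(nrow(fam), 1)]
        gi <- genes[genes$gene_id == fgene, ]
        cA <- gi$chromosome
        GA <- sum(genes$chromosome == cA)
        len <- anchors_per_block
        lo <- max(0L, gi$rank - sample(0:(len - 1L), 1))
        lo <- min(lo, GA - len)
        if (lo < 0) next
        span <- lo:(lo + len - 1L)
        prev <- used[[cA]]
        if (!is.null(prev) && any(span %in% prev)) next
        seg_genes <- genes |> filter(.data$chromosome == cA,
                                     .data$rank %in% span) |>
          arrange(.data$rank)
        seg_fam <- fam |> filter(.data$gene_id %in% seg_genes$gene_id)
        if (nrow(seg_fam) == 0) next
        # no family gene outside the segment may sit close enough (within
        # max_gap ranks) to chain onto the segment's anchors
        fam_ranks <- genes$rank[genes$gene_id %in% homolog_like &
                                genes$chromosome == cA]
        outside <- fam_ranks[!(fam_ranks %in% span)]
        if (length(outside) > 0 &&
            any(outside > min(span) - max_gap - 1 &
                outside < max(span) + max_gap + 1)) next
        # stay clear of planted within-genome duplication blocks: their
        # duplicate copy elsewhere in genome A would otherwise also be
        # collinear with the new ortholog run
        if (length(block_ranks[[cA]]) > 0 &&
            any(block_ranks[[cA]] > min(span) - max_gap - 1 &
                block_ranks[[cA]] < max(span) + max_gap + 1)) next
        segs[[b]] <- seg_genes
        used[[cA]] <- c(prev, span)
        placed <- TRUE
        break
      }
      if (!placed) abort("could not select an unambiguous ortholog segment")
    }

    # build genome B
    chromsB <- sprintf("bchr%02d", seq_len(n_chromosomes))
    GB <- genes_per_chromosome
    occ <- matrix(FALSE, n_chromosomes, GB, dimnames = list(chromsB, NULL))
    slot_gene <- list()   # per B slot: list(cds, ortho_of, block)
    blocks_truth <- list()
    for (b in seq_along(segs)) {
      seg <- segs[[b]]
      m <- nrow(seg)
      placed <- FALSE
      for (try in 1:5000) {
        cB <- sample(chromsB, 1)
        sB <- sample(0:(GB - m), 1)
        span <- sB:(sB + m - 1L)
        if (any(occ[cB, span + 1L])) next
        invert <- runif(1) < 0.3
        ordB <- if (invert) rev(seq_len(m)) else seq_len(m)
        for (k in seq_len(m)) {
          a_row <- seg[ordB[k], ]
          core <- a_row$cds
          cod <- split_codons(core)
          if (is_stop_codon(cod[length(cod)])) cod <- cod[-length(cod)]
          bc <- paste0(evolve_cds(paste0v(cod), ortholog_ks, omega), "TAA")
          slot_gene[[paste(cB, span[k])]] <- list(
            cds = bc, ortho_of = a_row$gene_id,
            block = sprintf("OB%02d", b))
          occ[cB, span[k] + 1L] <- TRUE
        }
        placed <- TRUE
        break
      }
      if (!placed) abort("could not place an ortholog block in genome B")
    }
    # background fill for genome B
    for (cB in chromsB) {
      for (s in which(!occ[cB, ]) - 1L) {
        slot_gene[[paste(cB, s)]] <- list(
          cds = paste0(reverse_translate(random_protein(sample(150:400, 1))),
                       "TAA"),
          ortho_of = NA_character_, block = NA_character_)
      }
    }

    genes_out <- list()
    chrom_seqs <- character(0)
    chrom_lens <- numeric(0)
    truth_rows <- list()
    for (cB in chromsB) {
      parts <- list()
      pos <- 0L
      for (s in 0:(GB - 1L)) {
        info <- slot_gene[[paste(cB, s)]]
        gid <- sprintf("%s_g%03d", cB, s + 1L)
        spacer <- sample(150:400, 1)
        parts[[length(parts) + 1]] <- random_dna(spacer)
        pos <- pos + spacer
        len <- nchar(info$cds)
        strand <- sample(c("+", "-"), 1)
        locus <- if (strand == "+") info$cds else revcomp(info$cds)
        ex <- matrix(c(pos, pos + len), 1, 2)
        parts[[length(parts) + 1]] <- locus
        genes_out[[length(genes_out) + 1]] <- tibble(
          gene_id = gid, chromosome = cB, start = pos, end = pos + len,
          strand = strand, exons = list(ex), cds = info$cds)
        if (!is.na(info$ortho_of)) {
          truth_rows[[length(truth_rows) + 1]] <- tibble(
            block_id = info$block, id_a = info$ortho_of, id_b = gid)
        }
        pos <- pos + len
      }
      tailsp <- sample(200:500, 1)
      parts[[length(parts) + 1]] <- random_dna(tailsp)
      pos <- pos + tailsp
      chrom_seqs[[cB]] <- paste0v(unlist(parts))
      chrom_lens[[cB]] <- pos
    }
    genesB <- bind_rows(genes_out) |> add_gene_ranks()
    protsB <- setNames(vapply(genesB$cds, translate_cds, character(1)),
                       genesB$gene_id)
    bundleB <- genome_bundle("ortholog_genome", chrom_lens, genesB, protsB,
                             chrom_seqs = chrom_seqs)
    blocks <- bind_rows(truth_rows)
    list(bundle = bundleB,
         truth = list(blocks = blocks,
                      family_orthologs = intersect(blocks$id_a,
                                                   fam$gene_id)))
  })
}
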