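# Tandem/segmental duplication detection, homolog pairing, collinear-block
# chaining, and evolutionary dating of duplicate pairs.

#' Detect tandem duplicate pairs within a gene family
#'
#' Two family genes on the same chromosome separated by at most five
#' intervening gene loci (counting every annotated gene strictly between
#' them, i.e. rank difference minus one) form a tandem pair.
#'
#' @param family_ids Ids of the family genes.
#' @param genes Gene-model tibble with `gene_id`, `chromosome`, `rank`.
#' @param max_intervening Maximum intervening loci (default 5).
#' @param family_only If `TRUE`, intervening loci are counted over family
#'   genes only instead of all annotated genes.
#' @return Tibble `id_a`, `id_b` (canonical order), `chromosome`,
#'   `intervening`.
#' @export
detect_tandem <- function(family_ids, genes, max_intervening = 5,
                          family_only = FALSE) {
  fam <- genes |> filter(.data$gene_id %in% family_ids)
  if (family_only) {
    fam <- fam |>
      group_by(.data$chromosome) |>
      mutate(rank = rank(.data$rank, ties.method = "first") - 1L) |>
      ungroup()
  }
  out <- list()
  for (chr in unique(fam$chromosome)) {
    sub <- fam |> filter(.data$chromosome == chr) |> arrange(.data$rank)
    if (nrow(sub) < 2) next
    prs <- combn(nrow(sub), 2)
    for (c_i in seq_len(ncol(prs))) {
      i <- prs[1, c_i]; j <- prs[2, c_i]
      intervening <- abs(sub$rank[j] - sub$rank[i]) - 1L
      if (intervening <= max_intervening) {
        out[[length(out) + 1]] <- bind_cols(
          canonical_pair(sub$gene_id[i], sub$gene_id[j]),
          tibble(chromosome = chr, intervening = intervening))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(id_a = character(), id_b = character(),
                  chromosome = character(), intervening = integer()))
  }
  bind_rows(out) |> arrange(.data$id_a, .data$id_b)
}

#' Find homologous gene pairs within or between genomes
#'
#' Two-stage search: a trimer-composition cosine prefilter shortlists
#' candidate pairs, which are then verified by local alignment (BLOSUM62,
#' affine gaps) with the Karlin-Altschul E-value cutoff. Within one genome,
#' self pairs are excluded and pairs are reported in canonical order.
#'
#' @param bundle_a,bundle_b `genome_bundle`s; omit `bundle_b` (or pass the
#'   same bundle) for within-genome pairs.
#' @param evalue_cutoff E-value threshold for the verification alignment.
#' @param prefilter_cosine Minimum trimer cosine similarity to shortlist.
#' @param top_hits Keep a pair only if it ranks within the `top_hits` best
#'   partners (by score) of at least one of its two genes, the usual
#'   best-hits cutoff of collinearity tools. `Inf` keeps everything.
#' @return Tibble `id_a`, `id_b`, `bitscore` (raw local score), `evalue`,
#'   `genome_a`, `genome_b`.
#' @export
find_homolog_pairs <- function(bundle_a, bundle_b = NULL,
                               evalue_cutoff = 1e-5,
                               prefilter_cosine = 0.12,
                               top_hits = Inf) {
  same <- is.null(bundle_b) || identical(bundle_b$genome_id, bundle_a$genome_id)
  if (is.null(bundle_b)) bundle_b <- bundle_a
  pa <- bundle_a$proteins
  pb <- bundle_b$proteins

  kmer_mat <- function(p) {
    rows <- lapply(p, function(s) {
      cd <- match(chars(s), AA_STANDARD)
      cd[is.na(cd)] <- 1L
      L <- length(cd)
      if (L < 3) return(integer(0))
      (cd[1:(L - 2)] - 1L) * 400L + (cd[2:(L - 1)] - 1L) * 20L + cd[3:L]
    })
    ij <- lapply(seq_along(rows), function(i) {
      tb <- table(rows[[i]])
      cbind(i = rep(i, length(tb)), j = as.integer(names(tb)),
            x = as.numeric(tb))
    })
    ij <- do.call(rbind, ij)
    m <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = ij[, 3],
                              dims = c(length(p), 8000L))
    nrm <- sqrt(Matrix::rowSums(m^2))
    nrm[nrm == 0] <- 1
    m / nrm
  }
  ma <- kmer_mat(pa)
  mb <- if (same) ma else kmer_mat(pb)
  sim <- as.matrix(Matrix::tcrossprod(ma, mb))
  rownames(sim) <- names(pa); colnames(sim) <- names(pb)
  cand <- which(sim >= prefilter_cosine, arr.ind = TRUE)
  if (same) cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble(id_a = character(), id_b = character(), bitscore = numeric(),
                  evalue = numeric(), genome_a = character(),
                  genome_b = character()))
  }
  ids_a <- names(pa)[cand[, 1]]
  ids_b <- names(pb)[cand[, 2]]

  # verify shortlisted pairs, batched by the a-side protein
  res <- list()
  for (ia in unique(ids_a)) {
    partners <- ids_b[ids_a == ia]
    set <- Biostrings::AAStringSet(gsub("[^A-Z]", "X", toupper(pb[partners])))
    names(set) <- partners
    sc <- Biostrings::pairwiseAlignment(
      pattern = set,
      subject = Biostrings::AAString(gsub("[^A-Z]", "X", toupper(pa[[ia]]))),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    sc <- pmax(sc, 0)
    ev <- KA_K_BLOSUM62 * nchar(pa[[ia]]) * nchar(pb[partners]) *
      exp(-KA_LAMBDA_BLOSUM62 * sc)
    keep <- ev <= evalue_cutoff
    if (any(keep)) {
      res[[length(res) + 1]] <- tibble(
        id_a = ia, id_b = partners[keep], bitscore = sc[keep],
        evalue = ev[keep])
    }
  }
  if (length(res) == 0) {
    return(tibble(id_a = character(), id_b = character(), bitscore = numeric(),
                  evalue = numeric(), genome_a = character(),
                  genome_b = character()))
  }
  out <- bind_rows(res)
  if (same) {
    cp <- canonical_pair(out$id_a, out$id_b)
    out$id_a <- cp$id_a; out$id_b <- cp$id_b
  }
  out <- out |>
    mutate(genome_a = bundle_a$genome_id, genome_b = bundle_b$genome_id) |>
    distinct(.data$id_a, .data$id_b, .keep_all = TRUE)
  if (is.finite(top_hits) && nrow(out) > 0) {
    # rank every pair within the full partner list of each of its two genes
    # (same-genome partner lists merge both orientations)
    long <- bind_rows(
      tibble(gene = paste0("a:", out$id_a), pair = seq_len(nrow(out)),
             score = out$bitscore),
      tibble(gene = paste0(if (same) "a:" else "b:", out$id_b),
             pair = seq_len(nrow(out)), score = out$bitscore))
    long <- long |>
      group_by(.data$gene) |>
      mutate(r = rank(-.data$score, ties.method = "first")) |>
      ungroup()
    best_rank <- long |>
      group_by(.data$pair) |>
      summarise(r = min(.data$r), .groups = "drop") |>
      arrange(.data$pair)
    out <- out[best_rank$r <= top_hits, ]
  }
  out |> arrange(.data$id_a, .data$id_b)
}

#' Detect collinear blocks between (or within) genomes
#'
#' Homolog pairs are treated as anchors on the gene-rank grid. Per
#' chromosome pair and orientation, maximal chains with strictly monotone
#' ranks on both sides and consecutive rank gaps of at most `max_gap` are
#' found by dynamic programming; chains are extracted best-first, each anchor
#' belongs to at most one block, and chains shorter than `min_anchors` are
#' dropped.
#'
#' @param bundle_a,bundle_b `genome_bundle`s (pass the same bundle twice, or
#'   omit `bundle_b`, for within-genome blocks).
#' @param pairs Homolog-pair tibble from [find_homolog_pairs()].
#' @param min_anchors Minimum anchors per block (default 5).
#' @param max_gap Maximum rank gap between consecutive anchors (default 25).
#' @return Tibble of anchors, one row each, with `block_id`, `genome_a`,
#'   `genome_b`, `chr_a`, `chr_b`, `orientation`, `id_a`, `id_b`, `rank_a`,
#'   `rank_b`.
#' @export
detect_collinear <- function(bundle_a, bundle_b = NULL, pairs,
                             min_anchors = 5, max_gap = 25) {
  same <- is.null(bundle_b)
  if (same) bundle_b <- bundle_a
  ga <- bundle_a$genes |> select(id_a = "gene_id", chr_a = "chromosome",
                                 rank_a = "rank")
  gb <- bundle_b$genes |> select(id_b = "gene_id", chr_b = "chromosome",
                                 rank_b = "rank")
  anchors <- pairs |>
    filter(.data$id_a != .data$id_b) |>
    inner_join(ga, by = "id_a") |>
    inner_join(gb, by = "id_b")

  empty <- tibble(block_id = character(), genome_a = character(),
                  genome_b = character(), chr_a = character(),
                  chr_b = character(), orientation = character(),
                  id_a = character(), id_b = character(),
                  rank_a = integer(), rank_b = integer())
  if (nrow(anchors) == 0) return(empty)

  blocks <- list()
  bi <- 0L
  for (key in unique(paste(anchors$chr_a, anchors$chr_b, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- anchors |> filter(.data$chr_a == parts[1],
                             .data$chr_b == parts[2]) |>
      arrange(.data$rank_a, .data$rank_b)
    used <- rep(FALSE, nrow(sub))          # an anchor joins at most one block
    for (orient in c("same", "inverted")) {
      repeat {
        avail <- which(!used)
        if (length(avail) < min_anchors) break
        s <- sub[avail, ]
        n <- nrow(s)
        # DP: longest chain with strict monotone ranks and bounded gaps
        len <- rep(1L, n); prev <- rep(NA_integer_, n)
        for (j in seq_len(n)) {
          for (i in seq_len(j - 1L)) {
            da <- s$rank_a[j] - s$rank_a[i]
            db <- if (orient == "same") s$rank_b[j] - s$rank_b[i]
                  else s$rank_b[i] - s$rank_b[j]
            if (da > 0 && db > 0 && da <= max_gap && db <= max_gap &&
                len[i] + 1L > len[j]) {
              len[j] <- len[i] + 1L
              prev[j] <- i
            }
          }
        }
        best_len <- max(len)
        if (best_len < min_anchors) break
        j <- which(len == best_len)[1]
        chain <- integer(0)
        while (!is.na(j)) { chain <- c(j, chain); j <- prev[j] }
        bi <- bi + 1L
        blk <- s[chain, ] |>
          mutate(block_id = paste0("block_", bi),
                 genome_a = bundle_a$genome_id,
                 genome_b = bundle_b$genome_id,
                 chr_a = parts[1], chr_b = parts[2], orientation = orient) |>
          select(block_id, genome_a, genome_b, chr_a, chr_b, orientation,
                 id_a, id_b, rank_a, rank_b)
        blocks[[length(blocks) + 1]] <- blk
        used[avail[chain]] <- TRUE
      }
    }
  }
  if (length(blocks) == 0) return(empty)
  bind_rows(blocks)
}

#' Classify family duplicate pairs as tandem or segmental
#'
#' Tandem pairs (from [detect_tandem()]) take priority; any other family
#' pair that appears as an anchor of a within-genome collinear block is
#' segmental.
#'
#' @param family_ids Family gene ids.
#' @param tandem Tandem-pair tibble.
#' @param self_blocks Within-genome block tibble from [detect_collinear()].
#' @return Tibble `id_a`, `id_b`, `dup_type`, `intervening` (`NA` for
#'   segmental), `block_id` (`NA` for tandem).
#' @export
classify_duplicates <- function(family_ids, tandem, self_blocks) {
  tnd <- tandem |>
    mutate(dup_type = "tandem", block_id = NA_character_) |>
    select("id_a", "id_b", "dup_type", "intervening", "block_id")
  seg <- self_blocks |>
    filter(.data$id_a %in% family_ids, .data$id_b %in% family_ids)
  if (nrow(seg) > 0) {
    cp <- canonical_pair(seg$id_a, seg$id_b)
    seg <- seg |> mutate(id_a = cp$id_a, id_b = cp$id_b) |>
      distinct(.data$id_a, .data$id_b, .keep_all = TRUE) |>
      anti_join(tnd, by = c("id_a", "id_b")) |>
      mutate(dup_type = "segmental", intervening = NA_integer_) |>
      select("id_a", "id_b", "dup_type", "intervening", "block_id")
  } else {
    seg <- tnd[0, ]
  }
  bind_rows(tnd, seg) |> arrange(.data$dup_type, .data$id_a, .data$id_b)
}

#' Date duplicate pairs: Ka, Ks, omega and divergence time
#'
#' For each pair the proteins are globally aligned, the alignment is expanded
#' to codons, NG86 Ka/Ks is computed and the synonymous rate converted to a
#' divergence time in million years.
#'
#' @param dup_pairs Tibble with `id_a`, `id_b` (e.g. from
#'   [classify_duplicates()]).
#' @param bundle A `genome_bundle` holding the proteins and CDSs.
#' @return `dup_pairs` with `ka`, `ks`, `omega`, `t_mya` columns appended.
#' @export
date_duplicates <- function(dup_pairs, bundle) {
  if (nrow(dup_pairs) == 0) {
    return(dup_pairs |> mutate(ka = numeric(0), ks = numeric(0),
                               omega = numeric(0), t_mya = numeric(0)))
  }
  genes <- bundle$genes
  stats <- purrr::map2(dup_pairs$id_a, dup_pairs$id_b, function(a, b) {
    pa <- bundle$proteins[[a]]; pb <- bundle$proteins[[b]]
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(pa), subject = Biostrings::AAString(pb),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    ca <- codon_align(
      as.character(Biostrings::alignedPattern(aln)),
      as.character(Biostrings::alignedSubject(aln)),
      genes$cds[match(a, genes$gene_id)],
      genes$cds[match(b, genes$gene_id)], id_a = a, id_b = b)
    st <- ng86(ca)
    st |> mutate(t_mya = divergence_time(.data$ks)) |>
      select("ka", "ks", "omega", "t_mya")
  }) |> bind_rows()
  bind_cols(dup_pairs, stats)
}

#' Count family genes with cross-species collinear orthologs
#'
#' @param blocks Cross-genome block tibble from [detect_collinear()].
#' @param family_ids Family gene ids of genome A.
#' @return Number of family genes appearing in at least one anchor.
#' @export
ortholog_counts <- function(blocks, family_ids) {
  length(intersect(unique(blocks$id_a), family_ids))
}
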