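# End-to-end orchestration: simulate (or load) -> identify -> phylogeny ->
# structure + motifs -> duplications -> synteny, with one config object,
# stage-level logging of record counts, and deterministic table outputs.

#' Pipeline configuration
#'
#' Either `simulate` (a [sim_config()]) or the full set of input paths must
#' be given. Analysis defaults follow the study parameterization: homology
#' E-value 1e-5, 1000 bootstrap replicates, motif widths 6-50 with at most
#' 15 motifs, tandem rule of at most 5 intervening loci, collinearity with 5
#' anchors minimum and rank gap 25.
#'
#' @param simulate Optional `sim_config` for synthetic input.
#' @param proteome,gff,genome_fasta,references,seed_alignment Input paths
#'   (references as labelled FASTA, subgroup after the id as `id|A4`).
#' @param evalue Homology E-value cutoff.
#' @param bit_threshold Domain-scan threshold (bits).
#' @param replicates Bootstrap replicates.
#' @param seed Master seed for all stochastic stages.
#' @param min_anchors,max_gap,top_hits Collinearity parameters.
#' @param motif_widths,max_motifs,motif_llr_floor Motif-discovery parameters.
#' @param with_ortholog_genome Also simulate a second genome and run the
#'   cross-species synteny stage (simulation mode only).
#' @param outdir Optional output directory for the report tables.
#' @return A `genefam_config` object.
#' @export
genefam_config <- function(simulate = NULL, proteome = NULL, gff = NULL,
                           genome_fasta = NULL, references = NULL,
                           seed_alignment = NULL,
                           evalue = 1e-5, bit_threshold = 25,
                           replicates = 1000, seed = 1,
                           min_anchors = 5, max_gap = 25, top_hits = Inf,
                           motif_widths = c(seq(6, 48, 3), 50),
                           max_motifs = 15, motif_llr_floor = 0,
                           with_ortholog_genome = TRUE, outdir = NULL) {
  if (is.null(simulate)) {
    missing <- c(proteome = is.null(proteome), gff = is.null(gff),
                 genome_fasta = is.null(genome_fasta),
                 references = is.null(references),
                 seed_alignment = is.null(seed_alignment))
    if (any(missing)) {
      abort(paste0("config needs either `simulate` or all input paths; ",
                   "missing: ", paste(names(missing)[missing],
                                      collapse = ", ")))
    }
  }
  stopifnot(evalue > 0, bit_threshold > 0, replicates >= 1,
            min_anchors >= 2, max_gap >= 1, max_motifs >= 0)
  structure(
    list(simulate = simulate, proteome = proteome, gff = gff,
         genome_fasta = genome_fasta, references = references,
         seed_alignment = seed_alignment, evalue = evalue,
         bit_threshold = bit_threshold, replicates = replicates, seed = seed,
         min_anchors = min_anchors, max_gap = max_gap, top_hits = top_hits,
         motif_widths = motif_widths, max_motifs = max_motifs,
         motif_llr_floor = motif_llr_floor,
         with_ortholog_genome = with_ortholog_genome, outdir = outdir),
    class = "genefam_config")
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage ", stage, "] ", conditionMessage(e)))
  })
}

#' Run the full gene-family characterization pipeline
#'
#' Executes simulate (optional), identification, phylogeny + subgroup
#' assignment, gene structure + motif discovery, duplication classification
#' with Ka/Ks dating, and (with a second genome) cross-species synteny.
#' Deterministic given the config seeds; every stage logs its record counts.
#'
#' @param cfg A `genefam_config`.
#' @return A `genefam_report` (list of result tables, counts and parameters).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "genefam_config"))
  t0 <- Sys.time()
  counts <- list()
  warnings <- character(0)

  # --- inputs ---------------------------------------------------------------
  sim <- NULL
  ortho <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- stage_run("simulate", simulate_genome(cfg$simulate))
    bundle <- sim$bundle
    proteome <- seq_tbl(names(bundle$proteins), bundle$proteins)
    refs <- sim$reference_panel
    ref_labels <- sim$ref_labels
    seed_aln <- sim$seed_alignment
    if (isTRUE(cfg$with_ortholog_genome)) {
      ortho <- stage_run("simulate", simulate_ortholog_genome(
        sim, seed = derive_seed(cfg$seed, 7)))
    }
    message("[simulate] genes: ", nrow(bundle$genes),
            "; family planted: ", nrow(sim$truth$family_members))
  } else {
    bundle <- stage_run("load", {
      genes <- read_gff3(cfg$gff)
      chrom <- read_fasta(cfg$genome_fasta)
      chrom_seqs <- seq_vec(chrom)
      prot <- read_fasta(cfg$proteome)
      genome_bundle("input_genome", setNames(nchar(chrom_seqs),
                                             names(chrom_seqs)),
                    genes, seq_vec(prot), chrom_seqs = chrom_seqs)
    })
    proteome <- seq_tbl(names(bundle$proteins), bundle$proteins)
    refs_raw <- stage_run("load", read_fasta(cfg$references))
    lab <- strsplit(refs_raw$id, "|", fixed = TRUE)
    refs <- refs_raw |>
      mutate(id = vapply(lab, `[[`, character(1), 1),
             description = vapply(lab, function(x) tail(x, 1), character(1)))
    ref_labels <- setNames(refs$description, refs$id)
    seed_aln <- stage_run("load", read_fasta(cfg$seed_alignment))
  }

  # --- identification -------------------------------------------------------
  ident <- stage_run("identify", {
    profile <- build_profile(seed_aln)
    identify_family(proteome, refs, profile, evalue_cutoff = cfg$evalue,
                    bit_threshold = cfg$bit_threshold)
  })
  counts$scanned <- nrow(ident$table)
  counts$accepted <- length(ident$accepted)
  counts$rejected <- nrow(ident$rejected)
  stopifnot(counts$accepted + counts$rejected == counts$scanned)
  message("[identify] scanned: ", counts$scanned,
          "; accepted: ", counts$accepted,
          " (V+E: ", length(ident$v_and_e),
          ", V only: ", length(ident$v_only), ")")

  family_ids <- sort(ident$accepted)
  fam_prot <- proteome |> filter(.data$id %in% family_ids)

  # --- phylogeny and subgroups ----------------------------------------------
  if (nrow(refs) == 0) abort("[stage phylo] missing input: references")
  phylo <- stage_run("phylo", {
    all_prot <- bind_rows(fam_prot, refs |> select("id", "residues") |>
                            mutate(description = ""))
    msa <- align_family(all_prot)
    bs <- bootstrap_supports(msa, n_replicates = cfg$replicates,
                             seed = derive_seed(cfg$seed, 1))
    groups <- assign_subgroups(bs$tree, ref_labels)
    list(msa = msa, tree = bs$tree, supports = bs$supports, groups = groups)
  })
  subgroup_counts <- phylo$groups |> count(.data$subgroup, name = "n")
  counts$assigned <- nrow(phylo$groups)
  stopifnot(counts$assigned == counts$accepted)
  message("[phylo] assigned: ", counts$assigned, " into ",
          nrow(subgroup_counts), " subgroups")

  # --- gene structure and motifs --------------------------------------------
  fam_genes <- bundle$genes |> filter(.data$gene_id %in% family_ids)
  structure_tbl <- stage_run("structure", gene_structure(fam_genes))
  motifs <- stage_run("motifs", discover_motifs(
    fam_prot, widths = cfg$motif_widths, max_motifs = cfg$max_motifs,
    seed = derive_seed(cfg$seed, 2), llr_floor = cfg$motif_llr_floor))
  occurrences <- stage_run("motifs", {
    occ <- list()
    for (m in motifs) {
      for (i in seq_len(nrow(fam_prot))) {
        occ[[length(occ) + 1]] <- scan_motif(fam_prot$residues[[i]], m,
                                             protein_id = fam_prot$id[[i]])
      }
    }
    bind_rows(occ)
  })
  pres <- presence_matrix(family_ids, motifs, occurrences)
  counts$motifs <- length(motifs)
  message("[motifs] discovered: ", counts$motifs,
          "; occurrences: ", nrow(occurrences))

  # --- duplications ---------------------------------------------------------
  dups <- stage_run("duplication", {
    tandem <- detect_tandem(family_ids, bundle$genes)
    pairs <- find_homolog_pairs(bundle, top_hits = cfg$top_hits)
    self_blocks <- detect_collinear(bundle, pairs = pairs,
                                    min_anchors = cfg$min_anchors,
                                    max_gap = cfg$max_gap)
    cls <- classify_duplicates(family_ids, tandem, self_blocks)
    dated <- date_duplicates(cls, bundle)
    list(tandem = tandem, pairs = pairs, self_blocks = self_blocks,
         dated = dated)
  })
  counts$tandem <- sum(dups$dated$dup_type == "tandem")
  counts$segmental <- sum(dups$dated$dup_type == "segmental")
  message("[duplication] tandem pairs: ", counts$tandem,
          "; segmental pairs: ", counts$segmental)

  # --- cross-species synteny ------------------------------------------------
  synteny <- NULL
  if (!is.null(ortho)) {
    synteny <- stage_run("synteny", {
      pairs_ab <- find_homolog_pairs(bundle, ortho$bundle,
                                     top_hits = cfg$top_hits)
      blocks <- detect_collinear(bundle, ortho$bundle, pairs = pairs_ab,
                                 min_anchors = cfg$min_anchors,
                                 max_gap = cfg$max_gap)
      list(pairs = pairs_ab, blocks = blocks,
           n_family_orthologs = ortholog_counts(blocks, family_ids))
    })
    counts$family_orthologs <- synteny$n_family_orthologs
    message("[synteny] family genes with collinear orthologs: ",
            counts$family_orthologs)
  }

  report <- structure(
    list(identification = ident$table, accepted = family_ids,
         v_and_e = ident$v_and_e, v_only = ident$v_only,
         rejected = ident$rejected,
         tree = phylo$tree, supports = phylo$supports, msa = phylo$msa,
         subgroups = phylo$groups, subgroup_counts = subgroup_counts,
         structure = structure_tbl, motifs = motifs,
         motif_occurrences = occurrences, presence = pres,
         duplications = dups$dated, self_blocks = dups$self_blocks,
         homolog_pairs = dups$pairs,
         synteny = synteny,
         sim = sim, ortho = ortho,
         counts = counts, config = cfg,
         wall_time = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "genefam_report")
  if (!is.null(cfg$outdir)) write_report(report, cfg$outdir)
  report
}

#' Write the report tables of a pipeline run
#'
#' Emits plain TSV tables (identification, subgroups and counts, structure,
#' motif summaries and occurrences, presence matrix, duplications, synteny)
#' plus the Newick tree. Deterministic: rerunning the same config yields
#' byte-identical files.
#'
#' @param report A `genefam_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(report$identification |> select(-any_of("col_to_residue")),
      "identification.tsv")
  tsv(report$subgroups, "subgroups.tsv")
  tsv(report$subgroup_counts, "subgroup_counts.tsv")
  tsv(report$structure |> select(-"intron_phases"), "structure.tsv")
  tsv(bind_rows(lapply(report$motifs, glance)), "motifs.tsv")
  tsv(report$motif_occurrences, "motif_sites.tsv")
  pm <- as.data.frame(report$presence)
  pm <- cbind(gene_id = rownames(pm), pm)
  tsv(pm, "presence_matrix.tsv")
  tsv(report$duplications, "duplications.tsv")
  if (!is.null(report$synteny)) {
    tsv(report$synteny$blocks, "synteny_blocks.tsv")
    tsv(tibble(n_family_orthologs = report$synteny$n_family_orthologs),
        "ortholog_counts.tsv")
  }
  write_newick(report$tree, file.path(dir, "family_tree.nwk"))
  invisible(dir)
}

#' @export
print.genefam_report <- function(x, ...) {
  cat("<genefam_report>\n")
  cat("  scanned:   ", x$counts$scanned, "\n")
  cat("  accepted:  ", x$counts$accepted, " (V+E: ", length(x$v_and_e),
      ", V only: ", length(x$v_only), ")\n", sep = "")
  cat("  subgroups: ", paste0(x$subgroup_counts$subgroup, "=",
                              x$subgroup_counts$n, collapse = ", "), "\n")
  cat("  motifs:    ", x$counts$motifs, "\n")
  cat("  tandem:    ", x$counts$tandem, "  segmental: ", x$counts$segmental,
      "\n", sep = "")
  if (!is.null(x$synteny)) {
    cat("  family genes with cross-species orthologs: ",
        x$synteny$n_family_orthologs, "\n")
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x A `genefam_report`.
#' @param ... Unused.
#' @return One-row tibble of the headline counts.
#' @export
glance.genefam_report <- function(x, ...) {
  tibble(
    n_scanned = x$counts$scanned, n_accepted = x$counts$accepted,
    n_v_and_e = length(x$v_and_e), n_v_only = length(x$v_only),
    n_subgroups = nrow(x$subgroup_counts), n_motifs = x$counts$motifs,
    n_tandem = x$counts$tandem, n_segmental = x$counts$segmental,
    n_family_orthologs = if (is.null(x$synteny)) NA_integer_ else
      x$synteny$n_family_orthologs,
    wall_time_s = x$wall_time)
}

#' Tidy the duplication table of a pipeline run
#' @param x A `genefam_report`.
#' @param ... Unused.
#' @return The dated duplication tibble.
#' @export
tidy.genefam_report <- function(x, ...) x$duplications
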