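# GFF3 <-> internal gene models.
#
# Internal convention everywhere in the package: 0-based half-open intervals.
# GFF3 files are 1-based inclusive; conversion happens only in this file.

#' Read gene models from a GFF3 file
#'
#' Expects gene / mRNA / exon (and optionally CDS) features tied together by
#' `ID=` / `Parent=` attributes, with one mRNA per gene. If a gene carries
#' several mRNAs the one with the longest summed exon length is kept with a
#' warning. Coordinates are converted from GFF3 1-based inclusive to the
#' package's 0-based half-open convention, and every gene receives a `rank`:
#' its 0-based position among all genes on its chromosome ordered by start.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `exons` (list column of two-column matrices, genomic order,
#'   0-based half-open) and `rank`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parents <- md$Parent
  parent1 <- vapply(seq_along(gr), function(i) {
    p <- parents[[i]]
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))

  genes_i <- which(type == "gene")
  if (length(genes_i) == 0) abort(paste0("no gene features in ", path))
  mrna_i <- which(type == "mRNA")
  exon_i <- which(type == "exon")
  if (any(is.na(parent1[mrna_i]))) abort("mRNA feature with missing Parent")
  if (any(is.na(parent1[exon_i]))) abort("exon feature with missing Parent")

  starts <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
  ends <- GenomicRanges::end(gr)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(GenomicRanges::strand(gr))

  models <- purrr::map(genes_i, function(gi) {
    gid <- ids[gi]
    if (is.na(gid)) abort("gene feature with missing ID")
    my_mrnas <- mrna_i[parent1[mrna_i] == gid]
    if (length(my_mrnas) == 0) abort(paste0("gene ", gid, " has no mRNA"))
    exon_len <- function(mi) {
      ei <- exon_i[parent1[exon_i] == ids[mi]]
      sum(ends[ei] - starts[ei])
    }
    if (length(my_mrnas) > 1) {
      warn(paste0("gene ", gid, " has ", length(my_mrnas),
                  " mRNAs; keeping the longest-CDS model"))
      my_mrnas <- my_mrnas[which.max(vapply(my_mrnas, exon_len, numeric(1)))]
    }
    mid <- ids[my_mrnas]
    my_exons <- exon_i[parent1[exon_i] == mid]
    if (length(my_exons) == 0) abort(paste0("mRNA ", mid, " has no exons"))
    ex <- cbind(starts[my_exons], ends[my_exons])
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (any(ex[, 1] < starts[gi]) || any(ex[, 2] > ends[gi])) {
      abort(paste0("exon outside gene span for ", gid))
    }
    if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])) {
      abort(paste0("overlapping exons in ", gid))
    }
    tibble(gene_id = gid, chromosome = chroms[gi], start = starts[gi],
           end = ends[gi], strand = strands[gi], exons = list(ex))
  })
  out <- bind_rows(models)
  if (anyDuplicated(out$gene_id)) {
    abort(paste0("duplicate gene ID: ", out$gene_id[duplicated(out$gene_id)][1]))
  }
  add_gene_ranks(out)
}

# Recompute per-chromosome 0-based ranks by start coordinate.
add_gene_ranks <- function(genes) {
  genes |>
    group_by(.data$chromosome) |>
    mutate(rank = rank(.data$start, ties.method = "first") - 1L) |>
    ungroup() |>
    arrange(.data$chromosome, .data$rank)
}

#' Write gene models to a GFF3 file
#'
#' The inverse of [read_gff3()]: emits gene, mRNA, exon and CDS features
#' (exon and CDS spans coincide; the models are CDS-only) with `ID=`/`Parent=`
#' attributes, converting back to 1-based inclusive coordinates.
#'
#' @param genes Gene-model tibble as returned by [read_gff3()].
#' @param path Output path.
#' @param chrom_lengths Optional named vector of chromosome lengths, used for
#'   the sequence-region pragma via seqinfo.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, chrom_lengths = NULL) {
  rows <- purrr::pmap(genes, function(gene_id, chromosome, start, end, strand,
                                      exons, ...) {
    mrna_id <- paste0(gene_id, ".1")
    n <- nrow(exons)
    lens <- exons[, 2] - exons[, 1]
    if (identical(strand, "-")) lens <- rev(lens)
    phase_tx <- (3L - c(0L, cumsum(lens)[-n]) %% 3L) %% 3L  # transcription order
    cds_phase <- if (identical(strand, "-")) rev(phase_tx) else phase_tx
    tibble(
      chromosome = chromosome,
      start = c(start, start, exons[, 1], exons[, 1]) + 1L,
      end = c(end, end, exons[, 2], exons[, 2]),
      strand = strand,
      type = c("gene", "mRNA", rep("exon", n), rep("CDS", n)),
      ID = c(gene_id, mrna_id, paste0(mrna_id, ".exon", seq_len(n)),
             paste0(mrna_id, ".cds", seq_len(n))),
      Parent = c(NA_character_, gene_id, rep(mrna_id, 2L * n)),
      phase = c(rep(NA_integer_, 2L + n), cds_phase)
    )
  }) |> bind_rows()
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chromosome,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand
  )
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$ID <- rows$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(rows$Parent), "", rows$Parent)
  S4Vectors::mcols(gr)$phase <- rows$phase
  if (!is.null(chrom_lengths)) {
    GenomeInfoDb::seqlengths(gr) <- chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract the coding sequence of a gene model from its chromosome sequence
#'
#' Exons are sliced from the chromosome in genomic order, concatenated, and
#' reverse-complemented for minus-strand genes.
#'
#' @param gene One row of a gene-model tibble (a list or one-row tibble with
#'   `exons` and `strand`).
#' @param chrom_seq Chromosome nucleotide sequence as a single string.
#' @return The CDS nucleotide string.
#' @export
extract_cds <- function(gene, chrom_seq) {
  ex <- gene$exons
  if (is.list(ex) && !is.matrix(ex)) ex <- ex[[1]]
  if (any(ex[, 1] < 0L) || any(ex[, 2] > nchar(chrom_seq))) {
    abort("exon outside chromosome bounds")
  }
  parts <- substring(chrom_seq, ex[, 1] + 1L, ex[, 2])
  cds <- paste(parts, collapse = "")
  strand <- gene$strand
  if (length(strand) > 1) strand <- strand[[1]]
  if (identical(strand, "-")) cds <- revcomp(cds)
  cds
}
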