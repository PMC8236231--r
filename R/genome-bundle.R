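# A genome bundle ties chromosomes, gene models, chromosome sequences and
# proteins together, with the consistency invariant translate(cds) == protein.

#' Assemble a genome bundle
#'
#' @param genome_id Genome identifier.
#' @param chromosomes Named numeric vector: chromosome name -> length (bp).
#' @param genes Gene-model tibble (see [read_gff3()]); a `cds` column is added
#'   from `chrom_seqs` if absent.
#' @param proteins Named character vector or sequence tibble of proteins,
#'   one per gene.
#' @param chrom_seqs Named character vector of chromosome sequences.
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(genome_id, chromosomes, genes, proteins,
                          chrom_seqs = NULL) {
  if (inherits(proteins, "data.frame")) proteins <- seq_vec(proteins)
  if (!all(genes$chromosome %in% names(chromosomes))) {
    bad <- setdiff(unique(genes$chromosome), names(chromosomes))
    abort(paste0("gene chromosome not in bundle: ", bad[[1]]))
  }
  if (!all(names(proteins) %in% genes$gene_id)) {
    bad <- setdiff(names(proteins), genes$gene_id)
    abort(paste0("protein without gene model: ", bad[[1]]))
  }
  if (!"cds" %in% names(genes)) {
    if (is.null(chrom_seqs)) abort("need chrom_seqs to derive CDS")
    genes$cds <- vapply(seq_len(nrow(genes)), function(i) {
      extract_cds(genes[i, ], chrom_seqs[[genes$chromosome[i]]])
    }, character(1))
  }
  structure(
    list(genome_id = genome_id, chromosomes = chromosomes, genes = genes,
         proteins = proteins, chrom_seqs = chrom_seqs),
    class = "genome_bundle"
  )
}

#' Validate a genome bundle
#'
#' Checks that every protein is the translation of its gene's CDS (terminal
#' stop stripped), that ranks are unique per chromosome, and that exon lengths
#' sum to the CDS length.
#'
#' @param bundle A `genome_bundle`.
#' @return `bundle`, invisibly; errors on the first violated invariant.
#' @export
validate_bundle <- function(bundle) {
  genes <- bundle$genes
  exlen <- vapply(genes$exons, function(e) sum(e[, 2] - e[, 1]), numeric(1))
  if (any(exlen != nchar(genes$cds))) {
    abort(paste0("exon lengths != CDS length for ",
                 genes$gene_id[exlen != nchar(genes$cds)][1]))
  }
  dup <- genes |> count(.data$chromosome, .data$rank) |> filter(n > 1)
  if (nrow(dup) > 0) abort("duplicate gene rank within a chromosome")
  for (gid in names(bundle$proteins)) {
    cds <- genes$cds[match(gid, genes$gene_id)]
    tr <- translate_cds(cds)
    if (!identical(tr, unname(bundle$proteins[[gid]]))) {
      abort(paste0("protein/CDS mismatch for ", gid))
    }
  }
  invisible(bundle)
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("<genome_bundle> ", x$genome_id, "\n",
      "  chromosomes: ", length(x$chromosomes),
      "  genes: ", nrow(x$genes),
      "  proteins: ", length(x$proteins), "\n", sep = "")
  invisible(x)
}
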