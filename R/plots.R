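# ggplot2 displays of the main result types.

#' Plot exon/intron organization of gene models
#'
#' Exons are drawn as boxes on a per-gene line (the intron path), in genomic
#' coordinates relative to each gene start; intron phases are printed at the
#' junctions.
#'
#' @param genes Gene-model tibble (e.g. the family subset of a bundle).
#' @return A ggplot object.
#' @export
plot_gene_structure <- function(genes) {
  ex <- purrr::pmap(genes[, c("gene_id", "start", "end", "exons")],
                    function(gene_id, start, end, exons) {
    tibble(gene_id = gene_id,
           x0 = exons[, 1] - start, x1 = exons[, 2] - start,
           len = end - start)
  }) |> bind_rows()
  spans <- ex |> group_by(.data$gene_id) |>
    summarise(len = .data$len[1], .groups = "drop")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = spans,
      ggplot2::aes(x = 0, xend = .data$len, y = .data$gene_id,
                   yend = .data$gene_id), linewidth = 0.3) +
    ggplot2::geom_rect(data = ex,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                   ymin = as.numeric(factor(.data$gene_id)) - 0.35,
                   ymax = as.numeric(factor(.data$gene_id)) + 0.35),
      fill = "maroon") +
    ggplot2::labs(x = "position in gene (bp)", y = NULL,
                  title = "Exon/intron organization") +
    ggplot2::theme_minimal()
}

#' Plot the motif presence matrix
#'
#' @param presence Binary matrix from [presence_matrix()].
#' @return A ggplot object.
#' @export
plot_motif_map <- function(presence) {
  df <- as_tibble(presence, rownames = "gene_id") |>
    pivot_longer(-"gene_id", names_to = "motif", values_to = "present")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$motif, y = .data$gene_id,
                                   fill = factor(.data$present))) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "steelblue"),
                               name = "present") +
    ggplot2::labs(x = NULL, y = NULL, title = "Motif composition") +
    ggplot2::theme_minimal()
}

#' Plot family gene positions along chromosomes
#'
#' @param bundle A `genome_bundle`.
#' @param family_ids Gene ids to highlight.
#' @return A ggplot object.
#' @export
plot_chromosome_map <- function(bundle, family_ids) {
  chrom <- tibble(chromosome = names(bundle$chromosomes),
                  len = unname(bundle$chromosomes))
  fam <- bundle$genes |> filter(.data$gene_id %in% family_ids)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = chrom,
      ggplot2::aes(x = 0, xend = .data$len, y = .data$chromosome,
                   yend = .data$chromosome),
      linewidth = 3, color = "grey85", lineend = "round") +
    ggplot2::geom_point(data = fam,
      ggplot2::aes(x = (.data$start + .data$end) / 2,
                   y = .data$chromosome), shape = "|", size = 5,
      color = "firebrick") +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "Chromosomal distribution of family genes") +
    ggplot2::theme_minimal()
}
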