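# Exon/intron organization and intron splicing phases.

#' Exon/intron structure and intron phases of gene models
#'
#' Introns are the gaps between consecutive exons in transcription order
#' (genomic order, reversed for minus-strand genes). The phase of intron `k`
#' is the cumulative coding length upstream of it modulo 3. Models are
#' CDS-only, so every exon base is coding.
#'
#' @param genes Gene-model tibble (one or more rows; see [read_gff3()]).
#' @return Tibble with `gene_id`, `n_exons`, `n_introns`, `intron_phases`
#'   (list column of integers) and `phases` (comma-joined string).
#' @export
gene_structure <- function(genes) {
  purrr::pmap(genes[, c("gene_id", "strand", "exons")],
              function(gene_id, strand, exons) {
    ex <- exons
    lens <- ex[, 2] - ex[, 1]
    if (identical(strand, "-")) lens <- rev(lens)
    n <- length(lens)
    phases <- if (n > 1) as.integer(cumsum(lens[-n]) %% 3L) else integer(0)
    tibble(gene_id = gene_id, n_exons = n, n_introns = n - 1L,
           intron_phases = list(phases),
           phases = paste(phases, collapse = ","))
  }) |> bind_rows()
}
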