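# Center-star progressive multiple alignment. The center sequence is the one
# maximizing summed pairwise global-alignment score; the others are merged
# against it under "once a gap, always a gap".

#' Align a protein family by the center-star method
#'
#' Deterministic: the center is the sequence with the highest summed pairwise
#' global score (ties broken by lexicographic id); pairwise alignments use
#' BLOSUM62 with affine gaps. An externally computed MSA can be supplied to
#' downstream steps instead; this aligner keeps the pipeline self-contained.
#'
#' @param proteins Sequence tibble or named character vector (>= 3 sequences).
#' @param gap_opening,gap_extension Positive gap costs.
#' @return Tibble with columns `id`, `aligned` (equal-length gapped strings),
#'   in input order.
#' @export
align_family <- function(proteins, gap_opening = 11, gap_extension = 1) {
  if (inherits(proteins, "data.frame")) proteins <- seq_vec(proteins)
  if (length(proteins) < 3) abort("alignment needs at least 3 sequences")
  ids <- names(proteins)
  clean <- gsub("[^A-Z]", "X", toupper(proteins))
  set <- Biostrings::AAStringSet(clean)
  names(set) <- ids

  total <- vapply(seq_along(set), function(i) {
    sum(Biostrings::pairwiseAlignment(
      pattern = set, subject = set[[i]], type = "global",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension,
      scoreOnly = TRUE))
  }, numeric(1))
  center_i <- order(-total, ids)[1]
  center <- clean[[center_i]]
  n_res <- nchar(center)

  others <- setdiff(seq_along(set), center_i)
  alns <- lapply(others, function(i) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = set[[i]], subject = set[[center_i]], type = "global",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension)
    list(other = as.character(Biostrings::alignedPattern(pa)),
         center = as.character(Biostrings::alignedSubject(pa)))
  })

  # g[k+1] = number of inserted columns between center residues k and k+1
  gap_runs <- function(center_aln) {
    cc <- chars(center_aln)
    isgap <- cc == "-"
    kcol <- cumsum(!isgap)
    g <- integer(n_res + 1L)
    if (any(isgap)) {
      tab <- table(kcol[isgap])
      g[as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
    g
  }
  g_list <- lapply(alns, function(a) gap_runs(a$center))
  G <- if (length(g_list) > 0) do.call(pmax, g_list) else integer(n_res + 1L)

  build_row <- function(other_aln, center_aln) {
    oc <- chars(other_aln)
    cc <- chars(center_aln)
    isgap <- cc == "-"
    kcol <- cumsum(!isgap)
    res_chars <- oc[!isgap]                  # aligned to center residues 1..n
    ins_list <- split(oc[isgap], kcol[isgap])
    pieces <- vector("list", n_res + 1L)
    for (k in 0:n_res) {
      ins <- ins_list[[as.character(k)]]
      if (is.null(ins)) ins <- character(0)
      piece <- c(ins, rep("-", G[k + 1L] - length(ins)))
      if (k < n_res) piece <- c(piece, res_chars[k + 1L])
      pieces[[k + 1L]] <- piece
    }
    paste0v(unlist(pieces))
  }
  center_row <- build_row(center, center)

  aligned <- character(length(proteins))
  aligned[center_i] <- center_row
  for (m in seq_along(others)) {
    aligned[others[m]] <- build_row(alns[[m]]$other, alns[[m]]$center)
  }
  stopifnot(length(unique(nchar(aligned))) == 1)
  tibble(id = ids, aligned = aligned)
}

# Character matrix (rows = sequences) from an MSA tibble or named vector.
msa_matrix <- function(msa) {
  if (inherits(msa, "data.frame")) {
    m <- do.call(rbind, strsplit(msa$aligned, "", fixed = TRUE))
    rownames(m) <- msa$id
  } else {
    m <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
    rownames(m) <- names(msa)
  }
  m
}
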