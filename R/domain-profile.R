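# Position-specific scoring matrix for the AP2 domain, and a glocal
# (full-profile vs. any protein substring) affine-gap scanner. The profile
# column numbering is the domain numbering used for the valine-14 /
# glutamate-19 conservation check.

#' Build a log-odds domain profile from a seed alignment
#'
#' Columns with more than 50% gaps are dropped (the retained-column mapping is
#' kept on the object). Per-column scores are
#' `log2((count + pseudocount * bg) / (total + pseudocount) / bg)` in bits.
#'
#' @param seed_aln Aligned sequences (equal lengths, gap `-`): a tibble from
#'   [read_fasta()] or a named character vector.
#' @param pseudocount Positive pseudocount mass.
#' @param background Named residue background frequencies.
#' @param gap_open,gap_extend Negative gap penalties (bits) used when scanning.
#' @return An object of class `domain_profile`.
#' @export
build_profile <- function(seed_aln, pseudocount = 1,
                          background = AA_BACKGROUND,
                          gap_open = -10, gap_extend = -1) {
  if (inherits(seed_aln, "data.frame")) seed_aln <- seq_vec(seed_aln)
  if (length(seed_aln) < 2) abort("seed alignment needs at least 2 sequences")
  lens <- nchar(seed_aln)
  if (length(unique(lens)) != 1) abort("seed alignment lengths differ")
  stopifnot(pseudocount > 0, gap_open < 0, gap_extend < 0)

  mat <- do.call(rbind, strsplit(toupper(seed_aln), "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  kept <- which(gap_frac <= 0.5)
  if (length(kept) == 0) abort("all columns are gap-dominated")
  if (length(kept) < ncol(mat)) {
    warn(paste0("dropping ", ncol(mat) - length(kept),
                " gap-dominated columns from the seed alignment"))
  }
  mat <- mat[, kept, drop = FALSE]
  bg <- background[AA_STANDARD]
  bg <- bg / sum(bg)

  lo <- t(vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col %in% AA_STANDARD]
    counts <- table(factor(col, levels = AA_STANDARD))
    total <- sum(counts)
    freq <- (as.numeric(counts) + pseudocount * bg) / (total + pseudocount)
    log2(freq / bg)
  }, numeric(length(AA_STANDARD))))
  colnames(lo) <- AA_STANDARD

  structure(
    list(log_odds = lo, n_columns = nrow(lo), background = bg,
         gap_open = gap_open, gap_extend = gap_extend, kept_columns = kept),
    class = "domain_profile"
  )
}

#' @export
print.domain_profile <- function(x, ...) {
  cat("<domain_profile> ", x$n_columns, " columns, consensus:\n  ",
      paste0(colnames(x$log_odds)[apply(x$log_odds, 1, which.max)],
             collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Tidy a domain profile into a long tibble of column scores
#'
#' @param x A `domain_profile`.
#' @param ... Unused.
#' @return Tibble with `column`, `residue`, `score` (bits).
#' @export
tidy.domain_profile <- function(x, ...) {
  lo <- x$log_odds
  tibble(
    column = rep(seq_len(nrow(lo)), times = ncol(lo)),
    residue = rep(colnames(lo), each = nrow(lo)),
    score = as.numeric(lo)
  ) |> arrange(.data$column, .data$residue)
}

#' Consensus string of a domain profile
#' @param profile A `domain_profile`.
#' @return Single string of per-column best-scoring residues.
#' @export
profile_consensus <- function(profile) {
  paste0v(colnames(profile$log_odds)[apply(profile$log_odds, 1, which.max)])
}

# Glocal affine DP against one protein string. Returns list(score, start, end,
# col_to_residue) for the best alignment, or NULL when the protein is empty.
scan_one_glocal <- function(protein, lo, go, ge) {
  n <- nrow(lo)
  L <- nchar(protein)
  if (L == 0) return(NULL)
  aa <- chars(protein)
  aa_idx <- match(aa, colnames(lo))          # NA for non-standard residues
  NEG <- -Inf

  M <- matrix(NEG, n + 1, L + 1)
  X <- matrix(NEG, n + 1, L + 1)
  Y <- matrix(NEG, n + 1, L + 1)
  M[1, ] <- 0                                 # free start anywhere in query
  i_off <- 0:(n - 1)                          # i-1 for i = 1..n
  # column j = 0
  Y[2:(n + 1), 1] <- go + i_off * ge
  for (j in seq_len(L)) {
    cur <- j + 1L
    prv <- j
    qs <- if (is.na(aa_idx[j])) numeric(n) else lo[, aa_idx[j]]
    diag <- pmax(M[1:n, prv], X[1:n, prv], Y[1:n, prv])
    M[2:(n + 1), cur] <- qs + diag
    if (n > 1) {
      rows <- 2:n                             # insert states between cols
      X[rows, cur] <- pmax(M[rows, prv] + go, X[rows, prv] + ge)
    }
    A <- M[1:n, cur] - i_off * ge
    Y[2:(n + 1), cur] <- go + i_off * ge + cummax(A)
  }

  endM <- M[n + 1, ]
  endY <- Y[n + 1, ]
  best <- max(endM, endY)
  j_end <- if (max(endM) >= max(endY)) which.max(endM) - 1L else which.max(endY) - 1L
  state <- if (max(endM) >= max(endY)) "M" else "Y"

  eps <- 1e-9
  col_res <- rep("-", n)
  i <- n; j <- j_end
  while (i > 0) {
    ri <- i + 1L; cj <- j + 1L
    if (state == "M") {
      col_res[i] <- aa[j]
      v <- M[ri, cj] - (if (is.na(aa_idx[j])) 0 else lo[i, aa_idx[j]])
      pr <- j                                  # matrix column for (j-1)
      if (abs(M[ri - 1L, pr] - v) < eps) state <- "M"
      else if (abs(Y[ri - 1L, pr] - v) < eps) state <- "Y"
      else state <- "X"
      i <- i - 1L; j <- j - 1L
    } else if (state == "Y") {
      col_res[i] <- "-"
      if (abs(Y[ri, cj] - (M[ri - 1L, cj] + go)) < eps) state <- "M" else state <- "Y"
      i <- i - 1L
    } else {                                   # X: query insertion
      if (abs(X[ri, cj] - (M[ri, cj - 1L] + go)) < eps) state <- "M" else state <- "X"
      j <- j - 1L
    }
  }
  j_start <- j
  list(score = best, start = j_start, end = j_end,
       col_to_residue = setNames(col_res, seq_len(n)))
}

#' Scan a protein for domain hits with a profile
#'
#' Glocal dynamic programming: the full profile is aligned against any
#' substring of the protein, with affine gaps on both sides. All
#' non-overlapping hits scoring at least `bit_threshold` are reported,
#' best-first (greedy masking of previous hit spans).
#'
#' @param protein A single protein string, or a one-row sequence tibble.
#' @param profile A `domain_profile`.
#' @param bit_threshold Minimum reported score in bits.
#' @param protein_id Identifier attached to the hits.
#' @return Tibble with columns `protein_id`, `start`, `end` (0-based
#'   half-open), `score`, `residue14`, `residue19` and a `col_to_residue`
#'   list column mapping profile columns to residues (`-` for deletions).
#' @export
scan_domain <- function(protein, profile, bit_threshold = 25,
                        protein_id = NULL) {
  if (inherits(protein, "data.frame")) {
    if (is.null(protein_id)) protein_id <- protein$id[[1]]
    protein <- protein$residues[[1]]
  }
  if (is.null(protein_id)) protein_id <- "query"
  if (nchar(protein) == 0) abort("empty protein")
  lo <- profile$log_odds
  go <- profile$gap_open
  ge <- profile$gap_extend

  hits <- list()
  # (offset, segment) queue: rescan the flanks of each accepted hit
  queue <- list(list(off = 0L, seq = protein))
  while (length(queue) > 0) {
    seg <- queue[[1]]; queue <- queue[-1]
    if (nchar(seg$seq) < 1) next
    h <- scan_one_glocal(seg$seq, lo, go, ge)
    if (is.null(h) || h$score < bit_threshold) next
    # degenerate all-deletion alignments carry no query span; drop them
    if (h$end <= h$start) next
    hits[[length(hits) + 1]] <- tibble(
      protein_id = protein_id,
      start = seg$off + h$start, end = seg$off + h$end,
      score = h$score,
      residue14 = if (length(h$col_to_residue) >= 14)
        unname(h$col_to_residue[[14]]) else NA_character_,
      residue19 = if (length(h$col_to_residue) >= 19)
        unname(h$col_to_residue[[19]]) else NA_character_,
      col_to_residue = list(h$col_to_residue)
    )
    left <- substr(seg$seq, 1L, h$start)
    right <- substr(seg$seq, h$end + 1L, nchar(seg$seq))
    if (nchar(left) > 0) queue[[length(queue) + 1]] <- list(off = seg$off, seq = left)
    if (nchar(right) > 0) queue[[length(queue) + 1]] <- list(off = seg$off + h$end, seq = right)
  }
  if (length(hits) == 0) {
    return(tibble(protein_id = character(), start = integer(), end = integer(),
                  score = numeric(), residue14 = character(),
                  residue19 = character(), col_to_residue = list()))
  }
  bind_rows(hits) |> arrange(desc(.data$score))
}
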