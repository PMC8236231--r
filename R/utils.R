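# Small shared helpers. Internal only.

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

paste0v <- function(x) paste(x, collapse = "")

#' Reverse-complement a nucleotide string
#'
#' @param x A nucleotide string over A, C, G, T, N.
#' @return The reverse complement as a single string.
#' @export
#' @examples
#' revcomp("CAT")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Canonical unordered pair order: id_a < id_b lexicographically.
canonical_pair <- function(a, b) {
  swap <- a > b
  tibble(id_a = ifelse(swap, b, a), id_b = ifelse(swap, a, b))
}

# Stable integer sub-seed derived from a master seed; keeps values < 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + (as.integer(k) %% 1000L)
}

# Validate a sequence tibble (id, description, residues) per record rules.
check_seq_tbl <- function(x, what = "sequence set") {
  if (!all(c("id", "residues") %in% names(x))) {
    abort(paste0(what, " must have columns id and residues"))
  }
  if (any(x$id == "" | is.na(x$id))) abort(paste0(what, ": empty id"))
  dup <- x$id[duplicated(x$id)]
  if (length(dup) > 0) {
    abort(paste0(what, ": duplicate id '", dup[[1]], "'"))
  }
  if (any(nchar(x$residues) == 0L)) {
    bad <- x$id[nchar(x$residues) == 0L][[1]]
    abort(paste0(what, ": empty sequence for id '", bad, "'"))
  }
  invisible(x)
}

# Named character vector from a sequence tibble.
seq_vec <- function(x) setNames(x$residues, x$id)

seq_tbl <- function(ids, residues, description = "") {
  tibble(id = ids, description = description, residues = unname(residues))
}
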