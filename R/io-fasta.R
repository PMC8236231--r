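#' Read a FASTA file into a tibble of sequence records
#'
#' Wrapped lines are joined; the record id is the first whitespace token of the
#' header and the remainder becomes the description. Ids must be unique and
#' sequences non-empty.
#'
#' @param path Path to a plain-text FASTA file.
#' @return A tibble with columns `id`, `description`, `residues`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- tibble(id = ids, description = desc,
                residues = unname(toupper(as.character(set))))
  check_seq_tbl(out, paste0("FASTA '", path, "'"))
  out
}

#' Write sequence records to a FASTA file
#'
#' Lines are wrapped at 60 characters. Accepts either a tibble as returned by
#' [read_fasta()] or a named character vector.
#'
#' @param seqs Tibble with `id`, `residues` (and optional `description`), or a
#'   named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- seq_tbl(names(seqs), seqs)
  }
  if (!"description" %in% names(seqs)) seqs$description <- ""
  check_seq_tbl(seqs, "write_fasta input")
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- ifelse(seqs$description == "", seqs$id,
                       paste(seqs$id, seqs$description))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Translate a coding sequence to protein
#'
#' Uses the standard genetic code. A single terminal stop codon is stripped;
#' an internal stop codon is an error, as is a length that is not a multiple
#' of three.
#'
#' @param cds Nucleotide string (A/C/G/T), length a multiple of 3.
#' @return Protein string (possibly empty).
#' @export
#' @examples
#' translate_cds("ATGAAATAG")
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  n <- nchar(cds)
  if (n == 0L) return("")
  if (n %% 3L != 0L) {
    abort(paste0("CDS length ", n, " is not a multiple of 3"))
  }
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(genetic_code()[codons])
  if (anyNA(aa)) {
    abort(paste0("CDS contains an untranslatable codon: ",
                 codons[which(is.na(aa))[1]]))
  }
  stops <- which(aa == "*")
  if (length(stops) > 0) {
    if (length(stops) > 1L || stops[1] != length(aa)) {
      abort(paste0("internal stop codon at codon ", stops[1]))
    }
    aa <- aa[-length(aa)]
  }
  paste0v(aa)
}
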