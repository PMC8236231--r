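#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_dbl map_int map_lgl map2 pmap imap keep
#' @importFrom tidyr unnest pivot_longer pivot_wider
#' @importFrom stats setNames median runif rexp rbinom
#' @importFrom utils head tail combn read.delim write.table
NULL

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average residue masses in Daltons (monoisotopic not used; these are the
# average masses common protein calculators sum, plus one water per chain).
AA_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Bjellqvist-style pKa values used by common web pI calculators.
# Charge model: N-terminus + K, R, H positive; C-terminus + D, E, C, Y negative.
PKA_DEFAULT <- list(
  nterm = 7.50, cterm = 3.55,
  side = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00,
           H = 5.98, K = 10.00, R = 12.00)
)

# Background amino-acid frequencies (Swiss-Prot-like composition), used as the
# default null model for profile and motif log-odds scores.
AA_BACKGROUND <- c(
  A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
  E = 0.0672, Q = 0.0393, G = 0.0708, H = 0.0227, I = 0.0593,
  L = 0.0965, K = 0.0580, M = 0.0241, F = 0.0386, P = 0.0472,
  S = 0.0664, T = 0.0534, W = 0.0110, Y = 0.0292, V = 0.0686
)

# Ungapped Karlin-Altschul parameters for BLOSUM62 (raw-score scale),
# the classic values used by gapped heuristics for E-value reporting.
KA_LAMBDA_BLOSUM62 <- 0.3176
KA_K_BLOSUM62 <- 0.134

# Substitution rate used for divergence dating, substitutions/site/year.
CLOCK_RATE <- 6.56e-9

BASES <- c("A", "C", "G", "T")

genetic_code <- function() Biostrings::GENETIC_CODE

codons_all <- function() {
  gc <- genetic_code()
  names(gc)
}

codons_sense <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

is_stop_codon <- function(codon) {
  genetic_code()[codon] == "*"
}
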