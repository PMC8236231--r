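# Nei-Gojobori (1986) synonymous/nonsynonymous rates with Jukes-Cantor
# correction, codon-aware pairwise alignment expansion, and molecular-clock
# divergence dating.

# --- codon bookkeeping -------------------------------------------------------

# Fractional synonymous sites of one codon: per position, the fraction of the
# three single-base changes that are synonymous; changes creating stop codons
# count as nonsynonymous, so s + n = 3 exactly.
codon_syn_sites <- function(codon) {
  gc <- genetic_code()
  aa <- gc[[codon]]
  b <- chars(codon)
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(BASES, b[pos])) {
      nb <- b; nb[pos] <- alt
      nc <- paste0v(nb)
      if (gc[[nc]] != "*" && gc[[nc]] == aa) s <- s + 1 / 3
    }
  }
  s
}

.ng_env <- new.env(parent = emptyenv())

syn_sites_table <- function() {
  if (is.null(.ng_env$sites)) {
    cods <- codons_sense()
    .ng_env$sites <- setNames(vapply(cods, codon_syn_sites, numeric(1)), cods)
  }
  .ng_env$sites
}

# Pathway-averaged synonymous/nonsynonymous differences between two sense
# codons: enumerate all orders of the differing positions, drop pathways that
# pass through a stop codon, average step classifications over valid paths.
codon_pair_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng_env$pairs[[key]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code()
  b1 <- chars(c1); b2 <- chars(c2)
  dpos <- which(b1 != b2)
  k <- length(dpos)
  res <- c(sd = 0, nd = 0)
  if (k > 0) {
    orders <- switch(k,
      list(dpos),
      list(dpos, rev(dpos)),
      {
        perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
        lapply(perms, function(p) dpos[p])
      })
    tot_sd <- 0; tot_nd <- 0; valid <- 0
    for (ord in orders) {
      cur <- b1
      sd <- 0; nd <- 0; ok <- TRUE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- b2[pos]
        a_cur <- gc[[paste0v(cur)]]
        a_nxt <- gc[[paste0v(nxt)]]
        if (a_nxt == "*") { ok <- FALSE; break }
        if (a_nxt == a_cur) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { tot_sd <- tot_sd + sd; tot_nd <- tot_nd + nd; valid <- valid + 1 }
    }
    if (valid == 0) {
      abort(paste0("all substitution pathways between ", c1, " and ", c2,
                   " pass through stop codons"))
    }
    res <- c(sd = tot_sd / valid, nd = tot_nd / valid)
  }
  if (is.null(.ng_env$pairs)) .ng_env$pairs <- new.env(parent = emptyenv())
  assign(key, res, envir = .ng_env$pairs)
  res
}

# --- codon alignment ---------------------------------------------------------

#' Expand a protein alignment to a codon alignment
#'
#' Each aligned residue becomes its codon, each protein gap a `---` codon.
#' The degapped translations must equal the CDS translations (a terminal stop
#' codon on either CDS is tolerated and stripped).
#'
#' @param prot_aln_a,prot_aln_b Gapped aligned protein strings (equal length).
#' @param cds_a,cds_b Nucleotide coding sequences.
#' @param id_a,id_b Ids used in error messages.
#' @return List with `codon_a`, `codon_b` (gapped codon strings, equal
#'   lengths, multiples of 3).
#' @export
codon_align <- function(prot_aln_a, prot_aln_b, cds_a, cds_b,
                        id_a = "a", id_b = "b") {
  if (nchar(prot_aln_a) != nchar(prot_aln_b)) {
    abort("aligned protein strings differ in length")
  }
  expand <- function(aln, cds, id) {
    n <- nchar(cds)
    if (n %% 3L != 0L) abort(paste0("CDS length not multiple of 3 for ", id))
    codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
    if (length(codons) > 0 && is_stop_codon(codons[length(codons)])) {
      codons <- codons[-length(codons)]
    }
    res <- chars(aln)
    stopifnot(all(res %in% c(AA_STANDARD, "-", "X")))
    need <- sum(res != "-")
    if (need != length(codons)) {
      abort(paste0("protein alignment does not match CDS for ", id,
                   " (", need, " residues vs ", length(codons), " codons)"))
    }
    tr <- translate_cds(paste0v(codons))
    if (tr != paste0v(res[res != "-"])) {
      abort(paste0("CDS translation mismatch for ", id))
    }
    out <- character(length(res))
    out[res == "-"] <- "---"
    out[res != "-"] <- codons
    paste0v(out)
  }
  list(codon_a = expand(prot_aln_a, cds_a, id_a),
       codon_b = expand(prot_aln_b, cds_b, id_b))
}

# --- NG86 --------------------------------------------------------------------

#' Nei-Gojobori (1986) Ka/Ks for a pairwise codon alignment
#'
#' Synonymous sites are counted fractionally per codon position and averaged
#' between the two sequences; differences between codons differing at several
#' positions are averaged over all substitution pathways that avoid stop
#' codons. Proportions are Jukes-Cantor corrected,
#' `d = -(3/4) ln(1 - (4/3) p)`. Codon pairs with a gap on either side are
#' excluded entirely.
#'
#' @param ca Codon alignment from [codon_align()] (list with `codon_a`,
#'   `codon_b`), or two gapped codon strings.
#' @param codon_b Second codon string when `ca` is given as a string.
#' @return One-row tibble: `ka`, `ks`, `omega` (`NA` when `ks` is 0), `S`,
#'   `N`, `Sd`, `Nd`, `n_codons`.
#' @export
ng86 <- function(ca, codon_b = NULL) {
  if (is.list(ca)) {
    a <- ca$codon_a; b <- ca$codon_b
  } else {
    a <- ca; b <- codon_b
  }
  if (nchar(a) != nchar(b) || nchar(a) %% 3L != 0L) {
    abort("codon alignment strings must have equal length, multiple of 3")
  }
  n <- nchar(a)
  ca_ <- substring(a, seq(1L, n, 3L), seq(3L, n, 3L))
  cb_ <- substring(b, seq(1L, n, 3L), seq(3L, n, 3L))
  keep <- !grepl("-", ca_, fixed = TRUE) & !grepl("-", cb_, fixed = TRUE)
  ca_ <- ca_[keep]; cb_ <- cb_[keep]
  if (length(ca_) == 0) abort("no ungapped codon pairs")
  if (any(is_stop_codon(ca_)) || any(is_stop_codon(cb_))) {
    abort("stop codon inside the alignment")
  }
  st <- syn_sites_table()
  S <- sum((st[ca_] + st[cb_]) / 2)
  N <- 3 * length(ca_) - S
  diffs <- vapply(seq_along(ca_), function(i) codon_pair_diffs(ca_[i], cb_[i]),
                  numeric(2))
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  jc <- function(p, what) {
    if (p >= 3 / 4) abort(paste0(what, " proportion ", signif(p, 4),
                                 " >= 3/4: Jukes-Cantor correction undefined"))
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  ks <- jc(pS, "synonymous")
  ka <- jc(pN, "nonsynonymous")
  tibble(ka = ka, ks = ks, omega = if (ks > 0) ka / ks else NA_real_,
         S = S, N = N, Sd = Sd, Nd = Nd, n_codons = length(ca_))
}

#' Divergence time from a synonymous rate
#'
#' `T = Ks / (2 x) * 1e-6` million years, with the clock rate
#' `x = 6.56e-9` substitutions per synonymous site per year.
#'
#' @param ks Synonymous substitutions per synonymous site (vectorized).
#' @param rate Clock rate in substitutions/site/year.
#' @return Divergence time(s) in million years (MYA).
#' @export
#' @examples
#' divergence_time(0.1312)  # 10 MYA
divergence_time <- function(ks, rate = CLOCK_RATE) {
  if (any(ks < 0)) abort("negative Ks")
  ks / (2 * rate) / 1e6
}
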