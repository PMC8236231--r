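# Independent brute-force oracles. These deliberately share no code with the
# package implementation: sites and pathway averages are recomputed from
# first principles by explicit enumeration.

oracle_codon_table <- function() Biostrings::GENETIC_CODE

# synonymous site count of one codon by explicit neighbor enumeration;
# changes to stop codons count as nonsynonymous (so s + n = 3)
oracle_sites <- function(codon) {
  gc <- oracle_codon_table()
  bases <- c("A", "C", "G", "T")
  b <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (alt in bases) {
      if (alt == b[pos]) next
      nb <- b
      nb[pos] <- alt
      nc <- paste(nb, collapse = "")
      if (gc[[nc]] != "*" && gc[[nc]] == gc[[codon]]) syn <- syn + 1
    }
  }
  syn / 3
}

# recursive enumeration of all substitution orders between two codons,
# dropping any pathway that visits a stop codon
oracle_paths <- function(from, to) {
  gc <- oracle_codon_table()
  b1 <- strsplit(from, "")[[1]]
  b2 <- strsplit(to, "")[[1]]
  walk <- function(cur, left) {
    if (length(left) == 0) return(list(c(sd = 0, nd = 0)))
    out <- list()
    for (k in seq_along(left)) {
      pos <- left[k]
      nxt <- cur
      nxt[pos] <- b2[pos]
      ncod <- paste(nxt, collapse = "")
      if (gc[[ncod]] == "*") next
      step_syn <- gc[[ncod]] == gc[[paste(cur, collapse = "")]]
      rest <- walk(nxt, left[-k])
      for (r in rest) {
        out[[length(out) + 1]] <-
          r + if (step_syn) c(sd = 1, nd = 0) else c(sd = 0, nd = 1)
      }
    }
    out
  }
  walk(b1, setdiff(which(b1 != b2), integer(0)))
}

oracle_pair_diffs <- function(from, to) {
  if (from == to) return(c(sd = 0, nd = 0))
  paths <- oracle_paths(from, to)
  if (length(paths) == 0) stop("no stop-free pathway")
  Reduce(`+`, paths) / length(paths)
}

# full NG86 from the oracle primitives
oracle_ng86 <- function(cds_a, cds_b) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split3(cds_a)
  cb <- split3(cds_b)
  S <- sum((vapply(ca, oracle_sites, numeric(1)) +
            vapply(cb, oracle_sites, numeric(1))) / 2)
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i) oracle_pair_diffs(ca[i], cb[i]),
              numeric(2))
  Sd <- sum(d["sd", ])
  Nd <- sum(d["nd", ])
  jc <- function(p) {
    if (p >= 3 / 4) stop("saturated: correction undefined")
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  c(ka = jc(if (N > 0) Nd / N else 0), ks = jc(if (S > 0) Sd / S else 0),
    S = S, N = N, Sd = Sd, Nd = Nd)
}

# exhaustive 4-taxon oracle: fit branch lengths for each of the three
# unrooted topologies by solving the linear path-length system; the additive
# matrix fits exactly on the true topology only
oracle_nj4 <- function(dm) {
  labs <- rownames(dm)
  splits <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  best <- NULL
  for (sp in splits) {
    a <- sp[1]; b <- sp[2]; c_ <- sp[3]; d <- sp[4]
    # unknowns: la, lb, lc, ld, internal m
    A <- rbind(
      c(1, 1, 0, 0, 0),   # d(a,b)
      c(1, 0, 1, 0, 1),   # d(a,c)
      c(1, 0, 0, 1, 1),   # d(a,d)
      c(0, 1, 1, 0, 1),   # d(b,c)
      c(0, 1, 0, 1, 1),   # d(b,d)
      c(0, 0, 1, 1, 0))   # d(c,d)
    y <- c(dm[a, b], dm[a, c_], dm[a, d], dm[b, c_], dm[b, d], dm[c_, d])
    fit <- qr.solve(A, y)
    resid <- max(abs(A %*% fit - y))
    if (is.null(best) || resid < best$resid) {
      best <- list(split = labs[sp], lengths = fit, resid = resid)
    }
  }
  best
}

# additive distance matrix from a random unrooted tree (ape is the
# independent tree machinery here, never the implementation under test)
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
  dm <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(dm))
  list(tree = tr, dm = dm[ord, ord])
}
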