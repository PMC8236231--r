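# Codon-level sequence evolution used by the synthetic-data generator:
# a stop-excluding, omega-scaled substitution scheme in which every
# single-base synonymous change has rate 1/3 and every nonsynonymous change
# rate omega/3 per unit time. With sites counted the NG86 way this makes one
# time unit equal one expected synonymous substitution per synonymous site,
# so a pair separated by total time Ks has expected synonymous divergence Ks.

.evo_env <- new.env(parent = emptyenv())

codon_neighbors <- function() {
  if (!is.null(.evo_env$nb)) return(.evo_env$nb)
  gc <- genetic_code()
  nb <- lapply(codons_sense(), function(cod) {
    b <- chars(cod)
    out_c <- character(0); out_s <- logical(0)
    for (pos in 1:3) {
      for (alt in setdiff(BASES, b[pos])) {
        nbv <- b; nbv[pos] <- alt
        nc <- paste0v(nbv)
        if (gc[[nc]] == "*") next
        out_c <- c(out_c, nc)
        out_s <- c(out_s, gc[[nc]] == gc[[cod]])
      }
    }
    list(codons = out_c, syn = out_s)
  })
  names(nb) <- codons_sense()
  .evo_env$nb <- nb
  nb
}

# Gillespie simulation per codon for total time t (uses the current RNG).
evolve_codons <- function(codons, t, omega) {
  if (t <= 0) return(codons)
  nb <- codon_neighbors()
  for (i in seq_along(codons)) {
    cur <- codons[i]
    rem <- t
    repeat {
      info <- nb[[cur]]
      if (length(info$codons) == 0) break
      rates <- ifelse(info$syn, 1 / 3, omega / 3)
      tot <- sum(rates)
      if (tot <= 0) break
      tau <- rexp(1, tot)
      if (tau > rem) break
      rem <- rem - tau
      cur <- info$codons[sample.int(length(rates), 1, prob = rates / tot)]
    }
    codons[i] <- cur
  }
  codons
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) abort("CDS length not a multiple of 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Evolve one lineage of a stop-free CDS for time t (expected synonymous
# substitutions per synonymous site). Uses the current RNG state.
evolve_cds <- function(cds, t, omega) {
  cod <- split_codons(cds)
  if (any(is_stop_codon(cod))) abort("ancestor CDS contains a stop codon")
  paste0v(evolve_codons(cod, t, omega))
}

#' Evolve a duplicate codon-sequence pair to a target synonymous divergence
#'
#' Both descendants evolve independently from the ancestor for time
#' `target_ks / 2` under the stop-excluding omega-scaled substitution scheme,
#' so the pair's expected synonymous divergence is `target_ks` (split equally
#' across the two lineages) and the expected Ka/Ks is `omega`. No stop codons
#' can be introduced.
#'
#' @param ancestor_cds Stop-free coding sequence, length a multiple of 3.
#' @param target_ks Target pairwise synonymous divergence (>= 0; values of 3
#'   or more would saturate beyond the Jukes-Cantor correction and are
#'   rejected with advice to use a smaller Ks).
#' @param omega Target Ka/Ks ratio (> 0).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return List with `cds_a`, `cds_b`.
#' @export
evolve_codon_pair <- function(ancestor_cds, target_ks, omega, seed) {
  if (target_ks < 0) abort("target_ks must be >= 0")
  if (target_ks >= 3) {
    abort(paste0("target_ks = ", target_ks, " would saturate synonymous ",
                 "sites (expected p_s >= 3/4); use a smaller Ks"))
  }
  if (omega < 0) abort("omega must be >= 0")
  if (target_ks == 0) {
    return(list(cds_a = ancestor_cds, cds_b = ancestor_cds))
  }
  withr::with_seed(seed, {
    list(cds_a = evolve_cds(ancestor_cds, target_ks / 2, omega),
         cds_b = evolve_cds(ancestor_cds, target_ks / 2, omega))
  })
}

#' Plant a motif consensus into a protein window
#'
#' The window starting at `offset` (0-based) is replaced by the consensus;
#' each column is then independently corrupted with probability `noise`
#' (replaced by a uniformly drawn different residue). Uses the current RNG.
#'
#' @param protein Protein string.
#' @param motif_consensus Ungapped consensus string (the motif).
#' @param offset 0-based start of the planted window.
#' @param noise Corruption probability per column, in `[0, 1)`.
#' @return The modified protein string.
#' @export
plant_motif <- function(protein, motif_consensus, offset, noise = 0) {
  w <- nchar(motif_consensus)
  if (noise < 0 || noise >= 1) abort("noise must be in [0, 1)")
  if (offset < 0 || offset + w > nchar(protein)) {
    abort("motif window out of bounds")
  }
  aa <- chars(protein)
  mot <- chars(motif_consensus)
  hit <- runif(w) < noise
  for (t in which(hit)) {
    mot[t] <- sample(setdiff(AA_STANDARD, mot[t]), 1)
  }
  aa[(offset + 1):(offset + w)] <- mot
  paste0v(aa)
}

# Uniform synonymous reverse translation of a protein (current RNG).
reverse_translate <- function(protein) {
  gc <- genetic_code()
  by_aa <- split(names(gc), gc)
  aa <- chars(protein)
  bad <- setdiff(aa, AA_STANDARD)
  if (length(bad) > 0) abort(paste0("cannot reverse-translate residue ", bad[[1]]))
  paste0v(vapply(aa, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1)))
}

# Re-encode a CDS so it translates to new_prot: positions whose residue
# changed get a fresh uniformly drawn synonymous codon (current RNG).
apply_protein_edits <- function(cds, new_prot) {
  cod <- split_codons(cds)
  old <- chars(translate_cds(cds))
  new <- chars(new_prot)
  stopifnot(length(old) == length(new))
  gc <- genetic_code()
  by_aa <- split(names(gc), gc)
  for (i in which(old != new)) {
    opts <- by_aa[[new[i]]]
    cod[i] <- opts[sample.int(length(opts), 1)]
  }
  paste0v(cod)
}
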