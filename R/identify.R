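# Family identification: homology candidate search with Karlin-Altschul
# E-values, the single-domain V14/E19 conservation filter, and
# physicochemical profiling.

#' Homology candidate search with E-value cutoff
#'
#' Local alignment (BLOSUM62, affine gaps) of every query against every
#' target; the E-value uses the ungapped Karlin-Altschul form
#' `E = K * m * n * exp(-lambda * S)` on the raw score `S`. A target is kept
#' when any query reaches `E <= evalue_cutoff`.
#'
#' @param queries,targets Sequence tibbles ([read_fasta()]) or named vectors.
#' @param evalue_cutoff E-value threshold (default `1e-5`).
#' @param gap_opening,gap_extension Positive gap costs for the local aligner.
#' @param lambda,K Karlin-Altschul parameters for the scoring system.
#' @return Tibble of kept targets: `target_id`, `best_query`, `score`
#'   (raw), `evalue`.
#' @export
candidate_search <- function(queries, targets, evalue_cutoff = 1e-5,
                             gap_opening = 11, gap_extension = 1,
                             lambda = KA_LAMBDA_BLOSUM62,
                             K = KA_K_BLOSUM62) {
  if (inherits(queries, "data.frame")) queries <- seq_vec(queries)
  if (inherits(targets, "data.frame")) targets <- seq_vec(targets)
  if (length(queries) == 0 || length(targets) == 0) {
    abort("candidate_search needs non-empty query and target sets")
  }
  tset <- Biostrings::AAStringSet(gsub("[^A-Z]", "X", toupper(targets)))
  names(tset) <- names(targets)
  m <- nchar(targets)

  best_score <- rep(-Inf, length(targets))
  best_query <- rep(NA_character_, length(targets))
  best_e <- rep(Inf, length(targets))
  for (qi in seq_along(queries)) {
    q <- Biostrings::AAString(gsub("[^A-Z]", "X", toupper(queries[[qi]])))
    sc <- Biostrings::pairwiseAlignment(
      pattern = tset, subject = q, type = "local",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension,
      scoreOnly = TRUE
    )
    sc <- pmax(sc, 0)
    ev <- K * m * nchar(queries[[qi]]) * exp(-lambda * sc)
    upd <- ev < best_e
    best_e[upd] <- ev[upd]
    best_score[upd] <- sc[upd]
    best_query[upd] <- names(queries)[qi]
  }
  keep <- best_e <= evalue_cutoff
  tibble(target_id = names(targets)[keep], best_query = best_query[keep],
         score = best_score[keep], evalue = best_e[keep]) |>
    arrange(.data$evalue)
}

#' Apply the single-domain valine-14 (and glutamate-19) filter
#'
#' A protein is accepted if and only if it carries exactly one domain hit and
#' that hit has valine at profile column 14. Accepted proteins are
#' partitioned by whether column 19 is glutamate. Rejection reasons are
#' `no_domain`, `multiple_domains`, or `not_V14` (a gap at column 14 counts
#' as not-V).
#'
#' @param hits_by_protein Named list: protein id -> hit tibble from
#'   [scan_domain()]. Proteins with zero rows count as scanned.
#' @return List with `accepted`, `v_and_e`, `v_only` (character vectors) and
#'   `rejected` (tibble `protein_id`, `reason`).
#' @export
filter_dreb <- function(hits_by_protein) {
  res <- imap(hits_by_protein, function(h, pid) {
    n <- if (is.null(h)) 0L else nrow(h)
    if (n == 0L) return(tibble(protein_id = pid, status = "no_domain"))
    if (n > 1L) return(tibble(protein_id = pid, status = "multiple_domains"))
    r14 <- h$residue14[[1]]
    r19 <- h$residue19[[1]]
    if (is.na(r14) || r14 != "V") {
      return(tibble(protein_id = pid, status = "not_V14"))
    }
    status <- if (!is.na(r19) && r19 == "E") "v_and_e" else "v_only"
    tibble(protein_id = pid, status = status)
  }) |> bind_rows()
  accepted <- res$protein_id[res$status %in% c("v_and_e", "v_only")]
  list(
    accepted = accepted,
    v_and_e = res$protein_id[res$status == "v_and_e"],
    v_only = res$protein_id[res$status == "v_only"],
    rejected = res |> filter(!.data$status %in% c("v_and_e", "v_only")) |>
      rename(reason = "status")
  )
}

# Net charge of a peptide at a given pH under the packaged pKa model.
net_charge <- function(counts, nterm, cterm, pH, pka = PKA_DEFAULT) {
  pos_groups <- c(nterm = nterm, counts["K"], counts["R"], counts["H"])
  pos_pka <- c(pka$nterm, pka$side[c("K", "R", "H")])
  neg_groups <- c(cterm = cterm, counts["D"], counts["E"],
                  counts["C"], counts["Y"])
  neg_pka <- c(pka$cterm, pka$side[c("D", "E", "C", "Y")])
  sum(pos_groups / (1 + 10^(pH - pos_pka))) -
    sum(neg_groups / (1 + 10^(neg_pka - pH)))
}

#' Physicochemical properties: length, molecular weight, isoelectric point
#'
#' Molecular weight is the sum of average residue masses plus one water.
#' The pI is the unique root of the net-charge curve, found by bisection on
#' pH 0-14 to `|charge| < 1e-4`; the charge model uses Bjellqvist-style pKa
#' values for the termini and the D, E, C, Y, H, K, R side chains.
#'
#' @param protein Protein string or sequence tibble (may have several rows).
#' @param pka pKa table (list with `nterm`, `cterm`, `side`).
#' @return Tibble with `id` (if available), `length`, `mw` (Da), `pi`.
#' @export
physchem <- function(protein, pka = PKA_DEFAULT) {
  if (inherits(protein, "data.frame")) {
    return(bind_rows(lapply(seq_len(nrow(protein)), function(i) {
      physchem(protein$residues[[i]], pka) |>
        mutate(id = protein$id[[i]], .before = 1)
    })))
  }
  stopifnot(is.character(protein), length(protein) == 1L, nchar(protein) > 0)
  aa <- chars(toupper(protein))
  if (!all(aa %in% AA_STANDARD)) {
    abort(paste0("non-standard residue: ", setdiff(aa, AA_STANDARD)[[1]]))
  }
  counts <- table(factor(aa, levels = AA_STANDARD))
  counts <- setNames(as.numeric(counts), AA_STANDARD)
  mw <- sum(counts * AA_MASS[AA_STANDARD]) + WATER_MASS

  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    ch <- net_charge(counts, 1, 1, mid, pka)
    if (abs(ch) < 1e-4 || (hi - lo) < 1e-12) break
    if (ch > 0) lo <- mid else hi <- mid
  }
  tibble(length = length(aa), mw = mw, pi = mid)
}

#' Identify family members in a proteome
#'
#' Runs the full identification stage: homology candidate search against the
#' reference queries, a domain-profile scan of every candidate, the
#' single-domain V14/E19 filter, and physicochemical profiling of the
#' accepted proteins.
#'
#' @param proteome Sequence tibble of target proteins.
#' @param queries Sequence tibble of reference (query) proteins.
#' @param profile A `domain_profile` from [build_profile()].
#' @param evalue_cutoff Homology E-value threshold.
#' @param bit_threshold Domain-scan score threshold (bits).
#' @return List with `table` (one row per scanned candidate: `gene_id`,
#'   `n_domains`, `domain_span`, `residue14`, `residue19`, `status`,
#'   `length`, `mw`, `pi`), `accepted`, `v_and_e`, `v_only`, `rejected`,
#'   `hits` and `candidates`.
#' @export
identify_family <- function(proteome, queries, profile,
                            evalue_cutoff = 1e-5, bit_threshold = 25) {
  check_seq_tbl(proteome, "proteome")
  cand <- candidate_search(queries, proteome, evalue_cutoff = evalue_cutoff)
  cand_ids <- cand$target_id
  pvec <- seq_vec(proteome)
  hits <- lapply(setNames(cand_ids, cand_ids), function(id) {
    scan_domain(pvec[[id]], profile, bit_threshold = bit_threshold,
                protein_id = id)
  })
  flt <- filter_dreb(hits)

  rows <- lapply(cand_ids, function(id) {
    h <- hits[[id]]
    status <- if (id %in% flt$v_and_e) "v_and_e"
      else if (id %in% flt$v_only) "v_only"
      else flt$rejected$reason[match(id, flt$rejected$protein_id)]
    span <- if (nrow(h) >= 1) paste0(h$start[[1]], "-", h$end[[1]]) else NA
    pc <- if (id %in% flt$accepted) physchem(pvec[[id]])
          else tibble(length = NA_integer_, mw = NA_real_, pi = NA_real_)
    tibble(gene_id = id, n_domains = nrow(h), domain_span = span,
           residue14 = if (nrow(h) >= 1) h$residue14[[1]] else NA_character_,
           residue19 = if (nrow(h) >= 1) h$residue19[[1]] else NA_character_,
           status = status) |> bind_cols(pc)
  }) |> bind_rows()

  list(table = rows, accepted = flt$accepted, v_and_e = flt$v_and_e,
       v_only = flt$v_only, rejected = flt$rejected, hits = hits,
       candidates = cand)
}
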