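# Ungapped protein motif discovery under the ZOOPS model ("zero or one
# occurrence per sequence") by expectation-maximization, with sequential
# discovery and hard masking of found sites.

# Window index structure: one big (total windows) x w integer matrix of
# residue codes, plus per-sequence contiguous row ranges. Windows touching a
# masked position (code NA) are invalid.
build_windows <- function(codes_list, w) {
  per <- lapply(codes_list, function(cd) {
    L <- length(cd)
    m <- L - w + 1L
    if (m < 1L) return(NULL)
    idx <- sapply(seq_len(w), function(t) cd[t:(t + m - 1L)])
    if (m == 1L) idx <- matrix(idx, nrow = 1L)
    idx
  })
  keep <- !vapply(per, is.null, logical(1))
  per <- per[keep]
  if (length(per) == 0) return(NULL)
  sizes <- vapply(per, nrow, integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  IDX <- do.call(rbind, per)
  valid <- rowSums(is.na(IDX)) == 0L
  list(IDX = IDX, starts = starts, ends = ends, valid = valid,
       seq_idx = which(keep), n_seq = length(per))
}

# One EM run for a fixed width from a given pwm initialization.
zoops_em <- function(win, pwm, bg, gamma = 0.5, max_iter = 100, tol = 1e-6,
                     pseudocount = 0.25) {
  IDX <- win$IDX
  w <- ncol(IDX)
  nseq <- win$n_seq
  ll_old <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    lr <- log(pwm / rep(bg, each = w))           # w x 20
    sc <- numeric(nrow(IDX))
    for (t in seq_len(w)) sc <- sc + lr[t, IDX[, t]]
    sc[!win$valid] <- -Inf

    Z <- numeric(nrow(IDX))
    ll <- 0
    site_prob <- numeric(nseq)
    for (s in seq_len(nseq)) {
      rows <- win$starts[s]:win$ends[s]
      m <- length(rows)
      lw <- c(log(1 - gamma), log(gamma / m) + sc[rows])
      mx <- max(lw)
      wexp <- exp(lw - mx)
      tot <- sum(wexp)
      ll <- ll + mx + log(tot)
      post <- wexp / tot
      Z[rows] <- post[-1]
      site_prob[s] <- 1 - post[1]
    }
    trace <- c(trace, ll)

    zt <- sum(Z)
    counts <- matrix(0, w, 20)
    for (t in seq_len(w)) {
      ok <- !is.na(IDX[, t])
      rs <- rowsum(Z[ok], group = IDX[ok, t])
      counts[t, as.integer(rownames(rs))] <- rs[, 1]
    }
    pwm <- (counts + pseudocount * rep(bg, each = w)) /
      (zt + pseudocount)
    gamma <- min(max(mean(site_prob), 1e-3), 1 - 1e-3)

    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  # hard ZOOPS sites and the log-likelihood-ratio of the occurrences
  lr <- log(pwm / rep(bg, each = w))
  sc <- numeric(nrow(IDX))
  for (t in seq_len(w)) sc <- sc + lr[t, IDX[, t]]
  sc[!win$valid] <- -Inf
  sites <- integer(0); site_seqs <- integer(0); site_scores <- numeric(0)
  llr <- 0
  for (s in seq_len(nseq)) {
    rows <- win$starts[s]:win$ends[s]
    m <- length(rows)
    lw <- c(log(1 - gamma), log(gamma / m) + sc[rows])
    post <- exp(lw - max(lw)); post <- post / sum(post)
    if (1 - post[1] > 0.5) {
      o <- which.max(sc[rows])
      if (is.finite(sc[rows][o])) {
        sites <- c(sites, o)
        site_seqs <- c(site_seqs, win$seq_idx[s])
        site_scores <- c(site_scores, sc[rows][o])
        llr <- llr + sc[rows][o]
      }
    }
  }
  list(pwm = pwm, gamma = gamma, ll = tail(trace, 1), trace = trace,
       llr = llr, site_seq = site_seqs, site_offset = sites,
       site_score = site_scores)
}

#' Discover ungapped protein motifs (ZOOPS expectation-maximization)
#'
#' Motifs are found sequentially: for each motif slot, EM is run under the
#' zero-or-one-occurrence-per-sequence model for every candidate width, the
#' width maximizing the occurrence log-likelihood ratio under a BIC-type
#' width penalty is kept, its sites are hard-masked,
#' and the next slot starts. Discovery stops at `max_motifs` or when the best
#' penalized score drops below `llr_floor`. Deterministic given `seed`
#' (seeded multi-start initialization from actual sequence windows).
#'
#' @param proteins Sequence tibble or named vector (>= 2 sequences).
#' @param widths Candidate motif widths, all within 6-50.
#' @param max_motifs Maximum number of motifs (default 15).
#' @param seed Integer seed.
#' @param llr_floor Minimum penalized log-likelihood ratio to keep a motif.
#' @param n_starts Seeded EM restarts per width.
#' @return List of `motif_model` objects (fields `motif_id`, `width`, `pwm`,
#'   `consensus`, `llr`, `sites`).
#' @export
discover_motifs <- function(proteins, widths = c(seq(6, 48, 3), 50),
                            max_motifs = 15, seed = 1, llr_floor = 0,
                            n_starts = 2) {
  if (inherits(proteins, "data.frame")) proteins <- seq_vec(proteins)
  if (length(proteins) < 2) abort("motif discovery needs >= 2 sequences")
  if (any(widths < 6 | widths > 50)) abort("widths must lie in [6, 50]")
  if (max_motifs == 0) return(list())
  ids <- names(proteins)
  codes_list <- lapply(proteins, function(p) {
    match(chars(toupper(p)), AA_STANDARD)     # NA codes = masked/unknown
  })
  all_codes <- unlist(codes_list)
  bg_counts <- tabulate(all_codes[!is.na(all_codes)], nbins = 20)
  bg <- (bg_counts + 1) / sum(bg_counts + 1)

  motifs <- list()
  withr::with_seed(seed, {
    for (k in seq_len(max_motifs)) {
      best <- NULL
      for (w in sort(widths)) {
        ok_len <- vapply(codes_list, length, integer(1)) >= w
        if (sum(ok_len) < 2) {
          warn(paste0("width ", w, " exceeds most sequences; skipped"))
          next
        }
        win <- build_windows(codes_list, w)
        if (is.null(win) || sum(win$valid) < 2) next
        total_positions <- sum(win$valid)

        # starting points: the most frequent exact w-mers (strong seeds for
        # conserved or planted sites) plus seeded random windows; candidates
        # are scored by a single EM iteration and the best few refined
        vrows <- which(win$valid)
        keys <- apply(win$IDX[vrows, , drop = FALSE], 1, paste, collapse = ",")
        tab <- sort(table(keys), decreasing = TRUE)
        top <- names(tab)[tab >= 2]
        top <- top[order(-tab[top], top)][seq_len(min(8, length(top)))]
        seed_rows <- c(vrows[match(top, keys)],
                       vrows[sample.int(length(vrows),
                                        min(n_starts, length(vrows)))])
        seed_init <- function(r0) {
          init <- matrix(rep(bg, each = w), w, 20)
          seed_codes <- win$IDX[r0, ]
          for (t in seq_len(w)) {
            init[t, ] <- init[t, ] * 0.4
            init[t, seed_codes[t]] <- init[t, seed_codes[t]] + 0.6
          }
          init
        }
        quick <- vapply(seed_rows, function(r0) {
          zoops_em(win, seed_init(r0), bg, max_iter = 1)$ll
        }, numeric(1))
        refine <- seed_rows[order(-quick)][seq_len(min(3, length(seed_rows)))]
        runs <- lapply(refine, function(r0) {
          zoops_em(win, seed_init(r0), bg, max_iter = 15)
        })
        lead <- runs[[which.max(vapply(runs, function(r) r$ll, numeric(1)))]]
        fit <- zoops_em(win, lead$pwm, bg, gamma = lead$gamma, max_iter = 100)
        # register polishing: EM can settle one or two columns off the best
        # register; re-seed from shifted site windows and keep improvements
        shift_fit <- function(fit0, delta) {
          rows <- integer(0)
          for (k in seq_along(fit0$site_seq)) {
            s <- match(fit0$site_seq[k], win$seq_idx)
            r <- win$starts[s] + fit0$site_offset[k] - 1L + delta
            if (r >= win$starts[s] && r <= win$ends[s] && win$valid[r]) {
              rows <- c(rows, r)
            }
          }
          if (length(rows) < 2) return(NULL)
          counts <- matrix(0, w, 20)
          for (t in seq_len(w)) {
            counts[t, ] <- tabulate(win$IDX[rows, t], nbins = 20)
          }
          pwm0 <- (counts + 0.5 * rep(bg, each = w)) / (length(rows) + 0.5)
          zoops_em(win, pwm0, bg, gamma = fit0$gamma, max_iter = 15)
        }
        for (delta in c(-2L, -1L, 1L, 2L)) {
          cand <- shift_fit(fit, delta)
          if (!is.null(cand) && cand$ll > fit$ll + 1e-6) {
            fit <- zoops_em(win, cand$pwm, bg, gamma = cand$gamma,
                            max_iter = 100)
          }
        }
        # BIC-type width penalty: 19/2 free parameters per column against
        # the number of supporting sites. A flat log(total positions) per
        # column would be ~9.5 nats, almost exactly the overfitting gain of
        # a fitted random column, leaving motif boundaries to chance.
        n_sites <- max(length(fit$site_seq), 2L)
        pen <- fit$llr - w * (19 / 2) * log(n_sites)
        if (is.null(best) || pen > best$pen) {
          best <- list(fit = fit, w = w, pen = pen, win = win)
        }
      }
      if (is.null(best) || best$pen < llr_floor) break
      fit <- best$fit
      cons <- paste0v(AA_STANDARD[apply(fit$pwm, 1, which.max)])
      sites <- tibble(
        motif_id = paste0("motif_", k),
        protein_id = ids[fit$site_seq],
        offset = fit$site_offset - 1L,        # 0-based
        site_score = fit$site_score
      )
      motifs[[k]] <- structure(
        list(motif_id = paste0("motif_", k), width = best$w, pwm = fit$pwm,
             consensus = cons, llr = fit$llr, penalized_llr = best$pen,
             background = bg, sites = sites, ll_trace = fit$trace),
        class = "motif_model")
      # hard-mask discovered sites
      for (r in seq_len(nrow(sites))) {
        si <- match(sites$protein_id[r], ids)
        o <- sites$offset[r] + 1L
        codes_list[[si]][o:(o + best$w - 1L)] <- NA_integer_
      }
    }
  })
  motifs
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model> ", x$motif_id, " width=", x$width,
      " llr=", sprintf("%.1f", x$llr), " sites=", nrow(x$sites),
      "\n  consensus: ", x$consensus, "\n", sep = "")
  invisible(x)
}

#' Tidy a motif model into a long position-weight tibble
#' @param x A `motif_model`.
#' @param ... Unused.
#' @return Tibble with `position`, `residue`, `probability`.
#' @export
tidy.motif_model <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$width), times = 20),
    residue = rep(AA_STANDARD, each = x$width),
    probability = as.numeric(x$pwm)
  ) |> arrange(.data$position, .data$residue)
}

#' One-row summary of a motif model
#' @param x A `motif_model`.
#' @param ... Unused.
#' @return Tibble with `motif_id`, `width`, `consensus`, `llr`, `n_sites`.
#' @export
glance.motif_model <- function(x, ...) {
  tibble(motif_id = x$motif_id, width = x$width, consensus = x$consensus,
         llr = x$llr, n_sites = nrow(x$sites))
}

#' Best motif occurrence in a protein (ZOOPS scan)
#'
#' Scores every window by the summed log-odds of the motif PWM against its
#' background and reports the best window if it reaches `score_floor`
#' (at most one occurrence per sequence).
#'
#' @param protein Protein string or one-row sequence tibble.
#' @param motif A `motif_model`.
#' @param score_floor Minimum reported score; default is
#'   `floor_frac` of the consensus (maximum attainable) score.
#' @param floor_frac Fraction used for the default floor.
#' @param protein_id Identifier attached to the occurrence.
#' @return One-row tibble (`motif_id`, `protein_id`, `offset`, `site_score`)
#'   or a zero-row tibble when no window reaches the floor.
#' @export
scan_motif <- function(protein, motif, score_floor = NULL, floor_frac = 0.5,
                       protein_id = NULL) {
  if (inherits(protein, "data.frame")) {
    if (is.null(protein_id)) protein_id <- protein$id[[1]]
    protein <- protein$residues[[1]]
  }
  if (is.null(protein_id)) protein_id <- "query"
  w <- motif$width
  lr <- log(motif$pwm / rep(motif$background, each = w))
  if (is.null(score_floor)) {
    score_floor <- floor_frac * sum(apply(lr, 1, max))
  }
  empty <- tibble(motif_id = character(), protein_id = character(),
                  offset = integer(), site_score = numeric())
  cd <- match(chars(toupper(protein)), AA_STANDARD)
  L <- length(cd)
  if (L < w) return(empty)
  m <- L - w + 1L
  sc <- numeric(m)
  for (t in seq_len(w)) {
    v <- lr[t, cd[t:(t + m - 1L)]]
    v[is.na(cd[t:(t + m - 1L)])] <- -Inf
    sc <- sc + v
  }
  if (max(sc) < score_floor) return(empty)
  o <- which.max(sc)
  tibble(motif_id = motif$motif_id, protein_id = protein_id,
         offset = o - 1L, site_score = sc[o])
}

#' Motif presence/absence matrix
#'
#' @param family_ids Gene ids (rows); sorted for a deterministic order.
#' @param motifs List of `motif_model`s (columns, in list order).
#' @param occurrences Occurrence tibble (rows from [scan_motif()]).
#' @return Binary integer matrix, genes x motifs.
#' @export
presence_matrix <- function(family_ids, motifs, occurrences) {
  rows <- sort(unique(family_ids))
  cols <- vapply(motifs, function(m) m$motif_id, character(1))
  mat <- matrix(0L, length(rows), length(cols),
                dimnames = list(rows, cols))
  if (nrow(occurrences) > 0) {
    occ <- occurrences |>
      filter(.data$protein_id %in% rows, .data$motif_id %in% cols)
    mat[cbind(match(occ$protein_id, rows), match(occ$motif_id, cols))] <- 1L
  }
  mat
}
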