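# Distance phylogenetics: Poisson-corrected protein distances with pairwise
# deletion, Saitou-Nei neighbor joining, nonparametric bootstrap supports,
# and subgroup assignment against a labelled reference panel.

#' Poisson-corrected distance matrix with pairwise deletion
#'
#' For each sequence pair only columns where neither sequence has a gap are
#' used; with mismatch fraction `p` the distance is `-ln(1 - p)`.
#'
#' @param msa MSA tibble (`id`, `aligned`) or named vector of gapped strings.
#' @return Symmetric numeric matrix with zero diagonal, labelled by id.
#' @export
poisson_distance <- function(msa) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  if (n < 2) abort("need at least 2 sequences")
  labels <- rownames(m)
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      used <- sum(ok)
      if (used == 0) {
        abort(paste0("no shared ungapped columns for pair ",
                     labels[i], " / ", labels[j]))
      }
      p <- sum(m[i, ok] != m[j, ok]) / used
      if (p >= 1) {
        abort(paste0("saturated pair (p = 1): ", labels[i], " / ", labels[j]))
      }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei Q-criterion agglomeration with the usual branch-length
#' estimates. Negative branch lengths are clamped to zero and the deficit is
#' transferred to the sibling edge. Ties in the Q criterion are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled by
#' its smallest leaf), so the output is deterministic. The result is an
#' unrooted tree (basal trifurcation).
#'
#' @param dm Symmetric distance matrix with labelled dimnames.
#' @return An `ape::phylo` object.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) abort("distance matrix not symmetric")
  labels <- rownames(dm)
  n0 <- length(labels)
  if (n0 < 3) abort("need at least 3 taxa")

  fmt <- function(x) sprintf("%.10g", max(x, 0))
  reps <- labels                     # cluster representative: smallest leaf
  sub <- labels                      # newick fragment per cluster
  D <- dm
  while (length(reps) > 3) {
    n <- length(reps)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      pr <- sort(c(reps[ij[1]], reps[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[[1]]; j <- pick[[2]]

    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)

    new_sub <- paste0("(", sub[i], ":", fmt(li), ",", sub[j], ":", fmt(lj), ")")
    new_rep <- min(reps[i], reps[j])
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    sub <- c(sub[keep], new_sub)
    reps <- c(reps[keep], new_rep)
  }
  a <- D[1, 2]; b <- D[1, 3]; cc <- D[2, 3]
  l1 <- (a + b - cc) / 2
  l2 <- (a + cc - b) / 2
  l3 <- (b + cc - a) / 2
  nwk <- paste0("(", sub[1], ":", fmt(l1), ",", sub[2], ":", fmt(l2),
                ",", sub[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

# Canonical bipartition keys of the non-trivial splits of a tree: each side is
# represented by the tip set NOT containing the overall smallest label.
tree_bipartitions <- function(tree) {
  labels <- tree$tip.label
  ntip <- length(labels)
  anchor <- min(labels)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (k in seq_along(pp)) {
    side <- attr(pp, "labels")[pp[[k]]]
    sz <- length(side)
    if (sz <= 1 || sz >= ntip - 1) next
    if (anchor %in% side) side <- setdiff(labels, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap supports for the splits of an alignment's NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the Poisson distance
#' matrix and NJ tree per replicate, and reports the percentage of replicates
#' containing each non-trivial bipartition of the full-alignment tree.
#' Replicates whose resampled distances are undefined (saturated or disjoint
#' pairs) are discarded; more than 10% discarded is an error.
#'
#' @param msa MSA tibble or named vector of gapped strings.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the run is deterministic given the seed.
#' @return List with `tree` (the full-alignment NJ tree whose `node.label`
#'   carries supports), `supports` (tibble `bipartition`, `percent`) and
#'   `n_discarded`.
#' @export
bootstrap_supports <- function(msa, n_replicates = 1000, seed = 1) {
  m <- msa_matrix(msa)
  L <- ncol(m)
  base_dm <- poisson_distance(msa)
  base_tree <- nj_tree(base_dm)
  base_keys <- tree_bipartitions(base_tree)

  counts <- setNames(numeric(length(base_keys)), base_keys)
  discarded <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      mb <- m[, cols, drop = FALSE]
      dmb <- tryCatch(poisson_distance(setNames(
        apply(mb, 1, paste0, collapse = ""), rownames(m))),
        error = function(e) NULL)
      if (is.null(dmb)) { discarded <- discarded + 1L; next }
      keys <- tree_bipartitions(nj_tree(dmb))
      hit <- base_keys %in% keys
      counts[hit] <- counts[hit] + 1
    }
  })
  if (discarded > 0.1 * n_replicates) {
    abort(paste0(discarded, " of ", n_replicates,
                 " bootstrap replicates had undefined distances"))
  }
  eff <- n_replicates - discarded
  pct <- if (eff > 0) 100 * counts / eff else counts * NA_real_
  supports <- tibble(bipartition = base_keys, percent = unname(pct))

  # attach supports to internal nodes of the base tree
  labels_all <- base_tree$tip.label
  anchor <- min(labels_all)
  pp <- ape::prop.part(base_tree)
  node_lab <- character(base_tree$Nnode)
  for (k in seq_along(pp)) {
    side <- attr(pp, "labels")[pp[[k]]]
    sz <- length(side)
    if (sz <= 1 || sz >= length(labels_all) - 1) { node_lab[k] <- ""; next }
    if (anchor %in% side) side <- setdiff(labels_all, side)
    key <- paste(sort(side), collapse = "|")
    node_lab[k] <- ifelse(key %in% base_keys,
                          sprintf("%.0f", pct[[key]]), "")
  }
  base_tree$node.label <- node_lab
  list(tree = base_tree, supports = supports, n_discarded = discarded)
}

#' Assign subgroup labels to query leaves from labelled references
#'
#' For each query leaf, the smallest edge-induced split side containing the
#' query and at least one reference decides the label: if all references in
#' that side share one label it is used (`method = "clade"`); otherwise the
#' label of the reference at smallest patristic distance is used
#' (`method = "nearest"`, ties broken by lexicographic reference id).
#'
#' @param tree An `ape::phylo` whose tips include all references.
#' @param reference_labels Named character vector: reference tip -> label.
#' @return Tibble with `gene_id`, `subgroup`, `method` for every
#'   non-reference tip.
#' @export
assign_subgroups <- function(tree, reference_labels) {
  tips <- tree$tip.label
  refs <- names(reference_labels)
  if (!all(refs %in% tips)) {
    abort(paste0("reference not in tree: ", setdiff(refs, tips)[[1]]))
  }
  for (lab in unique(reference_labels)) {
    if (!any(reference_labels == lab)) abort(paste0("label without reference: ", lab))
  }
  queries <- setdiff(tips, refs)
  ntip <- length(tips)

  # tip sets for both sides of every edge
  pp <- ape::prop.part(tree)
  sides <- list()
  for (k in seq_along(pp)) {
    s <- attr(pp, "labels")[pp[[k]]]
    if (length(s) < ntip) {
      sides[[length(sides) + 1]] <- s
      sides[[length(sides) + 1]] <- setdiff(tips, s)
    }
  }
  for (tp in tips) {
    sides[[length(sides) + 1]] <- tp
    sides[[length(sides) + 1]] <- setdiff(tips, tp)
  }
  has_ref <- vapply(sides, function(s) any(refs %in% s), logical(1))
  sizes <- vapply(sides, length, integer(1))

  pat <- NULL
  out <- lapply(queries, function(q) {
    cand <- which(has_ref & vapply(sides, function(s) q %in% s, logical(1)))
    cand <- cand[order(sizes[cand])]
    side <- sides[[cand[1]]]
    in_refs <- intersect(side, refs)
    labs <- unique(reference_labels[in_refs])
    if (length(labs) == 1) {
      return(tibble(gene_id = q, subgroup = unname(labs), method = "clade"))
    }
    if (is.null(pat)) pat <<- ape::cophenetic.phylo(tree)
    dd <- pat[q, refs]
    nearest <- refs[order(dd, refs)][1]
    tibble(gene_id = q, subgroup = unname(reference_labels[[nearest]]),
           method = "nearest")
  }) |> bind_rows()
  out
}
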