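# Distance, parsimony, and small-scale tree-search utilities. Standard
# operations (NJ, RF, patristic paths, topology enumeration) are delegated to
# ape/phangorn; the Fitch and distance code here exists because the pipeline
# needs specific ambiguity semantics (gap = missing, excluded from state
# sets) and logdet/paralinear entries with explicit singularity flags.

#' Uncorrected p-distance matrix
#'
#' Pairwise mismatch proportion with pairwise deletion of columns where
#' either sequence is a gap or ambiguous. Pairs with no comparable site are
#' `NA`.
#'
#' @param aln An [msa].
#' @return Symmetric matrix with zero diagonal; attribute `method = "p"`.
#' @export
p_distance <- function(aln) {
  if (n_taxa(aln) < 2) abort("need at least 2 taxa")
  codes <- msa_codes(aln)
  n <- nrow(codes)
  d <- matrix(0, n, n, dimnames = list(rownames(codes), rownames(codes)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- codes[i, ] > 0L & codes[j, ] > 0L
    d[i, j] <- d[j, i] <- if (!any(ok)) NA_real_ else
      mean(codes[i, ok] != codes[j, ok])
  }
  attr(d, "method") <- "p"
  d
}

#' Logdet (paralinear) distance matrix
#'
#' Lake-style paralinear distance: for each pair, the normalized joint
#' state-frequency matrix J gives
#' `d = -(1/k) * (log det J - 0.5 * sum(log f_x) - 0.5 * sum(log f_y))`.
#' Robust to compositional differences between lineages. Entries where the
#' joint matrix is singular (determinant <= 0, i.e. saturated pairs) are `NA`.
#'
#' @param aln An [msa].
#' @return Symmetric matrix; attribute `method = "logdet"`.
#' @export
logdet_distance <- function(aln) {
  if (n_taxa(aln) < 2) abort("need at least 2 taxa")
  codes <- msa_codes(aln)
  k <- if (aln$alphabet == "nucleotide") 4L else 20L
  n <- nrow(codes)
  d <- matrix(0, n, n, dimnames = list(rownames(codes), rownames(codes)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- codes[i, ] > 0L & codes[j, ] > 0L
    if (sum(ok) < k) { d[i, j] <- d[j, i] <- NA_real_; next }
    jm <- matrix(0, k, k)
    tb <- table(factor(codes[i, ok], levels = 1:k),
                factor(codes[j, ok], levels = 1:k))
    jm[] <- tb / sum(tb)
    dt <- det(jm)
    if (!is.finite(dt) || dt <= 0) { d[i, j] <- d[j, i] <- NA_real_; next }
    fx <- rowSums(jm); fy <- colSums(jm)
    if (any(fx == 0) || any(fy == 0)) { d[i, j] <- d[j, i] <- NA_real_; next }
    v <- -(1 / k) * (log(dt) - 0.5 * (sum(log(fx)) + sum(log(fy))))
    d[i, j] <- d[j, i] <- max(v, 0)
  }
  attr(d, "method") <- "logdet"
  d
}

#' Neighbor joining
#'
#' Saitou-Nei neighbor joining via ape, with negative branch-length
#' estimates clamped to zero (with a warning).
#'
#' @param dist Complete symmetric distance matrix (no `NA`).
#' @return An unrooted `ape::phylo`.
#' @export
neighbor_joining <- function(dist) {
  if (anyNA(dist)) abort("distance matrix contains undefined entries")
  if (nrow(dist) < 3) abort("need at least 3 taxa for NJ")
  tr <- ape::nj(as.dist(dist))
  if (any(tr$edge.length < 0)) {
    warn("negative NJ branch estimates clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

# Bitmask encoding of an alignment for Fitch: plain state i -> bit i;
# gap and ambiguity -> all bits (neutral in the pass; gaps contribute no
# steps, matching a missing-data reading).
fitch_masks <- function(aln, taxa = NULL) {
  codes <- msa_codes(aln)
  if (!is.null(taxa)) codes <- codes[taxa, , drop = FALSE]
  k <- if (aln$alphabet == "nucleotide") 4L else 20L
  full <- bitwShiftL(1L, k) - 1L
  m <- matrix(full, nrow(codes), ncol(codes), dimnames = dimnames(codes))
  st <- codes > 0L
  m[st] <- bitwShiftL(1L, codes[st] - 1L)
  m
}

#' Fitch parsimony length
#'
#' Per-site minimum substitution counts on a fixed tree (Fitch algorithm,
#' generalized to multifurcations by sequential intersection). Gaps and
#' ambiguity codes act as missing data and never force a step.
#'
#' @param tree `ape::phylo` whose tips match the alignment taxa.
#' @param aln An [msa].
#' @return List with `total` (sum of steps) and `per_site` (integer vector).
#' @export
parsimony_length <- function(tree, aln) {
  if (!setequal(tree$tip.label, msa_taxa(aln))) abort("tree tips must match alignment taxa")
  masks <- fitch_masks(aln)[tree$tip.label, , drop = FALSE]
  fitch_engine(tree, masks)
}

# masks: tips x sites integer matrix
fitch_engine <- function(tree, masks) {
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  n_tip <- nrow(masks)
  n_node <- max(edge)
  P <- ncol(masks)
  steps <- integer(P)
  node_set <- matrix(0L, n_node - n_tip, P)
  get_set <- function(v) if (v <= n_tip) masks[v, ] else node_set[v - n_tip, ]
  parents <- unique(edge[, 1])      # postorder: children before parents
  kids <- split(edge[, 2], factor(edge[, 1], levels = parents))
  for (pi in seq_along(parents)) {
    ks <- kids[[pi]]
    cur <- get_set(ks[1])
    for (v in ks[-1]) {
      nxt <- get_set(v)
      inter <- bitwAnd(cur, nxt)
      zero <- inter == 0L
      steps <- steps + zero
      cur <- ifelse(zero, bitwOr(cur, nxt), inter)
    }
    node_set[parents[pi] - n_tip, ] <- cur
  }
  list(total = sum(steps), per_site = steps)
}

#' Minimum possible parsimony steps per site
#'
#' The per-site lower bound: number of distinct unambiguous states minus one.
#'
#' @param aln An [msa].
#' @return Integer vector, one entry per column.
#' @export
min_steps <- function(aln) {
  codes <- msa_codes(aln)
  apply(codes, 2, function(col) max(0L, length(unique(col[col > 0L])) - 1L))
}

#' Parsimony homoplasy excess
#'
#' Tree length minus the per-site minimum achievable steps; zero on
#' homoplasy-free data.
#'
#' @param tree `ape::phylo`.
#' @param aln An [msa].
#' @return Non-negative integer.
#' @export
homoplasy_excess <- function(tree, aln) {
  parsimony_length(tree, aln)$total - sum(min_steps(aln))
}

#' Patristic distance matrix
#'
#' @param tree `ape::phylo` with branch lengths.
#' @return Symmetric matrix of path-length sums between leaves.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Robinson-Foulds distance
#'
#' @param t1,t2 `ape::phylo` trees over the same taxa.
#' @return Integer symmetric bipartition difference.
#' @export
rf_distance <- function(t1, t2) {
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

# canonical split representation: the side not containing the reference tip
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ref <- sort(tree$tip.label)[1]
  bp <- ape::prop.part(tree)
  labs <- attr(bp, "labels")
  out <- lapply(bp, function(ix) {
    s <- labs[ix]
    if (ref %in% s) setdiff(labs, s) else s
  })
  out <- out[vapply(out, function(s) length(s) > 1 && length(s) < length(labs) - 1,
                    logical(1))]
  unique(vapply(out, function(s) paste(sort(s), collapse = "|"), character(1)))
}

#' Is a clade present as a bipartition?
#'
#' Checks whether the split separating `taxa` from the rest occurs in the
#' (unrooted) tree. Trivial splits (single tips) are always present.
#'
#' @param tree `ape::phylo`.
#' @param taxa Character vector of tip labels.
#' @return Logical.
#' @export
has_clade <- function(tree, taxa) {
  taxa <- sort(taxa)
  rest <- setdiff(tree$tip.label, taxa)
  if (length(taxa) <= 1 || length(rest) <= 1) return(TRUE)
  ref <- sort(tree$tip.label)[1]
  key <- if (ref %in% taxa) paste(sort(rest), collapse = "|") else paste(taxa, collapse = "|")
  key %in% tree_splits(tree)
}

#' Sister group of a tip set
#'
#' For an unrooted tree, roots at a tip outside `taxa` and returns the tip
#' labels of the sibling clade of the minimal clade containing `taxa`.
#'
#' @param tree `ape::phylo`.
#' @param taxa Character vector of tip labels (must be a proper subset).
#' @return Character vector of sister-group tip labels (sorted).
#' @export
sister_of <- function(tree, taxa) {
  outside <- sort(setdiff(tree$tip.label, taxa))
  if (!length(outside)) abort("`taxa` must be a proper subset of the tips")
  # canonical rooting: comparisons between trees over the same taxa stay
  # consistent whatever tip order each inference produced
  tr <- ape::root(ape::unroot(tree), outgroup = outside[1], resolve.root = TRUE)
  node <- if (length(taxa) == 1) which(tr$tip.label == taxa) else ape::getMRCA(tr, taxa)
  parent <- tr$edge[tr$edge[, 2] == node, 1]
  if (!length(parent)) return(sort(outside))
  sibs <- setdiff(tr$edge[tr$edge[, 1] == parent, 2], node)
  tips <- unlist(lapply(sibs, function(s) {
    if (s <= length(tr$tip.label)) tr$tip.label[s]
    else tr$tip.label[phangorn::Descendants(tr, s, "tips")[[1]]]
  }))
  sort(tips)
}

#' Exhaustive maximum-likelihood topology search
#'
#' Enumerates every unrooted topology (up to 8 taxa; 10,395 trees at 8) and
#' fits the model on each, returning the best tree and the per-topology
#' log-likelihood table. Intended for the small focal-taxon experiments; use
#' [neighbor_joining()] beyond 8 taxa.
#'
#' @param aln An [msa].
#' @param spec A [model_spec()].
#' @param seed Integer seed passed to [fit_model()].
#' @return List with `tree` (best, fitted branch lengths), `logL`, and
#'   `table` (tibble of topology index, newick, logL).
#' @export
exhaustive_ml_topology <- function(aln, spec = spec_gtr(gamma = FALSE), seed = 1L) {
  nt <- n_taxa(aln)
  if (nt > 8) abort("exhaustive search limited to 8 taxa; use neighbor_joining()")
  trees <- phangorn::allTrees(nt, rooted = FALSE, tip.label = msa_taxa(aln))
  # index with the multiPhylo method so compressed tip labels are restored
  trees <- lapply(seq_along(trees), function(i) trees[[i]])
  fits <- purrr::map(trees, function(tr) {
    tr$edge.length <- rep(0.1, nrow(tr$edge))
    fit_model(aln, tr, spec, seed = seed)
  })
  ll <- vapply(fits, function(f) f$logL, numeric(1))
  best <- which.max(ll)
  list(tree = fits[[best]]$tree, logL = ll[best],
       table = tibble(topology = seq_along(ll),
                      newick = vapply(seq_along(trees), function(i)
                        write_newick(trees[[i]]), character(1)),
                      logL = ll))
}
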