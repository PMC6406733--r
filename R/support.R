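# --- bipartition bookkeeping -------------------------------------------------

#' Canonical keys of a tree's non-trivial bipartitions
#'
#' Each internal edge of the unrooted tree defines a bipartition of the
#' leaves; it is represented by the side *not* containing the alphabetically
#' first leaf, sorted and joined with `|`, so the key is invariant to rooting
#' and to taxon order.
#'
#' @param phy an [ape::phylo] tree.
#' @return character vector of split keys (empty for trees with < 4 leaves).
#' @export
tree_splits <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  ntip <- ape::Ntip(phy)
  labs <- phy$tip.label
  ref <- sort(labs)[1L]
  pp <- ape::prop.part(phy)
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

# split key of each internal node of `phy` (NA for trivial splits), in node
# order Ntip+1 .. Ntip+Nnode of the *given* (possibly rooted) tree
node_split_keys <- function(phy) {
  ntip <- ape::Ntip(phy)
  labs <- phy$tip.label
  ref <- sort(labs)[1L]
  pp <- ape::prop.part(phy)
  vapply(seq_along(pp), function(i) {
    side <- labs[pp[[i]]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
}

#' Robinson–Foulds distance between two trees
#'
#' The symmetric difference of the two trees' sets of non-trivial
#' bipartitions; 0 for topologically identical trees, at most `2(n-3)` for
#' fully resolved trees on `n` shared leaves.
#'
#' @param t1,t2 [ape::phylo] trees on the same leaf set.
#' @return a non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    abort("trees have different leaf sets: %s",
          paste(c(setdiff(t1$tip.label, t2$tip.label),
                  setdiff(t2$tip.label, t1$tip.label)), collapse = ", "))
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# --- bootstrap ---------------------------------------------------------------

# single inference step shared by bootstrap_support and expr_phylo
infer_tree <- function(data, method, metric = "euclidean") {
  switch(method,
    nj = {
      dm <- if (inherits(data, "char_matrix")) char_distance(data)
            else compute_distance(data, metric)
      neighbor_joining(dm)
    },
    parsimony = parsimony_search(data, "nni_from_nj")$trees[[1L]],
    ml = ml_search(data, "nni_from_nj")$tree,
    abort("unknown method '%s'", method))
}

# resample the characters of the data with replacement: genes (rows) of an
# expression matrix, characters (columns) of a character matrix
resample_characters <- function(data) {
  if (inherits(data, "expr_matrix")) {
    idx <- sample.int(nrow(data$values), replace = TRUE)
    out <- data
    out$values <- data$values[idx, , drop = FALSE]
    rownames(out$values) <- sprintf("bs%d", seq_along(idx))
    out
  } else if (inherits(data, "char_matrix")) {
    idx <- sample.int(ncol(data), replace = TRUE)
    char_matrix(unclass(data)[, idx, drop = FALSE],
                tau = attr(data, "tau"), outgroup = attr(data, "outgroup"))
  } else abort("bootstrap data must be an expr_matrix or char_matrix")
}

#' Character-bootstrap branch support
#'
#' Resamples the characters with replacement (genes for expression input,
#' discretized characters for parsimony/ML input), re-infers a tree per
#' pseudoreplicate, and annotates each internal edge of the point-estimate
#' tree with the percentage of replicate trees containing that bipartition.
#'
#' @param data an [expr_matrix()] (for `method = "nj"`) or a `char_matrix`.
#' @param method `"nj"`, `"parsimony"` or `"ml"`.
#' @param n_reps number of pseudoreplicates (default 100).
#' @param seed RNG seed for reproducible resampling.
#' @param metric distance metric for `method = "nj"` on expression input.
#' @param tree optional precomputed point-estimate tree; inferred from `data`
#'   when `NULL`.
#' @return the point-estimate tree with integer percent supports in
#'   `node.label` (empty for trivial splits) and attribute `n_reps`.
#' @export
bootstrap_support <- function(data, method = c("nj", "parsimony", "ml"),
                              n_reps = 100L, seed = NULL,
                              metric = "euclidean", tree = NULL) {
  method <- match.arg(method)
  if (!is.numeric(n_reps) || n_reps < 1L) abort("n_reps must be >= 1")
  n_reps <- as.integer(n_reps)
  if (method %in% c("parsimony", "ml") && !inherits(data, "char_matrix"))
    abort("%s bootstrap needs a discretized char_matrix", method)
  point <- tree %||% infer_tree(data, method, metric)
  counts <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      bt <- infer_tree(resample_characters(data), method, metric)
      for (k in tree_splits(bt))
        assign(k, (get0(k, envir = counts) %||% 0L) + 1L, envir = counts)
    }
  })
  keys <- node_split_keys(point)
  support <- vapply(keys, function(k) {
    if (is.na(k)) return(NA_integer_)
    as.integer(round(100 * (get0(k, envir = counts) %||% 0L) / n_reps))
  }, integer(1))
  point$node.label <- ifelse(is.na(support), "", as.character(support))
  attr(point, "n_reps") <- n_reps
  point
}

# --- baselines and ordering metrics -----------------------------------------

#' Hierarchical-clustering dendrogram baseline
#'
#' Standard agglomerative clustering (single or complete linkage) on a sample
#' distance matrix, returned as an ultrametric [ape::phylo] dendrogram for
#' side-by-side comparison with the phylogenetic reconstructions.
#'
#' @param dm symmetric distance matrix (e.g. from [compute_distance()]).
#' @param linkage `"single"` or `"complete"`.
#' @return an [ape::phylo] dendrogram.
#' @export
hierarchical_cluster <- function(dm, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  d <- stats::as.dist(unclass(as.matrix(dm)))
  if (attr(d, "Size") < 2L) abort("need >= 2 taxa to cluster")
  hc <- stats::hclust(d, method = linkage)
  ape::as.phylo(hc)
}

#' Temporal-order score of a rooted tree
#'
#' Measures how well the order in which leaves branch off from the root
#' recapitulates their known time order: the Kendall tau-b correlation
#' between each leaf's time rank and its divergence order (the depth, in
#' nodes from the root, at which its lineage splits off; replicate leaves of
#' one clade share a divergence order). 1 for a caterpillar tree matching
#' the time order, -1 for the reversed caterpillar, approximately 0 for
#' random arrangements.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param time_rank named integer vector of time ranks, one per leaf.
#' @return a number in `[-1, 1]`.
#' @export
temporal_order_score <- function(tree, time_rank) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    abort("temporal_order_score needs a rooted tree; root on the outgroup first")
  miss <- setdiff(tree$tip.label, names(time_rank))
  if (length(miss)) abort("no time rank for leaf/leaves: %s", paste(miss, collapse = ", "))
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  depth <- numeric(ntip + tree$Nnode)
  phy <- ape::reorder.phylo(tree, "cladewise")
  for (r in seq_len(nrow(phy$edge)))
    depth[phy$edge[r, 2L]] <- depth[phy$edge[r, 1L]] + 1L
  parent <- integer(ntip)
  parent[phy$edge[phy$edge[, 2L] <= ntip, 2L]] <- phy$edge[phy$edge[, 2L] <= ntip, 1L]
  div_order <- depth[parent]
  ranks <- as.numeric(time_rank[tree$tip.label])
  if (stats::sd(div_order) == 0 || stats::sd(ranks) == 0) return(0)
  unname(stats::cor(ranks, div_order, method = "kendall"))
}
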