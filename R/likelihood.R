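#' Transition probabilities of the symmetric 3-state Markov model
#'
#' The model is the k=3 analogue of Jukes–Cantor: equal stationary
#' frequencies 1/3 and a single exchange rate, with branch length measured in
#' expected state changes per character. Closed form:
#' `P_same(b) = 1/3 + (2/3) exp(-1.5 b)`, off-diagonals `(1 - P_same)/2`.
#'
#' @param b branch length, non-negative.
#' @return a 3x3 row-stochastic matrix.
#' @export
mk_transition_prob <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0)
    abort("branch length must be a single non-negative number (got %s)", format(b))
  psame <- 1 / 3 + (2 / 3) * exp(-1.5 * b)
  poff <- (1 - psame) / 2
  m <- matrix(poff, 3, 3)
  diag(m) <- psame
  m
}

# collapse identical character columns into unique patterns with counts
compress_patterns <- function(cm) {
  m <- unclass(cm)
  key <- apply(m, 2L, paste, collapse = "\r")
  first <- !duplicated(key)
  list(states = m[, first, drop = FALSE],
       weights = as.numeric(table(key)[key[first]]))
}

# Precompute everything branch-length-independent for pruning on a fixed
# topology: postorder edge list, per-parent edge groups, and tip partials for
# the compressed patterns. `bl` is then the only thing that varies during
# branch-length optimization.
prune_setup <- function(tree, cm) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    abort("tree has missing branch length(s); likelihood needs a length on every edge")
  if (any(tree$edge.length < 0)) abort("negative branch length(s) in tree")
  taxa <- rownames(cm)
  if (!setequal(tree$tip.label, taxa)) {
    d <- c(setdiff(tree$tip.label, taxa), setdiff(taxa, tree$tip.label))
    abort("tree leaves and matrix taxa differ: %s", paste(d, collapse = ", "))
  }
  pat <- compress_patterns(cm)
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(phy)
  P <- ncol(pat$states)
  tip_partial <- vector("list", ntip)
  tipstates <- pat$states[phy$tip.label, , drop = FALSE]
  for (i in seq_len(ntip)) {
    m <- matrix(0, 3, P)
    m[cbind(tipstates[i, ] + 1L, seq_len(P))] <- 1
    tip_partial[[i]] <- m
  }
  parents <- rev(unique(rev(phy$edge[, 1L])))
  list(edge = phy$edge, bl = phy$edge.length, ntip = ntip,
       nnode = phy$Nnode, parents = parents,
       edge_rows = lapply(parents, function(nd) which(phy$edge[, 1L] == nd)),
       tip_partial = tip_partial, weights = pat$weights, P = P)
}

# pruning pass over a prune_setup, with (possibly updated) branch lengths
prune_loglik <- function(su, bl = su$bl) {
  partial <- vector("list", su$ntip + su$nnode)
  partial[seq_len(su$ntip)] <- su$tip_partial
  e <- su$edge
  for (k in seq_along(su$parents)) {
    rows <- su$edge_rows[[k]]
    acc <- mk_transition_prob(bl[rows[1L]]) %*% partial[[e[rows[1L], 2L]]]
    for (r in rows[-1L])
      acc <- acc * (mk_transition_prob(bl[r]) %*% partial[[e[r, 2L]]])
    partial[[su$parents[k]]] <- acc
  }
  root <- e[nrow(e), 1L]
  site_l <- colSums(partial[[root]]) / 3
  if (any(site_l <= 0) || any(!is.finite(site_l)))
    abort("non-finite site likelihood encountered")
  sum(su$weights * log(site_l))
}

#' Log-likelihood of a character matrix on a tree
#'
#' Felsenstein's pruning algorithm under the symmetric 3-state model:
#' characters are independent, the root prior is the stationary distribution
#' (1/3 per state), and each character contributes
#' `log( sum_s (1/3) L_root(s) )`. Identical character patterns are
#' aggregated before pruning. Works for any (multi)furcating rooted or
#' unrooted tree; by reversibility the value does not depend on the root
#' position.
#'
#' @param tree an [ape::phylo] tree with non-negative branch lengths.
#' @param cm a `char_matrix` whose taxa match the tree's leaves.
#' @return the log-likelihood (a single numeric).
#' @export
tree_log_likelihood <- function(tree, cm) {
  prune_loglik(prune_setup(tree, cm))
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise scalar maximization of the log-likelihood: each edge in
#' turn is optimized by Brent's method on `[0, max_bl]`, sweeping over all
#' edges until the log-likelihood gain of a sweep falls below `min_gain` or
#' `max_sweeps` is reached. The log-likelihood is non-decreasing across
#' sweeps. The default upper bound of 10 expected changes reflects
#' saturation: `P_same(10)` is already 1/3 to within 3e-7, so longer branches
#' are unidentifiable.
#'
#' @param tree an [ape::phylo] topology (missing lengths initialized at 0.1).
#' @param cm a `char_matrix`.
#' @param max_bl upper branch-length bound (default 10).
#' @param tol Brent tolerance per edge (default 1e-6).
#' @param min_gain sweep-level convergence threshold (default 1e-8).
#' @param max_sweeps maximum number of sweeps (default 50).
#' @return the tree with optimized `edge.length` and attribute `loglik`.
#' @export
optimize_branch_lengths <- function(tree, cm, max_bl = 10, tol = 1e-6,
                                    min_gain = 1e-8, max_sweeps = 50L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length) | tree$edge.length < 0] <- 0.1
  tree$edge.length <- pmin(tree$edge.length, max_bl)
  tree <- ape::reorder.phylo(tree, "postorder")
  su <- prune_setup(tree, cm)
  bl <- su$bl
  ll <- prune_loglik(su, bl)
  for (sweep in seq_len(max_sweeps)) {
    ll0 <- ll
    for (ei in seq_along(bl)) {
      f <- function(b) {
        bl[ei] <- b
        prune_loglik(su, bl)
      }
      opt <- stats::optimize(f, c(0, max_bl), maximum = TRUE, tol = tol)
      if (!is.finite(opt$objective))
        abort("non-finite likelihood while optimizing edge %d", ei)
      if (opt$objective >= ll) {
        bl[ei] <- opt$maximum
        ll <- opt$objective
      }
    }
    # Brent never lands exactly on the boundary; snap near-zero lengths
    for (ei in which(bl > 0 & bl < tol)) {
      bl2 <- bl
      bl2[ei] <- 0
      ll2 <- prune_loglik(su, bl2)
      if (ll2 >= ll) {
        bl <- bl2
        ll <- ll2
      }
    }
    if (ll - ll0 < min_gain) break
  }
  tree$edge.length <- bl
  attr(tree, "loglik") <- ll
  tree
}

#' Maximum-likelihood tree search
#'
#' As [parsimony_search()], but each candidate topology is scored by its
#' branch-length-optimized log-likelihood under the symmetric 3-state model.
#' Exhaustive enumeration is allowed up to 7 taxa (945 topologies, each
#' optimized); `"nni_from_nj"` hill-climbs from the NJ tree on Hamming
#' distances.
#'
#' @param cm a `char_matrix` with >= 4 taxa.
#' @param strategy `"exhaustive"` or `"nni_from_nj"`.
#' @param tol,min_gain,max_sweeps optimization controls passed to
#'   [optimize_branch_lengths()] (search uses looser defaults for candidate
#'   scoring and re-polishes the winner at full precision).
#' @return a list of class `ml_result`: `tree` (optimized lengths),
#'   `loglik`, `strategy`, `n_evaluated`.
#' @export
ml_search <- function(cm, strategy = c("nni_from_nj", "exhaustive"),
                      tol = 1e-4, min_gain = 1e-4, max_sweeps = 10L) {
  strategy <- match.arg(strategy)
  n <- nrow(cm)
  if (n < 4L) abort("tree search needs >= 4 taxa (got %d)", n)
  score_fun <- function(tr) {
    tr$edge.length <- rep(0.1, nrow(tr$edge))
    opt <- optimize_branch_lengths(tr, cm, tol = tol, min_gain = min_gain,
                                   max_sweeps = max_sweeps)
    list(tree = opt, ll = attr(opt, "loglik"))
  }
  if (strategy == "exhaustive") {
    if (n > 7L)
      abort("exhaustive ML search is limited to 7 taxa (%d requested); use strategy = 'nni_from_nj'", n)
    trees <- all_topologies(n, rownames(cm))
    fits <- lapply(trees, score_fun)
    lls <- vapply(fits, `[[`, numeric(1), "ll")
    best <- fits[[which.max(lls)]]
    n_eval <- length(trees)
  } else {
    # two independent starting trees guard against NNI local optima: the NJ
    # tree on Hamming distances and the parsimony hill-climb optimum
    starts <- list(neighbor_joining(char_distance(cm)),
                   parsimony_search(cm, "nni_from_nj")$trees[[1L]])
    climbs <- lapply(starts, nni_hill_climb, score_fun = function(tr) -score_fun(tr)$ll)
    hc <- climbs[[which.min(vapply(climbs, `[[`, numeric(1), "score"))]]
    best <- score_fun(hc$tree)
    n_eval <- sum(vapply(climbs, `[[`, numeric(1), "n_eval"))
  }
  final <- optimize_branch_lengths(best$tree, cm)
  structure(list(tree = final, loglik = attr(final, "loglik"),
                 strategy = strategy, n_evaluated = n_eval),
            class = "ml_result")
}

#' @export
print.ml_result <- function(x, ...) {
  cat(sprintf("ML search (%s): log-likelihood %.4f, %d topologies evaluated\n",
              x$strategy, x$loglik, x$n_evaluated))
  invisible(x)
}
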