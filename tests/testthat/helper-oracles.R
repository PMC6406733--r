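# Independent brute-force oracles. These deliberately avoid the package's
# own algorithmic code paths: scores and likelihoods are computed by explicit
# enumeration over ancestral-state assignments, BH by the sort/cummin
# definition, hypergeometric tails by explicit combination sums.

# random 3-state character matrix on `n` named taxa
random_cm <- function(n, nchar) {
  char_matrix(matrix(sample(0:2, n * nchar, replace = TRUE), n, nchar,
                     dimnames = list(LETTERS[seq_len(n)], NULL)))
}

# random unrooted binary tree with positive branch lengths on named taxa
random_tree <- function(n, lengths = TRUE) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$tip.label <- LETTERS[seq_len(n)]
  tr$edge.length <- if (lengths) stats::runif(nrow(tr$edge), 0.05, 2) else NULL
  tr
}

# matrix of every internal-node state assignment (rows) for `nnode` nodes
all_assignments <- function(nnode) {
  as.matrix(expand.grid(rep(list(0:2), nnode)))
}

# minimum-change parsimony score by exhaustive enumeration of all internal
# state assignments
oracle_fitch <- function(tree, cm) {
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE)
  ntip <- ape::Ntip(tree)
  A <- all_assignments(tree$Nnode)
  e <- tree$edge
  m <- unclass(cm)[tree$tip.label, , drop = FALSE]
  total <- 0L
  for (ch in seq_len(ncol(m))) {
    getS <- function(nd) if (nd <= ntip) rep(m[nd, ch], nrow(A)) else A[, nd - ntip]
    cost <- rowSums(vapply(seq_len(nrow(e)),
                           function(r) getS(e[r, 1L]) != getS(e[r, 2L]),
                           logical(nrow(A))))
    total <- total + min(cost)
  }
  total
}

# 3-state symmetric-model log-likelihood by explicit summation over all
# internal-node state assignments (no pruning)
oracle_loglik <- function(tree, cm) {
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE)
  ntip <- ape::Ntip(tree)
  A <- all_assignments(tree$Nnode)
  e <- tree$edge
  bl <- tree$edge.length
  m <- unclass(cm)[tree$tip.label, , drop = FALSE]
  ll <- 0
  for (ch in seq_len(ncol(m))) {
    getS <- function(nd) if (nd <= ntip) rep(m[nd, ch], nrow(A)) else A[, nd - ntip]
    probs <- rep(1 / 3, nrow(A))  # stationary prior on the root state
    for (r in seq_len(nrow(e))) {
      psame <- 1 / 3 + (2 / 3) * exp(-1.5 * bl[r])
      probs <- probs * ifelse(getS(e[r, 1L]) == getS(e[r, 2L]), psame, (1 - psame) / 2)
    }
    ll <- ll + log(sum(probs))
  }
  ll
}

# Benjamini-Hochberg by the textbook definition: sort, p * m / rank, cummin
# from the largest rank down
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# upper-tail hypergeometric by explicit combination sums
oracle_hyper <- function(overlap, set_size, query_size, universe_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# Monte-Carlo family-wise adjusted p for every set of a collection:
# independent loop-based implementation of the min-p null
oracle_adjusted_p <- function(query, sets, universe, n_rep, seed) {
  set.seed(seed)
  U <- length(universe)
  k <- length(query)
  raw <- vapply(sets, function(s)
    oracle_hyper(length(intersect(s, query)), length(s), k, U), numeric(1))
  minp <- vapply(seq_len(n_rep), function(r) {
    q <- sample(universe, k)
    min(vapply(sets, function(s)
      oracle_hyper(length(intersect(s, q)), length(s), k, U), numeric(1)))
  }, numeric(1))
  vapply(raw, function(p) mean(minp <= p + 1e-12), numeric(1))
}

# simulate 3-state characters down a tree under the symmetric model
# (independent of the package's pruning code)
simulate_characters <- function(tree, nchar) {
  if (!ape::is.rooted(tree)) tree <- root_at(tree, tree$tip.label[1L])
  ntip <- ape::Ntip(tree)
  phy <- ape::reorder.phylo(tree, "cladewise")
  states <- matrix(NA_integer_, ntip + phy$Nnode, nchar)
  states[ntip + 1L, ] <- sample(0:2, nchar, replace = TRUE)
  for (r in seq_len(nrow(phy$edge))) {
    psame <- 1 / 3 + (2 / 3) * exp(-1.5 * phy$edge.length[r])
    par <- states[phy$edge[r, 1L], ]
    flip <- stats::runif(nchar) > psame
    shift <- sample(1:2, nchar, replace = TRUE)
    states[phy$edge[r, 2L], ] <- ifelse(flip, (par + shift) %% 3L, par)
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- phy$tip.label
  char_matrix(out)
}

# small expression matrix with metadata for workflow tests
tiny_expr <- function(n_genes = 40, seed = 1) {
  simulate_time_course(n_genes = n_genes, time_points = 0:3, replicates = 2,
                       drift_sd = 1, noise_sd = 0.05, signal_fraction = 0,
                       seed = seed)$expr
}
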