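#' Fitch parsimony score of a tree
#'
#' Minimum number of state changes the character matrix requires on the given
#' topology, by Fitch's post-order set-intersection algorithm, summed over
#' characters. The score does not depend on the root position, so rooted and
#' unrooted binary trees give identical scores.
#'
#' @param tree an [ape::phylo] binary tree whose leaves match the taxa of `cm`.
#' @param cm a `char_matrix` (taxa x characters over states 0/1/2).
#' @param per_character logical; return the per-character change counts
#'   instead of their sum.
#' @param weights optional per-character integer weights (for compressed
#'   pattern matrices).
#' @return integer score, or an integer vector when `per_character = TRUE`.
#' @export
fitch_score <- function(tree, cm, per_character = FALSE, weights = NULL) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- rownames(cm)
  if (!setequal(tree$tip.label, taxa)) {
    d <- c(setdiff(tree$tip.label, taxa), setdiff(taxa, tree$tip.label))
    abort("tree leaves and matrix taxa differ: %s", paste(d, collapse = ", "))
  }
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE)
  if (!ape::is.binary(tree)) abort("fitch_score requires a binary topology")
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(phy)
  nchar_ <- ncol(cm)
  S <- matrix(0L, ntip + phy$Nnode, nchar_)
  S[seq_len(ntip), ] <- bitwShiftL(1L, unclass(cm)[phy$tip.label, , drop = FALSE])
  changes <- integer(nchar_)
  e <- phy$edge
  parents <- rev(unique(rev(e[, 1L])))  # every child edge precedes this position
  for (nd in parents) {
    kids <- e[e[, 1L] == nd, 2L]
    acc <- S[kids[1L], ]
    for (k in kids[-1L]) {
      inter <- bitwAnd(acc, S[k, ])
      hit <- inter == 0L
      changes[hit] <- changes[hit] + 1L
      acc <- ifelse(hit, bitwOr(acc, S[k, ]), inter)
    }
    S[nd, ] <- acc
  }
  if (!is.null(weights)) changes <- changes * weights
  if (per_character) changes else sum(changes)
}

# Hamming-style distance between taxa of a character matrix: mean proportion
# of characters in which two taxa differ. Used as the NJ starting point for
# tree searches on discrete data.
char_distance <- function(cm) {
  m <- unclass(cm)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- mean(m[i, ] != m[j, ])
  structure(d, class = c("expr_dist", "matrix"), metric = "hamming")
}

# every unrooted binary topology on the given taxa, as a plain list of phylo
# objects with their tip labels attached (phangorn::allTrees compresses the
# labels into a multiPhylo attribute, which plain iteration would drop)
all_topologies <- function(n, taxa) {
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  lapply(seq_along(trees), function(i) trees[[i]])
}

# Deterministic NNI hill climb: move to the best strictly-improving neighbor;
# on a plateau, step to the first equal-score neighbor not seen before (up to
# `max_plateau` sideways steps) so flat regions of tree space do not trap the
# search. Minimization.
nni_hill_climb <- function(start, score_fun, max_plateau = 20L) {
  cur <- start
  cur_s <- score_fun(cur)
  n_eval <- 1L
  seen <- paste(sort(tree_splits(cur)), collapse = ";")
  plateau <- 0L
  repeat {
    nbrs <- phangorn::nni(cur)
    nbrs <- lapply(seq_along(nbrs), function(i) nbrs[[i]])
    ns <- vapply(nbrs, score_fun, numeric(1))
    n_eval <- n_eval + length(nbrs)
    if (min(ns) < cur_s) {
      cur <- nbrs[[which.min(ns)]]
      cur_s <- min(ns)
      plateau <- 0L
    } else if (min(ns) == cur_s && plateau < max_plateau) {
      keys <- vapply(nbrs, function(tr) paste(sort(tree_splits(tr)), collapse = ";"),
                     character(1))
      cand <- which(ns == cur_s & !keys %in% seen)
      if (!length(cand)) break
      cur <- nbrs[[cand[1L]]]
      seen <- c(seen, keys[cand[1L]])
      plateau <- plateau + 1L
    } else break
  }
  list(tree = cur, score = cur_s, n_eval = n_eval)
}

# constant parsimony cost contributed by the uninformative characters:
# (number of states present - 1) per character, identical on every topology
uninformative_cost <- function(cm) {
  inf <- informative_mask(cm)
  if (all(inf)) return(0L)
  sum(apply(unclass(cm)[, !inf, drop = FALSE], 2L,
            function(col) sum(tabulate(col + 1L, 3L) > 0L) - 1L))
}

#' Search tree space for the most-parsimonious topology
#'
#' `"exhaustive"` scores every unrooted binary topology (allowed up to 9 taxa,
#' i.e. 135,135 topologies) and returns all co-optimal trees. `"nni_from_nj"`
#' hill-climbs by nearest-neighbor interchange from a neighbor-joining
#' starting tree built on Hamming distances, accepting the first strictly
#' better neighbor of each round and stopping at a local optimum.
#' Uninformative characters cannot change the ranking, so the search scores
#' informative characters only and adds their constant cost back at the end.
#'
#' @param cm a `char_matrix` with >= 4 taxa.
#' @param strategy `"exhaustive"` or `"nni_from_nj"`.
#' @param max_cooptimal cap on the number of co-optimal trees kept (default
#'   100).
#' @return a list of class `parsimony_result`: `trees` (co-optimal trees,
#'   `multiPhylo`), `score`, `strategy`, `n_evaluated`, and `consensus`
#'   (strict consensus of the co-optimal trees).
#' @export
parsimony_search <- function(cm, strategy = c("nni_from_nj", "exhaustive"),
                             max_cooptimal = 100L) {
  strategy <- match.arg(strategy)
  n <- nrow(cm)
  if (n < 4L) abort("tree search needs >= 4 taxa (got %d)", n)
  inf <- informative_mask(cm)
  const <- uninformative_cost(cm)
  cmi <- if (any(inf)) unclass(cm)[, inf, drop = FALSE] else unclass(cm)[, 1L, drop = FALSE] * 0L
  cmi <- char_matrix(cmi)
  score_fun <- function(tr) fitch_score(tr, cmi)
  if (strategy == "exhaustive") {
    if (n > 9L)
      abort("exhaustive search is limited to 9 taxa (%d requested); use strategy = 'nni_from_nj'", n)
    trees <- all_topologies(n, rownames(cm))
    scores <- vapply(trees, score_fun, numeric(1))
    best <- min(scores)
    opt <- trees[scores == best]
    n_eval <- length(trees)
  } else {
    hc <- nni_hill_climb(neighbor_joining(char_distance(cm)), score_fun)
    best <- hc$score
    opt <- list(hc$tree)
    n_eval <- hc$n_eval
  }
  if (length(opt) > max_cooptimal) opt <- opt[seq_len(max_cooptimal)]
  class(opt) <- "multiPhylo"
  cons <- if (length(opt) > 1L) ape::consensus(opt, p = 1) else opt[[1L]]
  structure(list(trees = opt, score = as.integer(best + const),
                 strategy = strategy, n_evaluated = n_eval, consensus = cons),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf("parsimony search (%s): score %d, %d co-optimal tree(s), %d topologies evaluated\n",
              x$strategy, x$score, length(x$trees), x$n_evaluated))
  invisible(x)
}
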