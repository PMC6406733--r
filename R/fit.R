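#' Fit a phylogeny to an expression time course
#'
#' The package's central fitting function: treats samples as taxa and genes
#' as characters and infers their tree by one of three routes.
#' `method = "nj"` builds a neighbor-joining tree from a continuous
#' expression distance matrix. `method = "parsimony"` and `method = "ml"`
#' first express every sample as log2 ratios against the outgroup mean,
#' discretize to down/constant/up at the threshold maximizing the number of
#' parsimony-informative characters, then search tree space by Fitch
#' parsimony or maximum likelihood under the symmetric 3-state Markov model.
#' Optional character bootstrap annotates branch support; the tree is rooted
#' on the outgroup sample group when one is flagged in the metadata.
#'
#' @param expr an [expr_matrix()]; parsimony/ML and rooting require sample
#'   metadata with an outgroup group flagged.
#' @param method `"nj"`, `"parsimony"` or `"ml"`.
#' @param metric distance metric for `method = "nj"` (default `"euclidean"`).
#' @param tau `"auto"` (threshold search, the default) or a fixed positive
#'   threshold; ignored for `method = "nj"`.
#' @param grid optional threshold grid for the search (see
#'   [select_threshold()]).
#' @param search `"nni_from_nj"` (default) or `"exhaustive"` tree search for
#'   parsimony/ML.
#' @param n_boot bootstrap pseudoreplicates (0 disables; the field-standard
#'   choice is 100).
#' @param root root the tree on the outgroup (default `TRUE` when an
#'   outgroup is flagged).
#' @param seed RNG seed for the bootstrap.
#' @return an object of class `expr_phylo`: a list with the fitted `tree`
#'   ([ape::phylo], supports in `node.label` when bootstrapped), `method`,
#'   `metric`, `tau`, `threshold_search`, `char` (the character matrix, for
#'   parsimony/ML), `dist` (the distance matrix, for NJ), `score`
#'   (parsimony) or `loglik` (ML), `outgroup`, `n_boot` and
#'   `temporal_score` (when time ranks are available and the tree is
#'   rooted).
#' @examples
#' sim <- simulate_time_course(n_genes = 200, seed = 1)
#' fit <- expr_phylo(sim$expr, method = "nj")
#' fit
#' @export
expr_phylo <- function(expr, method = c("nj", "parsimony", "ml"),
                       metric = "euclidean", tau = "auto", grid = NULL,
                       search = c("nni_from_nj", "exhaustive"),
                       n_boot = 0L, root = TRUE, seed = NULL) {
  method <- match.arg(method)
  search <- match.arg(search)
  stopifnot(inherits(expr, "expr_matrix"))
  og <- outgroup_samples(expr)
  res <- list(method = method, metric = if (method == "nj") metric else NA_character_,
              outgroup = og, n_boot = as.integer(n_boot), call = match.call())
  if (method == "nj") {
    res$dist <- compute_distance(expr, metric)
    data <- expr
    res$tree <- neighbor_joining(res$dist)
  } else {
    ratio <- log_ratio_matrix(expr)
    if (identical(tau, "auto")) {
      res$threshold_search <- select_threshold(ratio, grid = grid)
      tau <- res$threshold_search$tau
    }
    res$tau <- tau
    data <- discretize(ratio, tau)
    res$char <- data
    if (method == "parsimony") {
      fit <- parsimony_search(data, search)
      res$tree <- fit$trees[[1L]]
      res$score <- fit$score
      res$search <- fit
    } else {
      fit <- ml_search(data, search)
      res$tree <- fit$tree
      res$loglik <- fit$loglik
      res$search <- fit
    }
  }
  if (n_boot > 0L)
    res$tree <- bootstrap_support(data, method, n_reps = n_boot, seed = seed,
                                  metric = metric, tree = res$tree)
  root_leaves <- if (method == "nj") og else attr(res$char, "outgroup")
  root_leaves <- intersect(root_leaves, res$tree$tip.label)
  if (root && length(root_leaves))
    res$tree <- root_at(res$tree, root_leaves)
  if (!is.null(expr$sample_meta) && ape::is.rooted(res$tree)) {
    ranks <- stats::setNames(expr$sample_meta$time_rank, expr$sample_meta$sample_id)
    ranks <- ranks[res$tree$tip.label]
    if (!anyNA(ranks))
      res$temporal_score <- temporal_order_score(res$tree, ranks)
  }
  class(res) <- "expr_phylo"
  res
}

#' @export
print.expr_phylo <- function(x, ...) {
  cat(sprintf("expr_phylo fit (%s): %d taxa, %s\n",
              x$method, ape::Ntip(x$tree),
              if (ape::is.rooted(x$tree)) sprintf("rooted on %s", paste(x$outgroup, collapse = ",")) else "unrooted"))
  if (!is.null(x$tau)) cat(sprintf("  discretization tau = %g\n", x$tau))
  if (!is.null(x$score)) cat(sprintf("  parsimony score = %d\n", x$score))
  if (!is.null(x$loglik)) cat(sprintf("  log-likelihood = %.4f\n", x$loglik))
  if (x$n_boot > 0) cat(sprintf("  bootstrap: %d pseudoreplicates\n", x$n_boot))
  if (!is.null(x$temporal_score))
    cat(sprintf("  temporal-order score = %.3f\n", x$temporal_score))
  invisible(x)
}

#' @export
summary.expr_phylo <- function(object, ...) {
  print(object)
  if (!is.null(object$threshold_search)) print(object$threshold_search)
  sup <- suppressWarnings(as.integer(object$tree$node.label))
  sup <- sup[!is.na(sup)]
  if (length(sup))
    cat(sprintf("  branch support: min %d, median %g, max %d\n",
                min(sup), stats::median(sup), max(sup)))
  invisible(object)
}

#' @export
plot.expr_phylo <- function(x, show_support = TRUE, ...) {
  ape::plot.phylo(x$tree, ...)
  if (show_support && !is.null(x$tree$node.label))
    ape::nodelabels(x$tree$node.label, frame = "none", adj = c(1.2, -0.3), cex = 0.8)
  invisible(x)
}
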