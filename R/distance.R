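#' Pairwise sample distances over all genes
#'
#' Computes a symmetric distance matrix between samples (taxa), using every
#' gene as a coordinate. Supported metrics: `euclidean`, `manhattan`, and
#' `one_minus_pearson` (1 - Pearson correlation of expression profiles, range
#' 0..2).
#'
#' @param expr an [expr_matrix()], or a plain numeric genes x samples matrix.
#' @param metric one of `"euclidean"`, `"manhattan"`, `"one_minus_pearson"`.
#' @return a symmetric numeric matrix with zero diagonal and attribute
#'   `metric`; class `expr_dist`.
#' @export
compute_distance <- function(expr, metric = c("euclidean", "manhattan", "one_minus_pearson")) {
  if (is.character(metric) && length(metric) == 1L &&
      !metric %in% c("euclidean", "manhattan", "one_minus_pearson"))
    abort("unknown metric '%s'; options: euclidean, manhattan, one_minus_pearson", metric)
  metric <- match.arg(metric)
  vals <- if (inherits(expr, "expr_matrix")) expr$values else expr
  if (!is.matrix(vals) || !is.numeric(vals)) abort("expression values must be a numeric matrix")
  if (ncol(vals) < 3L) abort("need >= 3 samples to build a tree-worthy distance matrix")
  if (anyNA(vals)) abort("missing values present; impute before computing distances")
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(t(vals), method = "euclidean")),
    manhattan = as.matrix(stats::dist(t(vals), method = "manhattan")),
    one_minus_pearson = 1 - stats::cor(vals, method = "pearson"))
  diag(d) <- 0
  d <- (d + t(d)) / 2  # enforce exact symmetry against FP noise
  structure(d, class = c("expr_dist", "matrix"), metric = metric)
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou–Nei agglomeration with the Studier–Keppler Q criterion:
#' repeatedly joins the pair (i, j) minimizing
#' `Q(i,j) = (n - 2) d(i,j) - R(i) - R(j)` (R = row sums), assigning pendant
#' lengths by the standard formulas and reducing the matrix with
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties on Q are broken toward
#' the lexicographically smallest pair of current indices, so the result is
#' deterministic. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling edge, preserving the path length
#' through the joined pair.
#'
#' @param dm symmetric numeric distance matrix with labeled rows/columns
#'   (e.g. from [compute_distance()]).
#' @return an unrooted binary [ape::phylo] tree.
#' @export
neighbor_joining <- function(dm) {
  D <- unclass(as.matrix(dm))
  labs <- rownames(D) %||% colnames(D)
  if (is.null(labs)) abort("distance matrix must have taxon labels")
  n <- nrow(D)
  if (n < 3L) abort("neighbor joining needs >= 3 taxa (got %d)", n)
  if (max(abs(D - t(D))) > 1e-9) abort("distance matrix is not symmetric")
  frag <- labs
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    hits <- which(Q <= min(Q) + 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(bi + bj, 0); bj <- 0 }
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    merged <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_bl(bi), frag[j], fmt_bl(bj))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    frag <- c(frag[keep], merged)
    n <- n - 1L
  }
  a <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  c_ <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt_bl(a), frag[2], fmt_bl(b), frag[3], fmt_bl(c_))
  ape::read.tree(text = nwk)
}

#' Root a tree on its outgroup edge
#'
#' Inserts a root on the edge separating the outgroup leaves from the rest,
#' splitting that edge's length equally between the two root children. The
#' outgroup must be monophyletic in the unrooted tree.
#'
#' @param tree an [ape::phylo] tree (rooted input is unrooted first).
#' @param outgroup character vector of one or more leaf labels.
#' @return a rooted [ape::phylo] tree.
#' @export
root_at <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  outgroup <- as.character(outgroup)
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) abort("outgroup leaf/leaves not in tree: %s", paste(missing, collapse = ", "))
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  if (length(outgroup) > 1L && !ape::is.monophyletic(tree, outgroup))
    abort("outgroup {%s} is not monophyletic in the tree; conflicting leaves cannot define a root edge",
          paste(outgroup, collapse = ", "))
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE, edgelabel = TRUE)
  root <- ape::Ntip(rooted) + 1L
  ce <- which(rooted$edge[, 1L] == root)
  if (length(ce) == 2L && !is.null(rooted$edge.length)) {
    half <- sum(rooted$edge.length[ce]) / 2
    rooted$edge.length[ce] <- half
  }
  rooted
}
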