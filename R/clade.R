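#' Split a rooted tree into its two major clades
#'
#' The two children of the root define the split (after optionally pruning
#' the outgroup leaves, which only serve to place the root). For an
#' expression time course this typically separates the early-treatment from
#' the late-treatment samples.
#'
#' @param tree a rooted [ape::phylo] tree with >= 4 leaves (supports in
#'   `node.label` are carried through when present).
#' @param exclude_outgroup drop the outgroup leaves before splitting
#'   (default `TRUE` when `outgroup` is given).
#' @param outgroup character vector of outgroup leaf labels (optional).
#' @return a list of class `clade_split`: `clade_a`, `clade_b` (leaf label
#'   vectors), and `support` (bootstrap percentage at the defining edge, `NA`
#'   if absent).
#' @export
split_major_clades <- function(tree, exclude_outgroup = !is.null(outgroup),
                               outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    abort("split_major_clades needs a rooted tree; use root_at() first")
  if (exclude_outgroup && length(outgroup)) {
    tree <- ape::drop.tip(tree, intersect(outgroup, tree$tip.label))
    if (is.null(tree) || !ape::is.rooted(tree))
      abort("tree collapsed while pruning the outgroup")
  }
  ntip <- ape::Ntip(tree)
  if (ntip < 4L) abort("need >= 4 leaves to define two major clades (got %d)", ntip)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  if (length(kids) != 2L)
    abort("root has %d children; reroot the tree so the root is binary", length(kids))
  tips_of <- function(nd) {
    if (nd <= ntip) return(tree$tip.label[nd])
    ape::extract.clade(tree, nd)$tip.label
  }
  a <- tips_of(kids[1L])
  b <- tips_of(kids[2L])
  support <- NA_integer_
  if (!is.null(tree$node.label)) {
    lab <- c(tree$node.label, rep("", ntip))[ifelse(kids > ntip, kids - ntip, NA)]
    lab <- lab[!is.na(lab) & nzchar(lab)]
    if (length(lab)) support <- suppressWarnings(as.integer(lab[1L]))
  }
  structure(list(clade_a = a, clade_b = b, support = support),
            class = "clade_split")
}

#' @export
print.clade_split <- function(x, ...) {
  cat(sprintf("clade split (support %s):\n  A (%d): %s\n  B (%d): %s\n",
              ifelse(is.na(x$support), "n/a", x$support),
              length(x$clade_a), paste(x$clade_a, collapse = ", "),
              length(x$clade_b), paste(x$clade_b, collapse = ", ")))
  invisible(x)
}

# vectorized Welch two-sample t-test across the rows of a matrix
welch_rows <- function(vals, ga, gb) {
  n1 <- length(ga); n2 <- length(gb)
  m1 <- rowMeans(vals[, ga, drop = FALSE])
  m2 <- rowMeans(vals[, gb, drop = FALSE])
  v1 <- apply(vals[, ga, drop = FALSE], 1L, stats::var)
  v2 <- apply(vals[, gb, drop = FALSE], 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  # genes with zero variance in both groups: no evidence either way
  degenerate <- !is.finite(stat)
  stat[degenerate] <- 0
  p[degenerate] <- 1
  list(statistic = stat, p = p, delta = m1 - m2)
}

#' Genes differentiating the two major clades
#'
#' Two modes. `"welch_bh"` (default) applies a per-gene two-sample Welch
#' t-test between the samples of the two clades with Benjamini–Hochberg
#' adjustment; a gene is significant at `q < alpha`. `"synapomorphy"` is the
#' phylogenetic reading: a gene is a hit when its discretized state is
#' uniform within each clade and differs between the clades (no p-values are
#' produced in this mode).
#'
#' @param expr an [expr_matrix()].
#' @param split a `clade_split` from [split_major_clades()].
#' @param mode `"welch_bh"` or `"synapomorphy"`.
#' @param alpha significance level on the BH-adjusted q (default 0.05).
#' @param cm a `char_matrix` (taxa x genes), required for
#'   `mode = "synapomorphy"`.
#' @return a data frame of class `differential_genes` with columns `gene`,
#'   `statistic`, `p`, `q`, `direction` (`"up_in_a"`/`"up_in_b"`/`"none"`),
#'   `significant`, and attribute `mode`.
#' @export
differential_genes <- function(expr, split, mode = c("welch_bh", "synapomorphy"),
                               alpha = 0.05, cm = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(split, "clade_split"))
  if (mode == "welch_bh") {
    stopifnot(inherits(expr, "expr_matrix"))
    ga <- intersect(split$clade_a, colnames(expr$values))
    gb <- intersect(split$clade_b, colnames(expr$values))
    if (length(ga) < 2L || length(gb) < 2L)
      abort("welch_bh needs >= 2 samples per clade (got %d and %d); consider mode = 'synapomorphy'",
            length(ga), length(gb))
    w <- welch_rows(expr$values, ga, gb)
    q <- stats::p.adjust(w$p, method = "BH")
    res <- data.frame(
      gene = rownames(expr$values),
      statistic = w$statistic, p = w$p, q = q,
      direction = ifelse(w$delta > 0, "up_in_a",
                         ifelse(w$delta < 0, "up_in_b", "none")),
      significant = q < alpha,
      stringsAsFactors = FALSE)
  } else {
    if (is.null(cm)) abort("synapomorphy mode needs the discretized char_matrix via `cm`")
    ga <- intersect(split$clade_a, rownames(cm))
    gb <- intersect(split$clade_b, rownames(cm))
    if (!length(ga) || !length(gb)) abort("clades not represented among the matrix taxa")
    m <- unclass(cm)
    ua <- apply(m[ga, , drop = FALSE], 2L, function(s) if (length(unique(s)) == 1L) s[1L] else NA_integer_)
    ub <- apply(m[gb, , drop = FALSE], 2L, function(s) if (length(unique(s)) == 1L) s[1L] else NA_integer_)
    hit <- !is.na(ua) & !is.na(ub) & ua != ub
    res <- data.frame(
      gene = colnames(m) %||% sprintf("char%d", seq_len(ncol(m))),
      statistic = NA_real_, p = NA_real_, q = NA_real_,
      direction = ifelse(hit, ifelse(ua > ub, "up_in_a", "up_in_b"), "none"),
      significant = hit,
      stringsAsFactors = FALSE)
  }
  attr(res, "mode") <- mode
  class(res) <- c("differential_genes", "data.frame")
  res
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing at least `overlap` query genes inside a set of
#' `set_size` genes when `query_size` genes are drawn without replacement
#' from a universe of `universe_size`.
#'
#' @param overlap,set_size,query_size,universe_size non-negative integer
#'   counts with `overlap <= min(set_size, query_size)` and all counts
#'   `<= universe_size`.
#' @return `P(X >= overlap)` for `X` hypergeometric.
#' @export
hypergeometric_p <- function(overlap, set_size, query_size, universe_size) {
  v <- c(overlap, set_size, query_size, universe_size)
  if (any(v < 0) || any(v != round(v))) abort("counts must be non-negative integers")
  if (overlap > min(set_size, query_size) || max(set_size, query_size) > universe_size)
    abort("inconsistent counts: overlap %d, set %d, query %d, universe %d",
          overlap, set_size, query_size, universe_size)
  stats::phyper(overlap - 1, set_size, universe_size - set_size, query_size,
                lower.tail = FALSE)
}

#' Gene-set enrichment with permutation-adjusted p-values
#'
#' For each gene set, the raw p-value is the upper-tail hypergeometric
#' probability of the observed overlap with the query. The adjusted p-value
#' is family-wise: the fraction of `n_perm` random queries of the same size
#' (drawn uniformly without replacement from the universe) whose *minimum*
#' raw p-value across the whole collection is at most the observed set's raw
#' p-value.
#'
#' @param query character vector of query gene ids (subset of `universe`).
#' @param collection a [gene_set_collection()]; each set is intersected with
#'   the universe before testing.
#' @param universe character vector of background gene ids; defaults to the
#'   collection's recorded universe.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return a data frame of class `enrichment_result` with one row per set:
#'   `set`, `overlap`, `set_size`, `query_size`, `universe_size`, `p`,
#'   `adj_p`, `n_perm`.
#' @export
enrichment <- function(query, collection, universe = NULL, n_perm = 1000L,
                       seed = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- universe %||% attr(collection, "universe")
  if (is.null(universe)) abort("no universe: pass `universe` or build the collection with one")
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(query)) abort("empty query")
  out <- setdiff(query, universe)
  if (length(out)) abort("query gene(s) outside the universe: %s", paste(out, collapse = ", "))
  sets <- lapply(collection, intersect, universe)
  U <- length(universe)
  k <- length(query)
  sizes <- lengths(sets)
  overlaps <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  p_raw <- stats::phyper(overlaps - 1, sizes, U - sizes, k, lower.tail = FALSE)
  member <- vapply(sets, function(s) universe %in% s, logical(U))  # U x nsets
  min_p <- with_seed(seed, vapply(seq_len(n_perm), function(r) {
    idx <- sample.int(U, k)
    ov <- colSums(member[idx, , drop = FALSE])
    min(stats::phyper(ov - 1, sizes, U - sizes, k, lower.tail = FALSE))
  }, numeric(1)))
  adj <- vapply(p_raw, function(p) mean(min_p <= p + 1e-12), numeric(1))
  res <- data.frame(set = names(sets), overlap = overlaps, set_size = sizes,
                    query_size = k, universe_size = U, p = p_raw, adj_p = adj,
                    n_perm = as.integer(n_perm), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  res[order(res$p), ]
}
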