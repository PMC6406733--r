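#' Log2 ratios of each sample versus the outgroup mean
#'
#' For every gene, subtracts the mean log2 expression over the outgroup
#' replicates from every non-outgroup sample, yielding a genes x samples
#' matrix of log2 fold changes against the reference (e.g. passage-0 or
#' untreated) sample group.
#'
#' @param expr an [expr_matrix()] with sample metadata attached.
#' @param outgroup optional character vector of outgroup sample ids; defaults
#'   to the samples flagged `is_outgroup` in the metadata.
#' @return an object of class `ratio_matrix`: numeric matrix (genes x
#'   non-outgroup samples) with attribute `outgroup` naming the reference
#'   samples.
#' @export
log_ratio_matrix <- function(expr, outgroup = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  expr <- ensure_log2(expr)
  og <- outgroup %||% outgroup_samples(expr)
  if (!length(og))
    abort("no outgroup designated: flag an outgroup sample group in sample_meta or pass `outgroup`")
  if (!all(og %in% colnames(expr$values)))
    abort("unknown outgroup sample(s): %s",
          paste(setdiff(og, colnames(expr$values)), collapse = ", "))
  ref <- rowMeans(expr$values[, og, drop = FALSE])
  rest <- setdiff(colnames(expr$values), og)
  if (!length(rest)) abort("all samples are outgroup; nothing to compare")
  out <- expr$values[, rest, drop = FALSE] - ref
  structure(out, class = c("ratio_matrix", "matrix"), outgroup = og)
}

#' Discretize log ratios into three character states
#'
#' Each cell becomes state 2 (up) if the log2 ratio is `>= tau`, state 0
#' (down) if `<= -tau`, and state 1 (constant) otherwise. Taxa are samples
#' (matrix rows of the result), characters are genes. The outgroup itself is
#' appended as an all-constant taxon so trees built from the characters can
#' be rooted on it.
#'
#' @param ratio a `ratio_matrix` from [log_ratio_matrix()].
#' @param tau positive threshold on |log2 ratio|.
#' @param add_outgroup logical; include the all-constant outgroup taxon
#'   (default `TRUE`).
#' @param outgroup_label label for the outgroup taxon; defaults to the first
#'   outgroup sample id.
#' @return an object of class `char_matrix`: integer matrix (taxa x
#'   characters) over `{0, 1, 2}` with attributes `tau`, `informative`
#'   (per-character logical mask, computed when there are >= 4 taxa) and
#'   `outgroup` (the outgroup taxon label, or `NA`).
#' @export
discretize <- function(ratio, tau, add_outgroup = TRUE, outgroup_label = NULL) {
  if (!inherits(ratio, "ratio_matrix")) abort("`ratio` must come from log_ratio_matrix()")
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    abort("`tau` must be a single positive number")
  states <- matrix(1L, ncol(ratio), nrow(ratio),
                   dimnames = list(colnames(ratio), rownames(ratio)))
  states[t(ratio) >= tau] <- 2L
  states[t(ratio) <= -tau] <- 0L
  og_label <- NA_character_
  if (add_outgroup) {
    og_label <- outgroup_label %||% attr(ratio, "outgroup")[1L]
    states <- rbind(states, matrix(1L, 1, ncol(states),
                                   dimnames = list(og_label, NULL)))
  }
  cm <- structure(states, class = c("char_matrix", "matrix"),
                  tau = tau, outgroup = og_label, informative = NULL)
  if (nrow(states) >= 4L)
    attr(cm, "informative") <- informative_mask(cm)
  cm
}

#' Construct a character matrix directly
#'
#' @param states integer matrix (taxa x characters) with values in `{0,1,2}`
#'   and unique row names.
#' @param tau threshold recorded on the object (optional).
#' @param outgroup outgroup taxon label or `NA`.
#' @return a `char_matrix`.
#' @export
char_matrix <- function(states, tau = NA_real_, outgroup = NA_character_) {
  if (!is.matrix(states)) abort("`states` must be a matrix")
  storage.mode(states) <- "integer"
  if (!all(states %in% 0:2)) abort("states must be 0 (down), 1 (constant) or 2 (up)")
  if (is.null(rownames(states)) || anyDuplicated(rownames(states)))
    abort("taxa (rows) must carry unique names")
  cm <- structure(states, class = c("char_matrix", "matrix"),
                  tau = tau, outgroup = outgroup, informative = NULL)
  if (nrow(states) >= 4L) attr(cm, "informative") <- informative_mask(cm)
  cm
}

# per-character parsimony-informativeness: >=2 states each seen in >=2 taxa
informative_mask <- function(cm) {
  apply(unclass(cm), 2L, function(col) {
    sum(tabulate(col + 1L, 3L) >= 2L) >= 2L
  })
}

#' Count parsimony-informative characters
#'
#' A character is parsimony-informative when at least two of its states each
#' occur in at least two taxa; only such characters can discriminate between
#' topologies under parsimony.
#'
#' @param cm a `char_matrix` with at least 4 taxa.
#' @return integer count of informative characters.
#' @export
count_informative <- function(cm) {
  if (!inherits(cm, "char_matrix")) abort("`cm` must be a char_matrix")
  if (nrow(cm) < 4L)
    abort("informative sites require >= 4 taxa (got %d): no character can be informative", nrow(cm))
  sum(informative_mask(cm))
}

#' Choose the discretization threshold maximizing informative characters
#'
#' Evaluates [count_informative()] over a grid of candidate thresholds and
#' selects the value attaining the maximum (ties broken toward the smallest
#' threshold). The objective is not monotone in the threshold, so the whole
#' grid is scanned. The default grid spans 21 evenly spaced values between
#' the 50th and 99th percentile of |log2 ratio|, i.e. from "almost nothing
#' constant" to "almost everything constant".
#'
#' @param ratio a `ratio_matrix`.
#' @param grid numeric vector of positive candidate thresholds, or `NULL` for
#'   the quantile-derived default.
#' @param include_outgroup logical; count informativeness with the
#'   all-constant outgroup taxon included (default `TRUE`).
#' @return a list of class `threshold_search` with elements `grid`,
#'   `informative` (count per grid value), `tau` (selected threshold) and
#'   `include_outgroup`.
#' @export
select_threshold <- function(ratio, grid = NULL, include_outgroup = TRUE) {
  if (!inherits(ratio, "ratio_matrix")) abort("`ratio` must come from log_ratio_matrix()")
  if (is.null(grid)) {
    q <- stats::quantile(abs(ratio), c(0.5, 0.99), names = FALSE)
    if (q[2] <= 0) q[2] <- max(abs(ratio), 1e-6)
    grid <- seq(max(q[1], 1e-6), max(q[2], 2e-6), length.out = 21L)
  }
  grid <- sort(unique(as.numeric(grid)))
  if (!length(grid) || any(grid <= 0) || any(!is.finite(grid)))
    abort("`grid` must be a non-empty set of positive thresholds")
  counts <- vapply(grid, function(tau) {
    cm <- discretize(ratio, tau, add_outgroup = include_outgroup)
    if (nrow(cm) < 4L)
      abort("threshold search needs >= 4 taxa in the character matrix")
    count_informative(cm)
  }, integer(1))
  sel <- grid[which.max(counts)]  # which.max takes the first (smallest) tie
  structure(list(grid = grid, informative = counts, tau = sel,
                 include_outgroup = include_outgroup),
            class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf("threshold search over %d cut-offs (outgroup %s)\n",
              length(x$grid), if (x$include_outgroup) "included" else "excluded"))
  cat(sprintf("selected tau = %g with %d informative characters\n",
              x$tau, max(x$informative)))
  invisible(x)
}

#' @export
print.char_matrix <- function(x, ...) {
  inf <- attr(x, "informative")
  cat(sprintf("char_matrix: %d taxa x %d characters (tau = %s)%s\n",
              nrow(x), ncol(x), format(attr(x, "tau")),
              if (is.null(inf)) "" else sprintf(", %d informative", sum(inf))))
  invisible(x)
}
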