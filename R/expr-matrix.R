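#' Expression matrix with sample metadata
#'
#' Container for a genes x samples matrix of expression values together with
#' the per-sample metadata the phylogenetic workflow needs: an ordinal time
#' rank, a replicate identifier, and an outgroup flag marking the reference
#' sample group (e.g. the untreated / passage-0 samples) used for rooting and
#' for defining up/down expression states.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimensions must carry unique names.
#' @param sample_meta data frame with one row per sample and columns
#'   `sample_id`, `time_rank` (non-negative integer), `replicate` (character)
#'   and `is_outgroup` (logical). May be `NULL`; metadata can be attached
#'   later with [set_sample_meta()].
#' @param log2_scale logical; `TRUE` if `values` are already on the log2
#'   scale. Discretization requires log-scale data and will transform
#'   linear-scale input with `log2(x + 1)`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `sample_meta` and `log2_scale`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' em <- expr_matrix(m, log2_scale = TRUE)
#' dim(em$values)
#' @export
expr_matrix <- function(values, sample_meta = NULL, log2_scale = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix (genes x samples)")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    abort("`values` must have both row (gene) and column (sample) names")
  dup <- gid[duplicated(gid)]
  if (length(dup))
    abort("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- sid[duplicated(sid)]
  if (length(dup))
    abort("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    abort("`values` contains missing or non-finite entries; impute or filter first")
  x <- structure(
    list(values = values, sample_meta = NULL, log2_scale = isTRUE(log2_scale)),
    class = "expr_matrix"
  )
  if (!is.null(sample_meta)) x <- set_sample_meta(x, sample_meta)
  x
}

#' Attach per-sample metadata to an expression matrix
#'
#' @param x an [expr_matrix()].
#' @param meta data frame with columns `sample_id`, `time_rank`, `replicate`,
#'   `is_outgroup`, covering every sample of `x` exactly once.
#' @return `x` with `sample_meta` set (rows ordered as the matrix columns).
#' @export
set_sample_meta <- function(x, meta) {
  stopifnot(inherits(x, "expr_matrix"), is.data.frame(meta))
  need <- c("sample_id", "time_rank", "replicate", "is_outgroup")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    abort("sample_meta is missing column(s): %s", paste(miss, collapse = ", "))
  sid <- colnames(x$values)
  if (!setequal(meta$sample_id, sid) || nrow(meta) != length(sid))
    abort("sample_meta must describe each sample exactly once")
  meta <- meta[match(sid, meta$sample_id), need, drop = FALSE]
  rownames(meta) <- NULL
  if (any(meta$time_rank < 0) || any(meta$time_rank != round(meta$time_rank)))
    abort("time_rank must be non-negative integers")
  meta$time_rank <- as.integer(meta$time_rank)
  meta$replicate <- as.character(meta$replicate)
  meta$is_outgroup <- as.logical(meta$is_outgroup)
  if (anyNA(meta$is_outgroup)) abort("is_outgroup must be TRUE/FALSE")
  og_ranks <- unique(meta$time_rank[meta$is_outgroup])
  if (length(og_ranks) > 1)
    abort("outgroup samples span more than one time rank (%s); exactly one sample group may be flagged",
          paste(og_ranks, collapse = ", "))
  x$sample_meta <- meta
  x
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log2_scale) "log2" else "linear"))
  if (!is.null(x$sample_meta)) {
    og <- x$sample_meta$sample_id[x$sample_meta$is_outgroup]
    cat(sprintf("time ranks: %s; outgroup: %s\n",
                paste(sort(unique(x$sample_meta$time_rank)), collapse = " "),
                if (length(og)) paste(og, collapse = ", ") else "<none>"))
  } else cat("no sample metadata attached\n")
  invisible(x)
}

#' Ensure an expression matrix is on the log2 scale
#'
#' Linear-scale values are transformed with `log2(x + 1)`; log-scale input is
#' returned unchanged. Symmetric up/down thresholds in the discretization step
#' are only meaningful on log ratios.
#'
#' @param x an [expr_matrix()].
#' @return an [expr_matrix()] with `log2_scale = TRUE`.
#' @export
ensure_log2 <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$log2_scale) return(x)
  if (any(x$values < 0))
    abort("linear-scale values must be non-negative for log2(x + 1) transform")
  x$values <- log2(x$values + 1)
  x$log2_scale <- TRUE
  x
}

#' Collapse probes to gene symbols by the max-mean rule
#'
#' Microarray platforms measure several probes per gene; when a probe-to-gene
#' map is supplied, each gene keeps the probe with the highest mean expression
#' across samples. Probes without a mapping are dropped.
#'
#' @param x an [expr_matrix()] whose rows are probe ids.
#' @param map data frame with columns `probe_id` and `gene_id`.
#' @return an [expr_matrix()] with one row per mapped gene.
#' @export
collapse_probes <- function(x, map) {
  stopifnot(inherits(x, "expr_matrix"), is.data.frame(map))
  if (!all(c("probe_id", "gene_id") %in% names(map)))
    abort("`map` needs columns probe_id and gene_id")
  map <- map[map$probe_id %in% rownames(x$values), , drop = FALSE]
  if (!nrow(map)) abort("no probes of the matrix appear in `map`")
  means <- rowMeans(x$values)[map$probe_id]
  keep <- vapply(split(seq_len(nrow(map)), map$gene_id),
                 function(i) map$probe_id[i][which.max(means[i])], character(1))
  out <- x$values[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  expr_matrix(out, x$sample_meta, x$log2_scale)
}

#' Impute missing expression values by the per-gene median
#'
#' Loading rejects missing values by default; this explicit step replaces
#' `NA`s gene-wise by the median of that gene's observed samples.
#'
#' @param values numeric matrix possibly containing `NA`s.
#' @return the matrix with `NA`s imputed.
#' @export
impute_gene_median <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  for (i in which(rowSums(is.na(values)) > 0)) {
    med <- stats::median(values[i, ], na.rm = TRUE)
    if (is.na(med)) abort("gene %s has no observed values", rownames(values)[i] %||% i)
    values[i, is.na(values[i, ])] <- med
  }
  values
}

#' Sample ids of the flagged outgroup group
#'
#' @param x an [expr_matrix()].
#' @return character vector of outgroup sample ids (may be several
#'   replicates; empty when none are flagged).
#' @export
outgroup_samples <- function(x) {
  if (is.null(x$sample_meta)) return(character(0))
  x$sample_meta$sample_id[x$sample_meta$is_outgroup]
}
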