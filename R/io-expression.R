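#' Read an expression table from disk
#'
#' Two dialects are supported. `"tsv"` expects a plain tab-separated table
#' whose first column holds gene ids and whose header names the samples.
#' `"geo_series_matrix"` reads the data block of a GEO series-matrix file:
#' everything between the `!series_matrix_table_begin` and
#' `!series_matrix_table_end` markers, with quoted sample accessions in the
#' header; all other `!`-prefixed annotation lines are skipped.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` or `"geo_series_matrix"`.
#' @param sample_meta optional data frame passed to [set_sample_meta()], or a
#'   path to a TSV sidecar with the same columns.
#' @param log2_scale logical flag recorded on the result (series-matrix files
#'   are usually already log2).
#' @return an [expr_matrix()].
#' @export
read_expression_table <- function(path,
                                  dialect = c("tsv", "geo_series_matrix"),
                                  sample_meta = NULL,
                                  log2_scale = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "geo_series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      abort("no series-matrix data block found (begin/end markers missing or empty)")
    lines <- lines[(beg + 1L):(end - 1L)]
    lines <- gsub('"', "", lines, fixed = TRUE)
  }
  tab <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) abort("expression table needs an id column and >=1 sample column")
  gid <- tab[[1L]]
  dup <- unique(gid[duplicated(gid)])
  if (length(dup)) abort("duplicate gene id(s): %s", paste(dup, collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) & nzchar(trimws(vals)), arr.ind = TRUE)
  if (nrow(bad))
    abort("non-numeric value '%s' at gene %s, sample %s",
          vals[bad[1, 1], bad[1, 2]], gid[bad[1, 1]], colnames(vals)[bad[1, 2]])
  if (anyNA(num))
    abort("missing value at gene %s, sample %s (use impute_gene_median() explicitly)",
          gid[which(is.na(num), arr.ind = TRUE)[1, 1]],
          colnames(vals)[which(is.na(num), arr.ind = TRUE)[1, 2]])
  dimnames(num) <- list(gid, colnames(vals))
  if (is.character(sample_meta) && length(sample_meta) == 1L)
    sample_meta <- utils::read.delim(sample_meta, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE)
  expr_matrix(num, sample_meta = sample_meta, log2_scale = log2_scale)
}

#' Write an expression matrix as a TSV table
#'
#' @param x an [expr_matrix()].
#' @param path output path; first column `gene_id`, then one column per sample.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
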