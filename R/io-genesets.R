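#' Read a GMT gene-set collection
#'
#' GMT is the tab-separated gene-set format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to a `.gmt` file.
#' @param universe optional explicit background gene-id vector recorded on
#'   the collection.
#' @return an object of class `gene_set_collection`: a named list of
#'   character vectors with attributes `description` and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty GMT file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    abort("GMT line %d has fewer than 3 fields (name, description, >=1 gene)", bad[1L])
  nm <- vapply(parts, `[`, character(1), 1L)
  gene_set_collection(
    sets = lapply(parts, function(p) unique(p[-(1:2)])) |> stats::setNames(nm),
    description = stats::setNames(vapply(parts, `[`, character(1), 2L), nm),
    universe = universe
  )
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (non-empty, unique names).
#' @param description optional named character vector of set descriptions.
#' @param universe optional explicit background gene-id vector.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL, universe = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    abort("`sets` must be a named list of gene-id vectors")
  if (anyDuplicated(names(sets)))
    abort("duplicate set name(s): %s",
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(lengths(sets) == 0L))
    abort("empty set(s): %s", paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  structure(lapply(sets, as.character), class = "gene_set_collection",
            description = description, universe = universe)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- attr(collection, "description")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}
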