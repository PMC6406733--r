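#' Read a Newick tree file
#'
#' Thin wrapper around [ape::read.tree()] with explicit syntax validation:
#' unbalanced parentheses and dangling commas are reported with the character
#' offset at which the problem is detected.
#'
#' @param path path to a Newick file, or a Newick string via `text`.
#' @param text Newick string (alternative to `path`).
#' @return an [ape::phylo] tree; internal node labels (bootstrap supports)
#'   are preserved as written.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path)) abort("file not found: %s", path %||% "<NULL>")
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  validate_newick(text)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) abort("ape could not parse the Newick string")
  tr
}

# minimal syntax check reporting a 1-based character offset
validate_newick <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  prev <- ""
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) abort("malformed Newick: unmatched ')' at offset %d", i)
      if (prev == ",") abort("malformed Newick: dangling comma at offset %d", i - 1L)
    }
    if (ch == "," && prev %in% c("", "(", ","))
      abort("malformed Newick: dangling comma at offset %d", i)
    if (!grepl("[[:space:]]", ch)) prev <- ch
  }
  if (depth != 0L)
    abort("malformed Newick: %d unclosed '(' at offset %d (end of input)", depth, length(chars))
  if (prev != ";" && !grepl(";", text))
    abort("malformed Newick: missing terminating ';' at offset %d", length(chars))
  invisible(TRUE)
}

#' Write a tree as Newick
#'
#' Branch lengths are written with enough digits to round-trip to 1e-6;
#' internal node labels (e.g. integer bootstrap supports) are emitted as-is.
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path; if `NULL`, the Newick string is returned instead.
#' @return `path` invisibly, or the Newick string when `path` is `NULL`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}
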