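#' Write a character matrix for external phylogeny tools
#'
#' Two interchange formats: relaxed PHYLIP (header line `ntaxa nchar`, then
#' one `name  states` line per taxon, names of any length) and NEXUS (a DATA
#' block with `FORMAT DATATYPE=STANDARD SYMBOLS="012"`).
#'
#' @param cm a `char_matrix`.
#' @param path output path.
#' @param format `"phylip_relaxed"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(cm, path, format = c("phylip_relaxed", "nexus")) {
  format <- match.arg(format)
  if (!inherits(cm, "char_matrix")) abort("`cm` must be a char_matrix")
  if (nrow(cm) == 0L || ncol(cm) == 0L) abort("cannot write an empty character matrix")
  taxa <- rownames(cm)
  if (any(grepl("[[:space:];]", taxa)))
    abort("taxon names may not contain whitespace or ';' in these formats")
  seqs <- apply(unclass(cm), 1L, paste, collapse = "")
  lines <- switch(format,
    phylip_relaxed = c(sprintf("%d %d", nrow(cm), ncol(cm)),
                       sprintf("%s  %s", taxa, seqs)),
    nexus = c("#NEXUS", "BEGIN DATA;",
              sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(cm), ncol(cm)),
              '  FORMAT DATATYPE=STANDARD SYMBOLS="012" MISSING=? GAP=-;',
              "  MATRIX",
              sprintf("    %s  %s", taxa, seqs),
              "  ;", "END;"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a character matrix written by [write_character_matrix()]
#'
#' @param path input path.
#' @param format `"phylip_relaxed"` or `"nexus"`.
#' @return a `char_matrix`.
#' @export
read_character_matrix <- function(path, format = c("phylip_relaxed", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "phylip_relaxed") {
    hdr <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
    if (length(hdr) != 2L) abort("malformed PHYLIP header: %s", lines[1L])
    ntax <- as.integer(hdr[1L]); nchar_ <- as.integer(hdr[2L])
    body <- lines[-1L][nzchar(trimws(lines[-1L]))]
    if (length(body) != ntax) abort("expected %d taxa, found %d lines", ntax, length(body))
  } else {
    i0 <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)
    i1 <- grep("^\\s*;\\s*$", lines)
    i1 <- i1[i1 > i0[1L]][1L]
    if (!length(i0) || is.na(i1)) abort("no MATRIX block found in NEXUS file")
    body <- trimws(lines[(i0[1L] + 1L):(i1 - 1L)])
    body <- body[nzchar(body)]
    nchar_ <- NULL
  }
  parts <- strsplit(trimws(body), "[[:space:]]+")
  taxa <- vapply(parts, `[`, character(1), 1L)
  seqs <- vapply(parts, function(p) paste(p[-1L], collapse = ""), character(1))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    abort("taxa have unequal character counts: %s", paste(unique(lens), collapse = ", "))
  if (!is.null(nchar_) && lens[1L] != nchar_)
    abort("header promises %d characters but rows hold %d", nchar_, lens[1L])
  digits <- do.call(rbind, lapply(strsplit(seqs, ""), function(s) {
    v <- suppressWarnings(as.integer(s))
    if (anyNA(v)) abort("non-state symbol '%s' in matrix", s[which(is.na(v))[1L]])
    v
  }))
  rownames(digits) <- taxa
  char_matrix(digits)
}
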