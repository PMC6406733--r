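#' Construct a well-level drug-screen dataset
#'
#' Holds one record per well of a viability screen: plate, well coordinates,
#' drug (or control kind for drug-free wells), treatment condition, knockdown
#' arm, plating density and the viability readout (e.g. CellTiterGlo signal).
#'
#' @param df data frame with columns `plate_id`, `well_row`, `well_col`,
#'   `drug_id` (`NA` for control wells), `control_kind` (one of `empty`,
#'   `DMSO`, `no_drug`, or `NA` for drug wells), `condition` (`vehicle` or
#'   `tgfb`), `arm` (`siCtrl`, `siATG16L1` or `none`), `density` (`low` or
#'   `high`) and `signal` (non-negative numeric).
#' @return an object of class `screen_dataset` (a validated data frame).
#' @export
screen_dataset <- function(df) {
  need <- c("plate_id", "well_row", "well_col", "drug_id", "control_kind",
            "condition", "arm", "density", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("screen table is missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  key <- paste(df$plate_id, df$well_row, df$well_col)
  if (anyDuplicated(key))
    abort("duplicate well(s): %s", paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))], collapse = "; "))
  if (!all(df$condition %in% c("vehicle", "tgfb")))
    abort("condition must be 'vehicle' or 'tgfb'")
  if (!all(df$arm %in% c("siCtrl", "siATG16L1", "none")))
    abort("arm must be 'siCtrl', 'siATG16L1' or 'none'")
  if (!all(df$density %in% c("low", "high")))
    abort("density must be 'low' or 'high'")
  ok_ctrl <- is.na(df$control_kind) | df$control_kind %in% c("empty", "DMSO", "no_drug")
  if (!all(ok_ctrl)) abort("control_kind must be empty, DMSO, no_drug or NA")
  if (any(is.na(df$drug_id) & is.na(df$control_kind)))
    abort("each well needs a drug_id or a control_kind")
  if (!is.numeric(df$signal) || anyNA(df$signal) || any(df$signal < 0))
    abort("signal must be non-negative and complete (negative or missing signal found)")
  class(df) <- c("screen_dataset", "data.frame")
  df
}

#' Read a long-format drug-screen CSV
#'
#' @param path path to a CSV with the columns documented in
#'   [screen_dataset()].
#' @return a `screen_dataset`.
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("drug_id", "control_kind"))
    if (col %in% names(df)) df[[col]][df[[col]] %in% c("", "NA")] <- NA_character_
  screen_dataset(df)
}

#' Write a screen dataset as CSV
#'
#' @param screen a `screen_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(screen, path) {
  stopifnot(inherits(screen, "screen_dataset"))
  utils::write.csv(as.data.frame(screen), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.screen_dataset <- function(x, ...) {
  nd <- length(unique(stats::na.omit(x$drug_id)))
  cat(sprintf("screen_dataset: %d wells, %d plates, %d drugs, arms: %s\n",
              nrow(x), length(unique(x$plate_id)), nd,
              paste(sort(unique(x$arm)), collapse = ", ")))
  invisible(x)
}
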