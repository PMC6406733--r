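# drug wells of one knockdown arm ("ctrl" = siCtrl or untransfected wells)
arm_wells <- function(screen, arm) {
  arms <- if (arm == "ctrl") c("siCtrl", "none") else "siATG16L1"
  df <- screen[screen$arm %in% arms & !is.na(screen$drug_id), , drop = FALSE]
  if (!nrow(df)) abort("no drug wells in arm '%s'", arm)
  df
}

#' Per-drug viability fold change between TGF-beta and vehicle
#'
#' For each drug and plating density, the fold change is the mean viability
#' signal of the TGF-beta-treated wells divided by the mean signal of the
#' vehicle wells; the per-drug score pools the densities by averaging their
#' fold changes. A fold change above 1 means the drug kills less effectively
#' after TGF-beta treatment (induced resistance); below 1 means
#' sensitization. Control wells are excluded.
#'
#' @param screen a [screen_dataset()].
#' @param arm `"ctrl"` (siCtrl or untransfected wells) or `"kd"`
#'   (siATG16L1 knockdown wells).
#' @return a list of class `resistance_table`: `per_density` (data frame of
#'   drug, density, vehicle/tgfb means and well counts, fold_change) and
#'   `per_drug` (drug, pooled fold_change).
#' @export
fold_change_table <- function(screen, arm = c("ctrl", "kd")) {
  stopifnot(inherits(screen, "screen_dataset"))
  arm <- match.arg(arm)
  df <- arm_wells(screen, arm)
  by_drug <- split(df, df$drug_id)
  bad <- names(by_drug)[!vapply(by_drug, function(d)
    any(d$condition == "vehicle") && any(d$condition == "tgfb"), logical(1))]
  if (length(bad))
    abort("drug(s) missing a condition in arm '%s': %s", arm, paste(bad, collapse = ", "))
  per_density <- do.call(rbind, lapply(by_drug, function(d) {
    do.call(rbind, lapply(split(d, d$density), function(dd) {
      mv <- mean(dd$signal[dd$condition == "vehicle"])
      mt <- mean(dd$signal[dd$condition == "tgfb"])
      data.frame(drug = dd$drug_id[1L], density = dd$density[1L],
                 mean_vehicle = mv, mean_tgfb = mt,
                 n_vehicle = sum(dd$condition == "vehicle"),
                 n_tgfb = sum(dd$condition == "tgfb"),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(per_density) <- NULL
  if (any(per_density$mean_vehicle == 0, na.rm = TRUE))
    abort("zero mean vehicle signal for drug %s",
          per_density$drug[which(per_density$mean_vehicle == 0)[1L]])
  # a density with no wells in one condition cannot contribute a fold change
  per_density <- per_density[per_density$n_vehicle > 0 & per_density$n_tgfb > 0, ]
  per_density$fold_change <- per_density$mean_tgfb / per_density$mean_vehicle
  per_drug <- stats::aggregate(fold_change ~ drug, per_density, mean)
  per_drug <- per_drug[order(per_drug$drug), ]
  rownames(per_drug) <- NULL
  structure(list(per_density = per_density, per_drug = per_drug, arm = arm),
            class = "resistance_table")
}

#' @export
print.resistance_table <- function(x, ...) {
  cat(sprintf("resistance_table (arm %s): %d drugs, fold change %.2f-%.2f\n",
              x$arm, nrow(x$per_drug), min(x$per_drug$fold_change),
              max(x$per_drug$fold_change)))
  invisible(x)
}

#' Call drugs resistant, sensitive or neutral
#'
#' A drug is called resistant when its pooled fold change exceeds the
#' threshold (default 1), sensitive when below, neutral when exactly equal.
#'
#' @param table a `resistance_table`.
#' @param threshold fold-change cut-off (default 1).
#' @return a list of class `resistance_calls`: `calls` (data frame with
#'   `drug`, `fold_change`, `call`), `n_resistant`, `n_sensitive`,
#'   `n_neutral`, `n_drugs`, `fraction_resistant`.
#' @export
resistance_calls <- function(table, threshold = 1) {
  stopifnot(inherits(table, "resistance_table"))
  fc <- table$per_drug$fold_change
  call <- ifelse(fc > threshold, "resistant",
                 ifelse(fc < threshold, "sensitive", "neutral"))
  res <- data.frame(drug = table$per_drug$drug, fold_change = fc, call = call,
                    stringsAsFactors = FALSE)
  structure(list(calls = res,
                 n_resistant = sum(call == "resistant"),
                 n_sensitive = sum(call == "sensitive"),
                 n_neutral = sum(call == "neutral"),
                 n_drugs = length(fc),
                 fraction_resistant = mean(call == "resistant"),
                 threshold = threshold),
            class = "resistance_calls")
}

#' @export
print.resistance_calls <- function(x, ...) {
  cat(sprintf("resistance calls at threshold %g: %d/%d resistant (%.1f%%), %d sensitive, %d neutral\n",
              x$threshold, x$n_resistant, x$n_drugs, 100 * x$fraction_resistant,
              x$n_sensitive, x$n_neutral))
  invisible(x)
}

#' Re-sensitization by knockdown
#'
#' Among the drugs called resistant in the control arm, counts those whose
#' resistance is lost in the knockdown arm. `"below_one"` (default) declares
#' a drug re-sensitized when its knockdown fold change drops to 1 or below —
#' the mirror image of the "above the 1" resistance definition.
#' `"relative_drop"` instead requires the knockdown fold change to fall to at
#' most `(1 - drop_fraction)` of the control fold change.
#'
#' @param ctrl,kd `resistance_table`s for the control and knockdown arms,
#'   over the same drug panel.
#' @param rule `"below_one"` or `"relative_drop"`.
#' @param drop_fraction relative drop required under `"relative_drop"`
#'   (default 0.2).
#' @param threshold resistance threshold applied to the control arm
#'   (default 1).
#' @return a list of class `resensitization`: `calls` (per resistant drug:
#'   control and knockdown fold changes, `resensitized`), `n_resistant`,
#'   `n_resensitized`, `fraction`.
#' @export
resensitization <- function(ctrl, kd, rule = c("below_one", "relative_drop"),
                            drop_fraction = 0.2, threshold = 1) {
  rule <- match.arg(rule)
  stopifnot(inherits(ctrl, "resistance_table"), inherits(kd, "resistance_table"))
  if (!setequal(ctrl$per_drug$drug, kd$per_drug$drug))
    abort("drug panels differ between arms: %s",
          paste(c(setdiff(ctrl$per_drug$drug, kd$per_drug$drug),
                  setdiff(kd$per_drug$drug, ctrl$per_drug$drug)), collapse = ", "))
  fc_c <- stats::setNames(ctrl$per_drug$fold_change, ctrl$per_drug$drug)
  fc_k <- stats::setNames(kd$per_drug$fold_change, kd$per_drug$drug)[names(fc_c)]
  resistant <- names(fc_c)[fc_c > threshold]
  resens <- switch(rule,
    below_one = fc_k[resistant] <= 1,
    relative_drop = fc_k[resistant] <= fc_c[resistant] * (1 - drop_fraction))
  calls <- data.frame(drug = resistant, fc_ctrl = fc_c[resistant],
                      fc_kd = fc_k[resistant], resensitized = unname(resens),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(calls = calls, n_resistant = length(resistant),
                 n_resensitized = sum(resens),
                 fraction = if (length(resistant)) mean(resens) else NA_real_,
                 rule = rule),
            class = "resensitization")
}

#' @export
print.resensitization <- function(x, ...) {
  cat(sprintf("re-sensitization (%s): %d/%d resistant drugs re-sensitized (%.0f%%)\n",
              x$rule, x$n_resensitized, x$n_resistant, 100 * x$fraction))
  invisible(x)
}

#' Plate-position quality control
#'
#' Ordinary least squares of the control-well signal on the row-major well
#' index, pooled across plates sharing a layout. A high R-squared indicates a
#' positional (edge/gradient) artifact; a clean screen shows essentially no
#' relationship.
#'
#' @param screen a [screen_dataset()].
#' @param wells which control kinds to use (default empty and DMSO wells).
#' @return a list of class `qc_report`: `r_squared`, `slope`, `n_wells`,
#'   `n_plates`.
#' @export
plate_position_qc <- function(screen, wells = c("empty", "DMSO")) {
  stopifnot(inherits(screen, "screen_dataset"))
  ctl <- screen[!is.na(screen$control_kind) & screen$control_kind %in% wells, ]
  if (nrow(ctl) < 3L) abort("need >= 3 control wells for the positional regression (got %d)", nrow(ctl))
  if (length(unique(ctl$plate_id)) < 2L)
    abort("need >= 2 plates sharing a layout to assess plate effects")
  ncol_plate <- max(screen$well_col)
  ctl$index <- (ctl$well_row - 1L) * ncol_plate + ctl$well_col
  fit <- stats::lm(signal ~ index, data = ctl)
  r2 <- if (stats::var(ctl$signal) == 0) 0 else summary(fit)$r.squared
  structure(list(r_squared = r2, slope = unname(stats::coef(fit)[2L]),
                 n_wells = nrow(ctl), n_plates = length(unique(ctl$plate_id))),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("plate-position QC: R^2 = %.4f over %d control wells on %d plates\n",
              x$r_squared, x$n_wells, x$n_plates))
  invisible(x)
}

#' Correlation of per-drug signals between plating densities
#'
#' For each treatment condition, the Pearson correlation between the
#' per-drug mean signals at low versus high plating density — a
#' reproducibility check across the density replicates of the screen.
#'
#' @param screen a [screen_dataset()].
#' @param arm `"ctrl"` or `"kd"`.
#' @return named numeric vector with elements `vehicle` and `tgfb`.
#' @export
density_replicate_correlation <- function(screen, arm = c("ctrl", "kd")) {
  arm <- match.arg(arm)
  df <- arm_wells(screen, arm)
  vapply(c(vehicle = "vehicle", tgfb = "tgfb"), function(cond) {
    d <- df[df$condition == cond, ]
    lo <- tapply(d$signal[d$density == "low"], d$drug_id[d$density == "low"], mean)
    hi <- tapply(d$signal[d$density == "high"], d$drug_id[d$density == "high"], mean)
    if (!setequal(names(lo), names(hi)))
      abort("drug(s) missing a density in condition %s: %s", cond,
            paste(c(setdiff(names(lo), names(hi)), setdiff(names(hi), names(lo))), collapse = ", "))
    stats::cor(lo, hi[names(lo)])
  }, numeric(1))
}
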