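#' Simulate an expression time course with Brownian drift and a late signal
#'
#' Generates the kind of data the phylogenetic workflow assumes. Each gene's
#' latent log2 expression starts from a baseline and follows a Gaussian
#' random walk over the ordered time points (step standard deviation
#' `drift_sd`), which makes the expected squared distance between samples
#' grow with their time separation — the additive regime in which
#' neighbor joining provably recovers the temporal chain. A fraction of
#' "signal" genes additionally shift by `+/- signal_shift` (sign fixed per
#' gene) at every rank at or beyond `signal_onset`, emulating the late-onset
#' transcriptional switch of an epithelial-to-mesenchymal transition time
#' course. Each replicate observes its time point's latent value plus i.i.d.
#' Gaussian measurement noise. The first time point is flagged as the
#' outgroup.
#'
#' Defaults emulate a 72-hour TGF-beta treatment microarray series: 2000
#' genes, 9 time ranks with 3 replicates each, unit drift per step, 5%
#' measurement noise, and a 10% signal-gene subset switching at rank 4.
#'
#' @param n_genes number of genes.
#' @param time_points ordered integer time ranks (default `0:8`).
#' @param replicates replicates per time point (default 3).
#' @param drift_sd random-walk step standard deviation (log2 units).
#' @param noise_sd replicate measurement noise standard deviation.
#' @param signal_fraction fraction of genes carrying the late-onset shift.
#' @param signal_onset time rank at which signal genes shift.
#' @param signal_shift magnitude of the shift (log2 units).
#' @param base_mean,base_sd distribution of per-gene baseline expression.
#' @param seed RNG seed.
#' @return a list with `expr` (an [expr_matrix()] with metadata, outgroup at
#'   the first rank) and `truth` (list: `signal_genes`, `signal_sign`,
#'   `time_order`, the per-sample time rank).
#' @export
simulate_time_course <- function(n_genes = 2000L, time_points = 0:8,
                                 replicates = 3L, drift_sd = 1,
                                 noise_sd = 0.05, signal_fraction = 0.1,
                                 signal_onset = 4L, signal_shift = 2,
                                 base_mean = 8, base_sd = 1.5, seed = NULL) {
  if (any(c(drift_sd, noise_sd, base_sd) < 0)) abort("standard deviations must be >= 0")
  if (signal_fraction < 0 || signal_fraction > 1) abort("signal_fraction must be in [0, 1]")
  time_points <- sort(unique(as.integer(time_points)))
  if (length(time_points) < 2L) abort("need >= 2 time points")
  if (replicates < 1L) abort("need >= 1 replicate per time point")
  if (signal_fraction > 0 &&
      (signal_onset <= min(time_points) || signal_onset > max(time_points)))
    abort("signal_onset must lie within the time range (after the first point)")
  with_seed(seed, {
    Tn <- length(time_points)
    genes <- sprintf("g%04d", seq_len(n_genes))
    base <- stats::rnorm(n_genes, base_mean, base_sd)
    steps <- matrix(stats::rnorm(n_genes * (Tn - 1L), 0, drift_sd), n_genes)
    latent <- cbind(base, base + t(apply(steps, 1L, cumsum)))
    n_sig <- round(signal_fraction * n_genes)
    sig_idx <- if (n_sig > 0) sort(sample.int(n_genes, n_sig)) else integer(0)
    sig_sign <- if (n_sig > 0) sample(c(-1, 1), n_sig, replace = TRUE) else numeric(0)
    late <- time_points >= signal_onset
    if (n_sig > 0)
      latent[sig_idx, late] <- latent[sig_idx, late] + sig_sign * signal_shift
    sample_ids <- as.vector(t(outer(time_points, seq_len(replicates),
                                    function(t, r) sprintf("t%d_r%d", t, r))))
    vals <- matrix(0, n_genes, Tn * replicates,
                   dimnames = list(genes, sample_ids))
    col <- 0L
    rank_of <- integer(Tn * replicates)
    for (ti in seq_len(Tn)) for (r in seq_len(replicates)) {
      col <- col + 1L
      vals[, col] <- latent[, ti] + stats::rnorm(n_genes, 0, noise_sd)
      rank_of[col] <- time_points[ti]
    }
    meta <- data.frame(sample_id = sample_ids, time_rank = rank_of,
                       replicate = sub("^.*_r", "r", sample_ids),
                       is_outgroup = rank_of == time_points[1L],
                       stringsAsFactors = FALSE)
    list(expr = expr_matrix(vals, meta, log2_scale = TRUE),
         truth = list(signal_genes = genes[sig_idx],
                      signal_sign = stats::setNames(sig_sign, genes[sig_idx]),
                      time_order = stats::setNames(rank_of, sample_ids)))
  })
}

# deterministic scattered layout for control wells on a 16 x 24 plate:
# alternating empty/DMSO wells spread over rows and columns so neither kind
# piles up at one end of the row-major index
control_layout <- function(n_ctrl = 24L, n_rows = 16L, n_cols = 24L) {
  r <- ((seq_len(n_ctrl) - 1L) %% n_rows) + 1L
  c_ <- (((seq_len(n_ctrl) - 1L) * 7L) %% n_cols) + 1L
  data.frame(well_row = r, well_col = c_,
             control_kind = rep(c("empty", "DMSO"), length.out = n_ctrl),
             stringsAsFactors = FALSE)
}

#' Simulate a 384-well single-dose viability screen
#'
#' Emulates a two-density drug screen with vehicle and TGF-beta arms run
#' with and without an autophagy-regulator knockdown. Well signal =
#' baseline x density factor x drug survival x condition multiplier x
#' lognormal noise. Resistant drugs receive a TGF-beta viability multiplier
#' above 1; in the knockdown arm, the re-sensitized subset loses that
#' multiplier. An optional additive positional gradient (signal per
#' row-major well index) plants a plate effect for QC testing. Every plate
#' shares one layout: scattered empty/DMSO control wells plus one well per
#' drug; one plate per (arm, condition, density) combination.
#'
#' Defaults reproduce the scale of a 119-compound approved-oncology-set
#' screen in which TGF-beta induces resistance to 71 drugs (60%) and
#' knockdown re-sensitizes 29 of those (41%).
#'
#' @param n_drugs number of drugs (default 119).
#' @param n_resistant number of planted TGF-beta-resistant drugs (default 71).
#' @param n_resensitized number of resistant drugs losing resistance under
#'   knockdown (default 29).
#' @param arms knockdown arms to simulate (default both `"siCtrl"` and
#'   `"siATG16L1"`).
#' @param baseline mean viability signal of a DMSO well at high density.
#' @param resistance_multiplier TGF-beta viability multiplier of resistant
#'   drugs (default 1.5).
#' @param tgfb_effect overall TGF-beta viability multiplier from growth
#'   slowing, applied to every drug well (default 0.9).
#' @param noise_cv lognormal noise coefficient of variation (default 0.03).
#' @param gradient_slope additive signal per well index (default 0, no plate
#'   effect).
#' @param seed RNG seed.
#' @return a list with `screen` (a [screen_dataset()]) and `truth` (list:
#'   `resistant`, `resensitized`, `survival`).
#' @export
simulate_screen <- function(n_drugs = 119L, n_resistant = 71L,
                            n_resensitized = 29L,
                            arms = c("siCtrl", "siATG16L1"),
                            baseline = 1e5, resistance_multiplier = 1.5,
                            tgfb_effect = 0.9, noise_cv = 0.03,
                            gradient_slope = 0, seed = NULL) {
  if (baseline <= 0) abort("baseline must be positive")
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  if (n_resistant > n_drugs || n_resensitized > n_resistant)
    abort("need n_resensitized <= n_resistant <= n_drugs")
  arms <- match.arg(arms, c("siCtrl", "siATG16L1", "none"), several.ok = TRUE)
  n_rows <- 16L; n_cols <- 24L
  ctl <- control_layout()
  if (n_drugs > n_rows * n_cols - nrow(ctl))
    abort("too many drugs for a 384-well layout")
  with_seed(seed, {
    drugs <- sprintf("drug%03d", seq_len(n_drugs))
    resistant <- drugs[seq_len(n_resistant)]
    resensitized <- resistant[seq_len(n_resensitized)]
    survival <- stats::setNames(stats::runif(n_drugs, 0.15, 0.95), drugs)
    # drug wells fill the remaining layout positions row-major
    all_pos <- expand.grid(well_col = seq_len(n_cols), well_row = seq_len(n_rows))
    all_pos <- all_pos[, c("well_row", "well_col")]
    used <- paste(ctl$well_row, ctl$well_col)
    free <- all_pos[!paste(all_pos$well_row, all_pos$well_col) %in% used, ]
    drug_pos <- free[seq_len(n_drugs), ]
    sdl <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    noise <- function(n) if (sdl == 0) rep(1, n) else
      stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
    recs <- list()
    for (arm in arms) for (cond in c("vehicle", "tgfb")) for (dens in c("low", "high")) {
      plate <- sprintf("%s_%s_%s", arm, cond, dens)
      dens_f <- if (dens == "low") 0.35 else 1
      cond_mult <- stats::setNames(rep(1, n_drugs), drugs)
      if (cond == "tgfb") {
        cond_mult[] <- tgfb_effect
        still_res <- if (arm == "siATG16L1") setdiff(resistant, resensitized) else resistant
        cond_mult[still_res] <- cond_mult[still_res] * resistance_multiplier
      }
      cond_f <- if (cond == "tgfb") tgfb_effect else 1
      dsig <- baseline * dens_f * survival * cond_mult * noise(n_drugs)
      csig <- ifelse(ctl$control_kind == "empty", baseline * 0.02,
                     baseline * dens_f * cond_f) * noise(nrow(ctl))
      idx_d <- (drug_pos$well_row - 1L) * n_cols + drug_pos$well_col
      idx_c <- (ctl$well_row - 1L) * n_cols + ctl$well_col
      recs[[plate]] <- data.frame(
        plate_id = plate,
        well_row = c(drug_pos$well_row, ctl$well_row),
        well_col = c(drug_pos$well_col, ctl$well_col),
        drug_id = c(drugs, rep(NA_character_, nrow(ctl))),
        control_kind = c(rep(NA_character_, n_drugs), ctl$control_kind),
        condition = cond, arm = arm, density = dens,
        signal = pmax(c(dsig, csig) + gradient_slope * c(idx_d, idx_c), 0),
        stringsAsFactors = FALSE)
    }
    list(screen = screen_dataset(do.call(rbind, recs)),
         truth = list(resistant = resistant, resensitized = resensitized,
                      survival = survival))
  })
}
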