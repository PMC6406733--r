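mini_screen <- function(signals) {
  # signals: named list drug -> c(vehicle wells, tgfb wells) per density "low"
  rows <- list()
  i <- 0L
  for (d in names(signals)) for (cond in c("vehicle", "tgfb")) {
    for (s in signals[[d]][[cond]]) {
      i <- i + 1L
      rows[[i]] <- data.frame(plate_id = paste0("p_", cond), well_row = 1L,
                              well_col = i, drug_id = d,
                              control_kind = NA_character_, condition = cond,
                              arm = "siCtrl", density = "low", signal = s,
                              stringsAsFactors = FALSE)
    }
  }
  screen_dataset(do.call(rbind, rows))
}

test_that("fold change is the ratio of condition means, per density then pooled", {
  scr <- mini_screen(list(d1 = list(vehicle = c(1, 1), tgfb = c(1.5, 1.5)),
                          d2 = list(vehicle = c(2, 2), tgfb = c(2, 2))))
  tab <- fold_change_table(scr, "ctrl")
  expect_equal(tab$per_drug$fold_change[tab$per_drug$drug == "d1"], 1.5)
  expect_equal(tab$per_drug$fold_change[tab$per_drug$drug == "d2"], 1)

  # global rescaling leaves the ratios unchanged
  scr2 <- scr; scr2$signal <- scr2$signal * 7.3
  tab2 <- fold_change_table(screen_dataset(as.data.frame(scr2)), "ctrl")
  expect_equal(tab2$per_drug$fold_change, tab$per_drug$fold_change)

  only_v <- mini_screen(list(d1 = list(vehicle = 1, tgfb = 2)))
  broken <- as.data.frame(only_v)
  broken <- broken[broken$condition == "vehicle", ]
  expect_error(fold_change_table(screen_dataset(broken), "ctrl"), "d1")

  zero <- mini_screen(list(d1 = list(vehicle = 0, tgfb = 2)))
  expect_error(fold_change_table(zero, "ctrl"), "zero mean vehicle")
})

test_that("resistance calls partition the panel at the threshold", {
  scr <- mini_screen(list(d1 = list(vehicle = 1, tgfb = 1.5),
                          d2 = list(vehicle = 1, tgfb = 0.7),
                          d3 = list(vehicle = 1, tgfb = 1)))
  calls <- resistance_calls(fold_change_table(scr, "ctrl"))
  expect_equal(calls$n_resistant, 1L)
  expect_equal(calls$n_sensitive, 1L)
  expect_equal(calls$n_neutral, 1L)
  expect_equal(calls$fraction_resistant, 1 / 3)
  expect_equal(calls$n_resistant + calls$n_sensitive + calls$n_neutral,
               calls$n_drugs)
})

test_that("re-sensitization rules follow their definitions", {
  fc <- function(v) structure(
    list(per_drug = data.frame(drug = names(v), fold_change = unname(v)),
         per_density = NULL, arm = "x"), class = "resistance_table")
  ctrl <- fc(c(d1 = 1.5, d2 = 0.8, d3 = 1.6))
  kd <- fc(c(d1 = 0.9, d2 = 0.7, d3 = 1.4))

  rs <- resensitization(ctrl, kd, "below_one")
  expect_equal(rs$n_resistant, 2L)          # d2 never resistant, excluded
  expect_equal(rs$n_resensitized, 1L)       # d1 drops below 1; d3 stays above
  expect_false("d2" %in% rs$calls$drug)

  rr <- resensitization(ctrl, kd, "relative_drop", drop_fraction = 0.2)
  # d3: needs <= 1.6 * 0.8 = 1.28; 1.4 fails. d1: needs <= 1.2; 0.9 passes.
  expect_equal(rr$calls$resensitized[rr$calls$drug == "d3"], FALSE)
  expect_equal(rr$calls$resensitized[rr$calls$drug == "d1"], TRUE)

  kd_bad <- fc(c(d1 = 0.9, dX = 1))
  expect_error(resensitization(ctrl, kd_bad), "d2|dX")
})

test_that("plate-position regression flags only planted gradients", {
  flat <- simulate_screen(n_drugs = 40, n_resistant = 10, n_resensitized = 5,
                          seed = 81)
  qc0 <- plate_position_qc(flat$screen)
  expect_lt(qc0$r_squared, 0.1)
  expect_gte(qc0$r_squared, 0)

  sloped <- simulate_screen(n_drugs = 40, n_resistant = 10, n_resensitized = 5,
                            gradient_slope = 200, seed = 81)
  qc1 <- plate_position_qc(sloped$screen)
  expect_gt(qc1$r_squared, qc0$r_squared)

  # constant control signal explains nothing
  const <- as.data.frame(flat$screen)
  const$signal[!is.na(const$control_kind)] <- 500
  expect_equal(plate_position_qc(screen_dataset(const))$r_squared, 0)

  one <- as.data.frame(flat$screen)
  one <- one[is.na(one$control_kind) | seq_len(nrow(one)) <= 2, ]
  expect_error(plate_position_qc(screen_dataset(one)), "control wells")
})

test_that("density-replicate correlations respect construction", {
  sim <- simulate_screen(n_drugs = 30, n_resistant = 8, n_resensitized = 4,
                         noise_cv = 0.02, seed = 82)
  r <- density_replicate_correlation(sim$screen, "ctrl")
  expect_named(r, c("vehicle", "tgfb"))
  expect_true(all(r > 0.8))

  # hand-built perfect and inverted tables
  rows <- expand.grid(drug_id = c("d1", "d2", "d3"), density = c("low", "high"),
                      condition = c("vehicle", "tgfb"), stringsAsFactors = FALSE)
  base <- c(d1 = 10, d2 = 20, d3 = 30)
  rows$signal <- ifelse(rows$density == "low", base[rows$drug_id],
                        base[rows$drug_id] * 2)
  rows$plate_id <- paste(rows$condition, rows$density)
  rows$well_row <- 1L
  rows$well_col <- as.integer(factor(rows$drug_id))
  rows$control_kind <- NA_character_
  rows$arm <- "siCtrl"
  perfect <- screen_dataset(rows)
  expect_equal(unname(density_replicate_correlation(perfect, "ctrl")), c(1, 1))

  rows$signal <- ifelse(rows$density == "low", base[rows$drug_id],
                        max(base) + min(base) - base[rows$drug_id])
  inverted <- screen_dataset(rows)
  expect_equal(unname(density_replicate_correlation(inverted, "ctrl")), c(-1, -1))
})

test_that("planted resistant drugs are recovered exactly at low noise", {
  sim <- simulate_screen(n_drugs = 119, n_resistant = 30, n_resensitized = 10,
                         resistance_multiplier = 1.5, noise_cv = 0.03, seed = 83)
  calls <- resistance_calls(fold_change_table(sim$screen, "ctrl"))
  called <- calls$calls$drug[calls$calls$call == "resistant"]
  expect_setequal(called, sim$truth$resistant)
})
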