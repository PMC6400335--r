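# A scarce ward with enough pressure that resource levers visibly move the
# death count within a short horizon.
scarce_sweep_config <- function(horizon_days = 10, n_trials = 3, ...) {
  tiny_config(admission_prob = 0.6, incidence_pct = 40,
              severity_mean = 0.2, smo_mortality = 0.6,
              deterioration_rate = 20, nurses = 1L, doctors = 1L,
              acute_nurse = 1L, acute_dose = 1, oxytocin = 30,
              horizon_days = horizon_days, n_trials = n_trials,
              base_seed = 21L, ...)
}

test_that("a zero restock amount is identical to disabling restocking", {
  cfg_amount0 <- scarce_sweep_config()
  cfg_amount0$inventory$restock_amounts[] <- 0
  cfg_flag <- scarce_sweep_config(restock_enabled = FALSE)
  a <- run_trial(cfg_amount0, seed = 4)
  b <- run_trial(cfg_flag, seed = 4)
  expect_identical(a$summary$deaths, b$summary$deaths)
  expect_identical(a$trajectories[c("census", "deaths_cum",
                                    "stock_oxytocin")],
                   b$trajectories[c("census", "deaths_cum",
                                    "stock_oxytocin")])
})

test_that("medication sweeps cover the grid and show stockout harm", {
  cfg <- scarce_sweep_config(horizon_days = 8, n_trials = 2)
  sw <- sweep_medication(cfg, drug = "oxytocin", stocks = c(0, 30),
                         restock = c(TRUE, FALSE))
  expect_s3_class(sw, "ward_sweep")
  expect_identical(nrow(sw), 4L * 2L) # cells x trials
  s <- glance(sw)
  expect_identical(nrow(s), 4L)
  worst <- s$deaths_mean[s$stock == 0 & !s$restock]
  expect_true(all(worst >= s$deaths_mean))

  # the swept drug's counterpart is pinned: hydralazine 11 packs, no restock
  expect_true(all(c("drug", "stock", "restock", "trial", "deaths") %in%
                    names(sw)))

  # the default oxytocin grid includes the common 150- and 200-pack shipments
  sw_def <- sweep_medication(tiny_config(horizon_days = 1, n_trials = 1),
                             drug = "oxytocin")
  expect_true(all(c(150, 200) %in% glance(sw_def)$stock))
})

test_that("staffing grid: no staff means no treatment; more staff never hurts", {
  cfg <- scarce_sweep_config(horizon_days = 8, n_trials = 3)
  sw <- sweep_staffing(cfg, nurses = c(0, 2, 6), doctors = c(0, 1))
  s <- glance(sw)
  expect_identical(nrow(s), 6L)
  # with (0, 0) every complicated patient goes untreated; deaths maximal
  d00 <- s$deaths_mean[s$nurses == 0 & s$doctors == 0]
  expect_true(all(d00 >= s$deaths_mean))
  # adding nurses at fixed doctors never increases mean deaths (common seeds)
  for (d in unique(s$doctors)) {
    col <- s[s$doctors == d, ]
    col <- col[order(col$nurses), ]
    expect_true(all(diff(col$deaths_mean) <= 1e-9))
  }
})

test_that("saturated staffing matches an effectively unlimited ward", {
  cfg <- scarce_sweep_config(horizon_days = 6, n_trials = 2)
  sw <- sweep_staffing(cfg, nurses = c(8, 50), doctors = c(8, 50))
  s <- glance(sw)
  expect_equal(s$deaths_mean[s$nurses == 8 & s$doctors == 8],
               s$deaths_mean[s$nurses == 50 & s$doctors == 50])
})

test_that("shift-pattern sweep reproduces the baseline bit-for-bit", {
  cfg <- scarce_sweep_config(horizon_days = 6, n_trials = 3)
  sw <- sweep_shift_patterns(cfg)
  expect_setequal(unique(sw$pattern),
                  c("current", "one_fewer_each", "five_nurses_all_shifts",
                    "three_doctors_all_shifts"))
  base <- run_trials(cfg)
  cur <- sw[sw$pattern == "current", ]
  expect_identical(cur$deaths, base$summary$deaths)
  expect_identical(cur$seed, base$summary$seed)

  cmp <- attr(sw, "comparisons")
  expect_identical(nrow(cmp), 6L) # all pairs of 4 patterns
  expect_true(all(c("pattern_a", "pattern_b", "statistic", "p_value") %in%
                    names(cmp)))
  expect_true(all(is.na(cmp$p_value) | (cmp$p_value >= 0 & cmp$p_value <= 1)))
})

test_that("admission multipliers scale influx and clip with a warning", {
  cfg <- scarce_sweep_config(horizon_days = 6, n_trials = 2)
  sw <- sweep_admission(cfg, multipliers = c(0, 0.5, 1))
  s <- glance(sw)
  expect_identical(s$multiplier, c(0, 0.5, 1))
  # zero influx: nothing happens
  z <- sw[sw$multiplier == 0, ]
  expect_true(all(z$admissions == 0))
  expect_true(all(z$deaths == 0))
  # halved influx admits about half as many patients
  adm <- tapply(sw$admissions, sw$multiplier, mean)
  expect_equal(unname(adm[["0.5"]] / adm[["1"]]), 0.5, tolerance = 0.1)
  # mortality among complicated patients non-decreasing in load (common seeds)
  m <- s$mortality_rate_complicated_pct_mean
  m[is.na(m)] <- 0
  expect_true(all(diff(m) >= -1e-9))

  expect_warning(sweep_admission(cfg, multipliers = 2), "clipped")
})

test_that("summary statistics implement the outcome-measure definitions", {
  # 10 complicated patients, exactly one death: mortality rate 10%;
  # 1 death among 10 'bleed' cases: CFR 10%; engineered via the lifetime
  # survival variates.
  cfg <- tiny_config(admission_prob = 0, nurses = 0L, acute_nurse = 1L,
                     deterioration_rate = 1e12)
  n <- 10
  U <- rep(0.5, n)
  U[4] <- 0.999 # dies on the first evaluation (hazard ~5.6% < 1 - U fails)
  st <- toy_cohort(cfg, severities = rep(0.5, n), complication = "bleed",
                   U = U)
  ward_cycle(st)
  expect_identical(st$deaths, 1L)
  tr <- structure(
    list(summary = wardsim:::trial_summary_row(st, 1L, cfg),
         per_complication = wardsim:::trial_per_complication(st)),
    class = "ward_trial")
  sm <- summarize_trials(list(tr))
  expect_equal(sm$overall$mortality_rate_complicated_pct_mean, 10)
  pc <- sm$per_complication
  expect_equal(pc$cfr_pct_pooled[pc$complication == "bleed"], 10)
  expect_equal(pc$incidence_pct_mean[pc$complication == "bleed"], 100)

  # empty cohort: rates are missing, not zero
  cfg0 <- tiny_config(admission_prob = 0, horizon_days = 1)
  res0 <- run_trials(cfg0, n_trials = 2)
  sm0 <- summarize_trials(res0)
  expect_true(is.na(sm0$overall$mortality_rate_complicated_pct_mean))
  expect_true(is.na(sm0$per_complication$cfr_pct_mean))

  # census of a no-discharge, no-death run equals cumulative admissions
  cfg_c <- tiny_config(admission_prob = 1, incidence_pct = 0,
                       delivery_duration = 2000L, delivery_nurse = 0L,
                       horizon_days = 1)
  tr_c <- run_trial(cfg_c, seed = 2)
  expect_identical(tr_c$trajectories$census,
                   tr_c$trajectories$admissions_cum)
})

test_that("sweep results carry tidy() and autoplot() methods", {
  cfg <- scarce_sweep_config(horizon_days = 4, n_trials = 2)
  sw <- sweep_admission(cfg, multipliers = c(0.5, 1))
  td <- tidy(sw)
  expect_false(inherits(td, "ward_sweep"))
  expect_identical(nrow(td), nrow(sw))
  expect_s3_class(autoplot(sw), "ggplot")
  sw2 <- sweep_staffing(cfg, nurses = c(0, 1), doctors = 0)
  expect_s3_class(autoplot(sw2), "ggplot")
})
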