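test_that("admission counts follow the shift Bernoulli process", {
  # degenerate probabilities
  cfg0 <- tiny_config(admission_prob = 0, horizon_days = 2)
  tr0 <- run_trial(cfg0, seed = 1)
  expect_identical(tr0$summary$admissions, 0L)
  expect_identical(tr0$summary$deaths, 0L)

  cfg1 <- tiny_config(admission_prob = 1, horizon_days = 1,
                      delivery_duration = 1L, incidence_pct = 0,
                      delivery_nurse = 0L)
  tr1 <- run_trial(cfg1, seed = 1)
  expect_identical(tr1$summary$admissions, 96L) # one per 15-minute cycle

  # binomial expectation at p = 0.4 over 1e4 cycles
  n_cycles <- 1e4
  cfg <- tiny_config(admission_prob = 0.4, incidence_pct = 0,
                     delivery_duration = 1L, delivery_nurse = 0L,
                     horizon_days = ceiling(n_cycles / 96))
  st <- new_ward_state(cfg, record = FALSE)
  set.seed(42)
  for (t in seq_len(n_cycles)) ward_cycle(st)
  expect_lt(abs(st$admissions - n_cycles * 0.4),
            3 * sqrt(n_cycles * 0.4 * 0.6))
})

test_that("identical seeds give bit-identical trials", {
  cfg <- tiny_config(horizon_days = 3)
  a <- run_trial(cfg, seed = 5)
  b <- run_trial(cfg, seed = 5)
  expect_identical(a$summary, b$summary)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$events, b$events)
  c <- run_trial(cfg, seed = 6)
  expect_false(identical(a$trajectories, c$trajectories))
})

test_that("replicate streams stay aligned across resource scenarios", {
  # common random numbers: changing stocks must not change the admission
  # process, only treatment outcomes
  rich <- tiny_config(horizon_days = 5, oxytocin = 100)
  poor <- tiny_config(horizon_days = 5, oxytocin = 0)
  a <- run_trial(rich, seed = 3)
  b <- run_trial(poor, seed = 3)
  expect_identical(a$trajectories$admissions_cum, b$trajectories$admissions_cum)
  expect_identical(a$summary$complicated, b$summary$complicated)
})

test_that("a two-plan chain discharges after its treated duration", {
  # acute(4) -> obs(8): discharge processed at the start of cycle 13
  cfg <- tiny_config(admission_prob = 0, acute_duration = 4L,
                     obs_duration = 8L, nurses = 5L, oxytocin = 100)
  st <- toy_cohort(cfg, severities = 0.1, complication = "bleed")
  for (t in 1:12) ward_cycle(st)
  expect_identical(st$discharges, 0L)
  expect_identical(length(st$act), 1L)
  ward_cycle(st)
  expect_identical(st$discharges, 1L)
  expect_identical(st$deaths, 0L)
  expect_identical(length(st$act), 0L)
  # tallies reconcile
  expect_identical(st$admissions, st$deaths + st$discharges + length(st$act))
})

test_that("plans advance to successors and progress only on treated cycles", {
  cfg <- tiny_config(admission_prob = 0, acute_duration = 2L,
                     obs_duration = 8L, nurses = 1L, oxytocin = 100)
  st <- toy_cohort(cfg, severities = 0.2, complication = "bleed")
  plan_ids <- st$cc$plan_ids
  # treated both acute cycles -> successor "obs" active on cycle 3
  for (t in 1:3) ward_cycle(st)
  expect_identical(plan_ids[st$cd_plan[1]], "obs")

  # starve the ward: progress must freeze while untreated
  cfg2 <- tiny_config(admission_prob = 0, nurses = 0L)
  st2 <- toy_cohort(cfg2, severities = 0.2, complication = "bleed")
  for (t in 1:5) ward_cycle(st2)
  expect_identical(st2$cd_prog[1], 0L)
  expect_identical(st2$untreated_c[1], 5L)
})

test_that("triage treats the sickest first, all-or-nothing", {
  # one doctor, two patients needing one doctor each: p_c = 0.9 wins
  cfg <- tiny_config(admission_prob = 0, nurses = 0L, doctors = 1L,
                     acute_nurse = 0L, acute_doctor = 1L, acute_dose = 0)
  st <- toy_cohort(cfg, severities = c(0.1, 0.9), complication = "bleed")
  assign_plans(st)
  allocate_resources(st)
  expect_identical(st$treated, 2L)
  expect_identical(st$untreated, 1L)

  # nurse available but the drug is out: all-or-nothing refusal
  cfg <- tiny_config(admission_prob = 0, nurses = 1L, acute_nurse = 1L,
                     acute_dose = 1, oxytocin = 0)
  st <- toy_cohort(cfg, severities = 0.5, complication = "bleed")
  assign_plans(st)
  allocate_resources(st)
  expect_identical(st$treated, integer(0))
  expect_identical(st$untreated, 1L)
  expect_identical(unname(st$stocks["oxytocin"]), 0)

  # ample resources: the whole cohort is treated
  cfg <- tiny_config(admission_prob = 0, nurses = 10L, doctors = 10L,
                     oxytocin = 100)
  st <- toy_cohort(cfg, severities = c(0.3, 0.2, NA, 0.8))
  assign_plans(st)
  allocate_resources(st)
  expect_setequal(st$treated, 1:4)
})

test_that("greedy allocation matches the brute-force oracle on small cohorts", {
  set.seed(202)
  for (rep in 1:30) {
    n <- sample(1:6, 1)
    sev <- round(stats::runif(n), 3)
    sev[stats::runif(n) < 0.3] <- NA
    nurses <- sample(0:3, 1)
    doctors <- sample(0:2, 1)
    stock_ox <- sample(0:3, 1)
    cfg <- tiny_config(admission_prob = 0, nurses = nurses,
                       doctors = doctors, oxytocin = stock_ox,
                       acute_nurse = 1L, acute_doctor = 1L, acute_dose = 1,
                       delivery_nurse = 1L)
    st <- toy_cohort(cfg, severities = sev, complication = "bleed")
    assign_plans(st)
    allocate_resources(st)
    oracle <- greedy_alloc_oracle(
      cfg, sev, "bleed", nurses, doctors,
      c(oxytocin = stock_ox, hydralazine = 10))
    expect_setequal(st$treated, oracle)
  }
})

test_that("dynamics follow the treatment and deterioration closed forms", {
  # treated: eta = 0.5 halves the probability each cycle
  cfg <- tiny_config(admission_prob = 0, efficacy = 0.5, nurses = 5L,
                     oxytocin = 10)
  st <- toy_cohort(cfg, severities = 0.4, complication = "bleed")
  assign_plans(st); allocate_resources(st); apply_dynamics(st)
  expect_equal(st$cd_p[1], 0.2)

  # untreated for two cycles: p = 0.5^(1/6) by the gamma closed form
  cfg <- tiny_config(admission_prob = 0, nurses = 0L, deterioration_rate = 1)
  st <- toy_cohort(cfg, severities = 0.5, complication = "bleed")
  for (t in 1:2) {
    assign_plans(st); allocate_resources(st); apply_dynamics(st)
  }
  expect_equal(st$cd_p[1], deterioration_closed_form(0.5, 1, 2))
  expect_equal(st$cd_p[1], 0.5^(1 / 6))

  # an uncomplicated patient's probability stays 0 untreated
  st <- toy_cohort(cfg, severities = NA)
  for (t in 1:4) {
    assign_plans(st); allocate_resources(st); apply_dynamics(st)
  }
  expect_identical(st$cd_p[1], 0)
})

test_that("survival evaluation reproduces the scaled mortality law", {
  # p_c = 0, certain survival over any horizon
  cfg <- tiny_config(admission_prob = 0, nurses = 1L)
  st <- toy_cohort(cfg, severities = rep(NA, 20))
  for (t in 1:50) ward_cycle(st)
  expect_identical(st$deaths, 0L)

  # p_c = 0.99 with one remaining cycle: death frequency ~0.99
  n <- 4000
  set.seed(7)
  cfg <- tiny_config(admission_prob = 0)
  st <- toy_cohort(cfg, severities = rep(0.99, n), complication = "bleed",
                   U = stats::runif(n))
  st$cd_plan[seq_len(n)] <- 0L # chain complete: remaining floored at 1
  evaluate_survival(st)
  expect_lt(abs(st$deaths / n - 0.99), 3 * sqrt(0.99 * 0.01 / n))

  # constant p_c = 0.2 over a 10-cycle stay: cumulative deaths ~0.2.
  # Untreated patients with an (effectively) infinite deterioration rate
  # keep p and remaining stay constant, so each cycle applies the same
  # scaled hazard.
  n <- 5000
  set.seed(8)
  cfg <- tiny_config(admission_prob = 0, nurses = 0L, acute_nurse = 1L,
                     acute_duration = 2L, obs_duration = 8L,
                     deterioration_rate = 1e12)
  st <- toy_cohort(cfg, severities = rep(0.2, n), complication = "bleed",
                   U = stats::runif(n))
  for (t in 1:10) ward_cycle(st)
  expect_lt(abs(st$deaths / n - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("deaths release held staff for the next cycle", {
  # the acute plan holds 2 nurses; kill the patient and the pool recovers
  cfg <- default_mmh_config(horizon_days = 1)
  st <- toy_cohort(cfg, severities = 0.95,
                   complication = "postpartum_haemorrhage", U = 0.999999)
  assign_plans(st); allocate_resources(st)
  expect_identical(st$held_n_total, 2L)
  apply_dynamics(st)
  evaluate_survival(st) # p_c ~0.95, n = 1... dies almost surely given U
  expect_identical(st$deaths, 1L)
  expect_identical(st$held_n_total, 0L)
  expect_identical(st$deaths_by_comp[["postpartum_haemorrhage"]], 1L)
})

test_that("staff and stock ledgers balance cycle by cycle", {
  cfg <- default_mmh_config(horizon_days = 2)
  set.seed(31)
  st <- new_ward_state(cfg, record = FALSE, horizon_cycles = 192L)
  init <- st$stocks
  for (t in seq_len(192L)) {
    ward_cycle(st)
    act_cond <- st$act_cond
    expect_identical(st$held_n_total, sum(st$cd_held_n[act_cond]))
    expect_identical(st$held_d_total, sum(st$cd_held_d[act_cond]))
    staff <- ward_staff(st)
    expect_true(all(staff$available >= 0))
    expect_identical(staff$available,
                     pmax(0L, staff$on_shift_total - staff$held))
    expect_equal(unname(st$stocks),
                 unname(init + st$restocked - st$dispensed),
                 tolerance = 1e-9)
    expect_true(all(st$stocks >= 0))
  }
  expect_identical(st$admissions,
                   st$deaths + st$discharges + length(st$act))
})

test_that("ledgers and tallies balance over full 90-day runs of random configs", {
  for (seed in c(11, 12)) {
    cfg <- random_config(seed, horizon_days = 90)
    tr <- run_trial(cfg, seed = seed)
    lg <- tr$ledger
    expect_equal(unname(lg$final_stocks),
                 unname(lg$initial_stocks + lg$restocked - lg$dispensed),
                 tolerance = 1e-9)
    expect_true(all(lg$final_stocks >= 0))
    s <- tr$summary
    expect_identical(s$admissions, s$deaths + s$discharges + s$in_ward_end)
    # tallies reconstruct from the event log
    expect_identical(nrow(tr$events$deaths), s$deaths)
    expect_identical(nrow(tr$events$discharges), s$discharges)
    expect_identical(tr$summary$admissions,
                     max(tr$trajectories$admissions_cum))
  }
})

test_that("restocking happens at exact monthly multiples", {
  cfg <- tiny_config(admission_prob = 0, horizon_days = 90,
                     restock_interval = 2880L)
  tr <- run_trial(cfg, seed = 1)
  expect_identical(tr$events$restocks$cycle, c(2880L, 5760L, 8640L))

  # restocking disabled: stocks monotone non-increasing
  cfg2 <- tiny_config(horizon_days = 30, restock_enabled = FALSE)
  tr2 <- run_trial(cfg2, seed = 2)
  expect_identical(nrow(tr2$events$restocks), 0L)
  expect_true(all(diff(tr2$trajectories$stock_oxytocin) <= 0))
})

test_that("shift boundaries switch staffing totals and admission rates", {
  cfg <- default_mmh_config(horizon_days = 1)
  st <- new_ward_state(cfg, record = FALSE)
  # cycle-of-day 0 (midnight) is night; 24 is 06:00 morning; 56 evening
  shift_at <- function(cod) {
    st$cycle <- cod + 1L
    s <- st$cc$shift_of_cod[cod + 1L]
    list(name = st$cc$shift_names[s],
         nurses = st$cc$shift_nurses[s],
         doctors = st$cc$shift_doctors[s],
         padm = st$cc$shift_padm[s])
  }
  expect_identical(shift_at(0L)$name, "night")
  expect_identical(shift_at(23L)$padm, 0.625)
  m <- shift_at(24L)
  expect_identical(m[c("nurses", "doctors", "padm")],
                   list(nurses = 5L, doctors = 3L, padm = 0.4))
  e <- shift_at(56L)
  expect_identical(e[c("nurses", "doctors", "padm")],
                   list(nurses = 3L, doctors = 2L, padm = 0.28))
  n <- shift_at(88L)
  expect_identical(n[c("nurses", "doctors", "padm")],
                   list(nurses = 3L, doctors = 1L, padm = 0.625))
})

test_that("multi-morbidity configs run and combine probabilities", {
  cfg <- tiny_config(multi_morbidity = TRUE, incidence_pct = 40,
                     horizon_days = 3)
  # add a second complication sharing the acute plan
  cfg$complications <- dplyr::bind_rows(
    cfg$complications,
    dplyr::mutate(cfg$complications, name = "fever", incidence_pct = 30,
                  severity_mean = 0.05,
                  severity_sd = derive_severity_sd(0.05, 0.4)))
  cfg$uncomplicated_pct <- 100 - sum(cfg$complications$incidence_pct)
  validate_config(cfg)
  tr <- run_trial(cfg, seed = 9)
  expect_gt(tr$summary$admissions, 0)
  # under independent assignment some patients carry both conditions
  st <- new_ward_state(cfg, record = FALSE)
  set.seed(9)
  for (t in seq_len(cfg$horizon_days * 96L)) ward_cycle(st)
  expect_gt(max(st$cond_n[seq_len(st$n_pat)]), 1L)
  # determinism is preserved
  tr2 <- run_trial(cfg, seed = 9)
  expect_identical(tr$summary, tr2$summary)
})
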