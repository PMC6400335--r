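#' Synthetic ward configurations
#'
#' The package ships no clinical data. [default_mmh_config()] builds a
#' complete, runnable baseline emulating a busy East-African referral
#' maternity ward (shift staffing and admission probabilities from ward
#' observation, five potentially life-threatening complications plus
#' uncomplicated delivery, chained treatment plans, oxytocin/hydralazine
#' inventory with monthly restocking). Severity means, SMO mortality and plan
#' parameters are illustrative stand-ins for unpublished clinical constants
#' and are flagged `illustrative = TRUE` in the config. [random_config()]
#' generates randomized but always-valid configurations for property-based
#' testing.
#'
#' @name fixtures
NULL

#' Baseline maternity-ward configuration
#'
#' Three 8-hour shifts (morning 06:00, evening 14:00, night 22:00) with
#' nurse/doctor totals 5/3, 3/2, 3/1 and per-15-minute admission
#' probabilities 0.4, 0.28, 0.625. Five complications — postpartum
#' haemorrhage, preeclampsia, eclampsia, uterine rupture, sepsis — cover
#' 13.05% of admissions (the remaining 86.95% are uncomplicated deliveries);
#' every delivery receives a prophylactic oxytocin dose, and hydralazine is
#' demanded by the preeclampsia and eclampsia plans. Baseline inventory: 200
#' packs of oxytocin (about 20,000 IU) and 11 packs of hydralazine (about
#' 2,200 mg/mL), restocked monthly (every 2,880 cycles) by the same amounts.
#'
#' Severity distributions use illustrative case-fatality-rate means with a
#' shared SMO mortality anchor of 0.17; standard deviations come from
#' [derive_severity_sd()] and plan efficacies from [calibrate_efficacy()]
#' applied to each complication's full plan chain, so a fully treated
#' condition decays to the 1e-10 mortality floor by discharge.
#'
#' @param horizon_days Simulated horizon (default 90 days).
#' @param n_trials Default replicate count (default 50).
#' @param base_seed Default base seed.
#' @return A validated `ward_config`.
#' @examples
#' cfg <- default_mmh_config()
#' cfg
#' @export
default_mmh_config <- function(horizon_days = 90, n_trials = 50,
                               base_seed = 1L) {
  shifts <- tibble::tibble(
    name = c("morning", "evening", "night"),
    start_cycle = c(24L, 56L, 88L), # 06:00, 14:00, 22:00
    nurses = c(5L, 3L, 3L),
    doctors = c(3L, 2L, 1L),
    admission_prob = c(0.4, 0.28, 0.625)
  )

  smo <- 0.17 # illustrative: deaths among severe maternal outcomes
  comps <- tibble::tibble(
    name = c("postpartum_haemorrhage", "preeclampsia", "eclampsia",
             "uterine_rupture", "sepsis"),
    incidence_pct = c(4.0, 4.5, 1.5, 1.0, 2.05),
    severity_mean = c(0.020, 0.005, 0.040, 0.100, 0.070),
    smo_mortality = smo,
    deterioration_rate = c(150, 400, 100, 60, 250),
    entry_plan = c("pph_acute", "pec_acute", "ecl_acute",
                   "rup_surgical", "sep_acute"),
    illustrative = TRUE
  )
  comps$severity_sd <- derive_severity_sd(comps$severity_mean,
                                          comps$smo_mortality)

  drug <- function(dose, every) list(dose = dose, every = as.integer(every))
  plan <- function(id, duration, successor = NA_character_,
                   nurse_count = 0L, nurse_every = 1L, nurse_hold = FALSE,
                   doctor_count = 0L, doctor_every = 1L, doctor_hold = FALSE,
                   drugs = list(), efficacy = 0) {
    tibble::tibble(
      id = id, duration = as.integer(duration), efficacy = efficacy,
      successor = successor,
      nurse_count = as.integer(nurse_count),
      nurse_every = as.integer(nurse_every), nurse_hold = nurse_hold,
      doctor_count = as.integer(doctor_count),
      doctor_every = as.integer(doctor_every), doctor_hold = doctor_hold,
      drugs = list(drugs)
    )
  }

  plans <- dplyr::bind_rows(
    # uncomplicated pathway: 1 h attended delivery with prophylactic
    # oxytocin, then 19 h postnatal observation (two nurse rounds, one
    # doctor review). Chain = 80 cycles = 20 h, giving a steady census
    # near the mid-30s under the baseline admission schedule.
    plan("normal_delivery", 4, successor = "postnatal_recovery",
         nurse_count = 1, nurse_every = 1, nurse_hold = TRUE,
         drugs = list(oxytocin = drug(0.1, 4))),
    plan("postnatal_recovery", 76,
         nurse_count = 1, nurse_every = 38,
         doctor_count = 1, doctor_every = 76),
    # postpartum haemorrhage: 2 h intensive care with repeated oxytocin,
    # then 34 h of monitored recovery. Chain = 144 cycles.
    plan("pph_acute", 8, successor = "pph_recovery",
         nurse_count = 2, nurse_every = 1, nurse_hold = TRUE,
         doctor_count = 1, doctor_every = 4,
         drugs = list(oxytocin = drug(0.2, 2))),
    plan("pph_recovery", 136,
         nurse_count = 1, nurse_every = 12,
         doctor_count = 1, doctor_every = 48),
    # preeclampsia: 12 h stabilisation on hydralazine, then 36 h of
    # monitored recovery with tapering doses. Chain = 192 cycles.
    plan("pec_acute", 48, successor = "pec_recovery",
         nurse_count = 1, nurse_every = 8,
         doctor_count = 1, doctor_every = 24,
         drugs = list(hydralazine = drug(0.03, 12))),
    plan("pec_recovery", 144,
         nurse_count = 1, nurse_every = 24,
         doctor_count = 1, doctor_every = 72,
         drugs = list(hydralazine = drug(0.015, 48))),
    # eclampsia: 6 h continuous nursing with hydralazine, then 42 h
    # recovery. Chain = 192 cycles.
    plan("ecl_acute", 24, successor = "ecl_recovery",
         nurse_count = 1, nurse_every = 1, nurse_hold = TRUE,
         doctor_count = 1, doctor_every = 8,
         drugs = list(hydralazine = drug(0.03, 8))),
    plan("ecl_recovery", 168,
         nurse_count = 1, nurse_every = 16,
         doctor_count = 1, doctor_every = 48,
         drugs = list(hydralazine = drug(0.015, 56))),
    # uterine rupture: 3 h surgery holding two doctors and two nurses,
    # then 45 h post-operative recovery. Chain = 192 cycles.
    plan("rup_surgical", 12, successor = "rup_recovery",
         nurse_count = 2, nurse_every = 1, nurse_hold = TRUE,
         doctor_count = 2, doctor_every = 1, doctor_hold = TRUE,
         drugs = list(oxytocin = drug(0.2, 12))),
    plan("rup_recovery", 180,
         nurse_count = 1, nurse_every = 16,
         doctor_count = 1, doctor_every = 48),
    # sepsis: 4 h acute phase, then 44 h of monitored recovery.
    # Chain = 192 cycles.
    plan("sep_acute", 16, successor = "sep_recovery",
         nurse_count = 1, nurse_every = 4,
         doctor_count = 1, doctor_every = 8),
    plan("sep_recovery", 176,
         nurse_count = 1, nurse_every = 24,
         doctor_count = 1, doctor_every = 48)
  )

  # efficacy of every plan in a complication's chain is solved so that the
  # mean severity decays to the 1e-10 floor over the full chain duration
  chain_total <- stats::setNames(plan_chain_lengths(plans), plans$id)
  for (i in seq_len(nrow(comps))) {
    eta <- calibrate_efficacy(comps$severity_mean[i],
                              chain_total[[comps$entry_plan[i]]])
    pid <- comps$entry_plan[i]
    while (!is.na(pid)) {
      plans$efficacy[plans$id == pid] <- eta
      pid <- plans$successor[plans$id == pid]
    }
  }

  inventory <- list(
    stocks = c(oxytocin = 200, hydralazine = 11),
    restock_interval_cycles = 2880L, # one 30-day month
    restock_amounts = c(oxytocin = 200, hydralazine = 11),
    restock_enabled = TRUE,
    units = c(oxytocin = "pack = 100 IU", hydralazine = "pack = 200 mg/mL")
  )

  ward_config(
    shifts = shifts, complications = comps, plans = plans,
    inventory = inventory,
    uncomplicated_pct = 100 - sum(comps$incidence_pct), # 86.95
    uncomplicated_entry_plan = "normal_delivery",
    horizon_days = horizon_days, n_trials = n_trials, base_seed = base_seed
  )
}

#' Randomized valid configurations for property-based tests
#'
#' Draws a configuration that always passes [validate_config()], spanning
#' degenerate corners (zero staff, zero stock, single complication, extreme
#' efficacies) useful for invariant testing. Pure function of `seed`.
#'
#' @param seed Integer seed.
#' @param n_complications Number of complications (default random 1-4).
#' @param richness One of `"scarce"`, `"baseline"`, `"abundant"`; scales
#'   staff totals and drug stocks.
#' @param horizon_days Horizon, default 30.
#' @return A validated `ward_config`.
#' @export
random_config <- function(seed, n_complications = NULL,
                          richness = c("baseline", "scarce", "abundant"),
                          horizon_days = 30) {
  richness <- match.arg(richness)
  set.seed(seed)
  if (is.null(n_complications)) n_complications <- sample(1:4, 1)
  rich <- switch(richness, scarce = 0.25, baseline = 1, abundant = 4)

  drugs_all <- c("oxytocin", "hydralazine")
  n_shift <- sample(1:4, 1)
  cpd <- CYCLES_PER_DAY
  starts <- sort(sample(0:(cpd - 1L), n_shift))
  shifts <- tibble::tibble(
    name = paste0("shift", seq_len(n_shift)),
    start_cycle = as.integer(starts),
    nurses = as.integer(pmax(0, round(rich * sample(0:6, n_shift, TRUE)))),
    doctors = as.integer(pmax(0, round(rich * sample(0:3, n_shift, TRUE)))),
    admission_prob = round(stats::runif(n_shift, 0, 0.7), 3)
  )

  mk_drugs <- function() {
    k <- sample(0:2, 1)
    if (k == 0) return(list())
    ds <- sample(drugs_all, k)
    stats::setNames(lapply(ds, function(d) {
      list(dose = round(stats::runif(1, 0.02, 0.3), 3),
           every = sample(c(1L, 2L, 4L, 8L, 12L), 1))
    }), ds)
  }
  mk_plan <- function(id, successor = NA_character_) {
    duration <- sample(c(1L, 2L, 4L, 8L, 24L, 48L), 1)
    tibble::tibble(
      id = id, duration = duration,
      efficacy = sample(c(0, 1, round(stats::runif(1), 3)), 1),
      successor = successor,
      nurse_count = sample(0:2, 1), nurse_every = sample(c(1L, 2L, 6L), 1),
      nurse_hold = sample(c(TRUE, FALSE), 1),
      doctor_count = sample(0:2, 1), doctor_every = sample(c(1L, 4L, 12L), 1),
      doctor_hold = sample(c(TRUE, FALSE), 1),
      drugs = list(mk_drugs())
    )
  }

  plans <- mk_plan("delivery", successor = "recovery")
  plans <- dplyr::bind_rows(plans, mk_plan("recovery"))
  comp_rows <- list()
  for (i in seq_len(n_complications)) {
    depth <- sample(1:3, 1)
    ids <- paste0("comp", i, "_p", seq_len(depth))
    for (d in seq_len(depth)) {
      succ <- if (d < depth) ids[d + 1] else NA_character_
      plans <- dplyr::bind_rows(plans, mk_plan(ids[d], succ))
    }
    mean_sev <- round(stats::runif(1, 0.01, 0.3), 4)
    smo <- round(mean_sev + stats::runif(1, 0.05, 0.5), 4)
    comp_rows[[i]] <- tibble::tibble(
      name = paste0("comp", i),
      incidence_pct = NA_real_,
      severity_mean = mean_sev,
      smo_mortality = min(smo, 0.95),
      severity_sd = NA_real_,
      deterioration_rate = round(10^stats::runif(1, 0.5, 3), 3),
      entry_plan = ids[1],
      illustrative = TRUE
    )
  }
  comps <- dplyr::bind_rows(comp_rows)
  w <- stats::runif(n_complications)
  complicated_total <- stats::runif(1, 5, 40)
  comps$incidence_pct <- round(complicated_total * w / sum(w), 6)
  comps$severity_sd <- derive_severity_sd(comps$severity_mean,
                                          comps$smo_mortality)

  stocks <- round(rich * stats::runif(2, 0, 60), 2)
  inventory <- list(
    stocks = stats::setNames(stocks, drugs_all),
    restock_interval_cycles = sample(c(480L, 1440L, 2880L), 1),
    restock_amounts = stats::setNames(round(rich * stats::runif(2, 0, 40), 2),
                                      drugs_all),
    restock_enabled = sample(c(TRUE, FALSE), 1),
    units = stats::setNames(c("pack", "pack"), drugs_all)
  )

  ward_config(
    shifts = shifts, complications = comps, plans = plans,
    inventory = inventory,
    uncomplicated_pct = 100 - sum(comps$incidence_pct),
    uncomplicated_entry_plan = "delivery",
    horizon_days = horizon_days, n_trials = 5, base_seed = seed
  )
}
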