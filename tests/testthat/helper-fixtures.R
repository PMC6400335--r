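# Shared fixtures and independent oracles for the test suite.

# A small single-shift configuration with one complication and short plan
# chains; every knob overridable. Used for engine-level unit tests where the
# full MMH baseline would be overkill.
tiny_config <- function(admission_prob = 0.5,
                        nurses = 2L, doctors = 1L,
                        incidence_pct = 20,
                        severity_mean = 0.1,
                        smo_mortality = 0.4,
                        deterioration_rate = 50,
                        oxytocin = 50, hydralazine = 10,
                        restock_interval = 2880L,
                        restock_enabled = TRUE,
                        acute_duration = 4L, obs_duration = 8L,
                        delivery_duration = 2L,
                        acute_nurse = 1L, acute_doctor = 0L,
                        acute_dose = 1, delivery_nurse = 1L,
                        efficacy = NULL,
                        horizon_days = 5, n_trials = 3,
                        multi_morbidity = FALSE,
                        base_seed = 7L) {
  drug <- function(dose, every) list(dose = dose, every = as.integer(every))
  mk_plan <- function(id, duration, successor = NA_character_,
                      nurse_count = 0L, nurse_every = 1L, nurse_hold = FALSE,
                      doctor_count = 0L, doctor_every = 1L,
                      doctor_hold = FALSE, drugs = list(), efficacy = 0) {
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
  chain <- acute_duration + obs_duration
  eta <- if (is.null(efficacy)) {
    calibrate_efficacy(severity_mean, chain)
  } else {
    efficacy
  }
  plans <- dplyr::bind_rows(
    mk_plan("delivery", delivery_duration, nurse_count = delivery_nurse),
    mk_plan("acute", acute_duration, successor = "obs",
            nurse_count = acute_nurse, doctor_count = acute_doctor,
            drugs = if (acute_dose > 0) list(oxytocin = drug(acute_dose, 1))
            else list(),
            efficacy = eta),
    mk_plan("obs", obs_duration, nurse_count = 0L, efficacy = eta)
  )
  comps <- tibble::tibble(
    name = "bleed",
    incidence_pct = incidence_pct,
    severity_mean = severity_mean,
    smo_mortality = smo_mortality,
    severity_sd = derive_severity_sd(severity_mean, smo_mortality),
    deterioration_rate = deterioration_rate,
    entry_plan = "acute",
    illustrative = TRUE
  )
  ward_config(
    shifts = tibble::tibble(name = "all_day", start_cycle = 0L,
                            nurses = as.integer(nurses),
                            doctors = as.integer(doctors),
                            admission_prob = admission_prob),
    complications = comps,
    plans = plans,
    inventory = list(
      stocks = c(oxytocin = oxytocin, hydralazine = hydralazine),
      restock_interval_cycles = as.integer(restock_interval),
      restock_amounts = c(oxytocin = oxytocin, hydralazine = hydralazine),
      restock_enabled = restock_enabled,
      units = c(oxytocin = "pack", hydralazine = "pack")
    ),
    uncomplicated_pct = 100 - incidence_pct,
    uncomplicated_entry_plan = "delivery",
    horizon_days = horizon_days, n_trials = n_trials,
    multi_morbidity = multi_morbidity, base_seed = base_seed
  )
}

# Truncated-normal moments on (0, 1) by numerical integration — an oracle
# independent of the inverse-CDF sampler.
truncnorm_moments <- function(mean, sd) {
  z <- stats::pnorm(1, mean, sd) - stats::pnorm(0, mean, sd)
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mean, sd) / z,
                         0, 1, rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, mean, sd) / z,
                         0, 1, rel.tol = 1e-10)$value
  list(mean = m1, sd = sqrt(m2 - m1^2), mass = z)
}

truncnorm_tail_mass <- function(mean, sd, cut) {
  z <- stats::pnorm(1, mean, sd) - stats::pnorm(0, mean, sd)
  (stats::pnorm(1, mean, sd) - stats::pnorm(cut, mean, sd)) / z
}

# Independent greedy allocation oracle for cohorts at plan progress 0 with a
# single condition each: walks patients in descending severity (ties by
# admission cycle then id) and treats all-or-nothing against the plan's
# cycle-0 demands. Returns the treated patient ids.
greedy_alloc_oracle <- function(config, severities, complication,
                                nurses, doctors, stocks) {
  comps <- config$complications
  plans <- config$plans
  n <- length(severities)
  entry <- ifelse(is.na(severities), config$uncomplicated_entry_plan,
                  comps$entry_plan[match(complication, comps$name)])
  sev <- ifelse(is.na(severities), 0, severities)
  ord <- order(-sev, seq_len(n))
  avail_n <- nurses
  avail_d <- doctors
  stock <- stocks
  treated <- logical(n)
  for (i in ord) {
    pl <- plans[plans$id == entry[i], ]
    dn <- pl$nurse_count
    dd <- pl$doctor_count
    ddrug <- stats::setNames(numeric(length(stock)), names(stock))
    for (d in names(pl$drugs[[1]])) ddrug[d] <- pl$drugs[[1]][[d]]$dose
    if (dn <= avail_n && dd <= avail_d && all(ddrug <= stock)) {
      treated[i] <- TRUE
      avail_n <- avail_n - dn
      avail_d <- avail_d - dd
      stock <- stock - ddrug
    }
  }
  which(treated)
}

run_quiet <- function(expr) suppressMessages(force(expr))
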