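#' The four-step simulation cycle
#'
#' Each 15-minute cycle runs, in order: admission of at most one new patient
#' (shift-dependent Bernoulli), assignment/advancement of treatment plans,
#' greedy all-or-nothing allocation of staff and medicines in descending
#' order of composite mortality, probability dynamics (geometric improvement
#' for treated conditions, gamma-deterioration for untreated ones), survival
#' evaluation against each patient's lifetime uniform variate, and restocking
#' / shift bookkeeping. [run_trial()] composes these over a full horizon.
#'
#' A fixed number of uniform draws is consumed every cycle whether or not an
#' admission occurs, so trials with the same seed stay aligned across
#' scenario variants (common random numbers).
#'
#' @name ward-engine
NULL

severity_from_u <- function(cc, comp, u) {
  x <- stats::qnorm(cc$sev_lo[comp] + u * (cc$sev_hi[comp] - cc$sev_lo[comp]),
                    cc$sev_mean[comp], cc$sev_sd[comp])
  pmin(pmax(x, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' Admission step
#'
#' With the current shift's admission probability, admits exactly one patient
#' (or none) this cycle. An admitted patient receives complications by
#' incidence (a single categorical draw by default; independent per-
#' complication draws under multi-morbidity), severities from each
#' complication's truncated-normal severity distribution, the entry treatment
#' plan of each condition, and her lifetime survival variate.
#'
#' @param state A `ward_state`; modified in place.
#' @return The state, invisibly.
#' @export
step_admission <- function(state) {
  st <- state
  cc <- st$cc
  u <- stats::runif(cc$draws_per_cycle)
  s <- current_shift(st)
  if (u[1] <= cc$shift_padm[s] && cc$shift_padm[s] > 0) {
    if (cc$multi) {
      k <- cc$n_comp
      hit <- which(u[1L + seq_len(k)] < cc$inc_frac)
      U <- u[2L * k + 2L]
      if (length(hit) == 0L) {
        add_patient(st, integer(0), numeric(0), U)
      } else {
        sev <- severity_from_u(cc, hit, u[1L + k + hit])
        add_patient(st, hit, sev, U)
      }
    } else {
      cidx <- findInterval(u[2], c(0, cc$cum_inc))
      U <- u[4]
      if (cidx > cc$n_comp) {
        add_patient(st, integer(0), numeric(0), U)
      } else {
        add_patient(st, cidx, severity_from_u(cc, cidx, u[3]), U)
      }
    }
  }
  invisible(st)
}

#' Plan assignment step
#'
#' Advances conditions whose plan completed last cycle to the successor plan
#' (releasing any staff held by the completed plan), and discharges alive any
#' patient whose every plan chain is complete.
#'
#' @param state A `ward_state`; modified in place.
#' @return The state, invisibly.
#' @export
assign_plans <- function(state) {
  st <- state
  refresh_active(st)
  act <- st$act
  if (length(act) == 0L) return(invisible(st))
  cc <- st$cc
  j <- st$act_cond
  pl <- st$cd_plan[j]
  done <- pl > 0L
  done[done] <- st$cd_prog[j[done]] >= cc$plan_dur[pl[done]]
  if (any(done)) {
    rows <- j[done]
    st$held_n_total <- st$held_n_total - sum(st$cd_held_n[rows])
    st$held_d_total <- st$held_d_total - sum(st$cd_held_d[rows])
    st$cd_held_n[rows] <- 0L
    st$cd_held_d[rows] <- 0L
    st$cd_plan[rows] <- cc$plan_succ[st$cd_plan[rows]]
    st$cd_prog[rows] <- 0L
  }
  pl <- st$cd_plan[j]
  if (!cc$multi) {
    any_active <- pl > 0L
  } else {
    any_active <- as.vector(rowsum((pl > 0L) + 0, st$cd_pat[j])) > 0
  }
  if (!all(any_active)) {
    disc <- act[!any_active]
    st$in_ward[disc] <- FALSE
    st$discharges <- st$discharges + length(disc)
    st$ev_disc_cycle <- c(st$ev_disc_cycle, rep(st$cycle, length(disc)))
    st$ev_disc_pat <- c(st$ev_disc_pat, disc)
    st$act <- act[any_active]
    st$act_dirty <- TRUE
    refresh_active(st)
  }
  invisible(st)
}

#' Resource allocation step
#'
#' Computes each patient's incremental demand for this cycle (staff visits
#' due at the current plan progress, minus staff already held with the
#' patient, plus drug doses due) and walks the cohort in strictly descending
#' composite probability of mortality (ties: earlier admission, then patient
#' id). A patient is treated only if *every* demanded unit is available —
#' all-or-nothing; shortage is a modelled outcome, not an error. Treated
#' demands are decremented from stock and the staff pool; plans flagged
#' `*_hold` keep their staff reserved across cycles until the plan completes.
#'
#' On return `state$treated` / `state$untreated` hold the patient ids of this
#' cycle's treated and untreated sets.
#'
#' @param state A `ward_state`; modified in place.
#' @return The state, invisibly.
#' @export
allocate_resources <- function(state) {
  st <- state
  refresh_active(st)
  act <- st$act
  if (length(act) == 0L) {
    st$treated <- integer(0)
    st$untreated <- integer(0)
    return(invisible(st))
  }
  cc <- st$cc
  j <- st$act_cond
  nj <- length(j)
  pl <- st$cd_plan[j]
  prog <- st$cd_prog[j]
  ip <- which(pl > 0L)

  new_n <- numeric(nj)
  new_d <- numeric(nj)
  dem_drug <- matrix(0, nj, cc$n_drugs)
  due_hold_n <- logical(nj)
  due_hold_d <- logical(nj)
  req_n <- numeric(nj)
  req_d <- numeric(nj)
  if (length(ip)) {
    plp <- pl[ip]
    progp <- prog[ip]
    dn <- cc$plan_ncount[plp] > 0L & progp %% cc$plan_nevery[plp] == 0L
    dd <- cc$plan_dcount[plp] > 0L & progp %% cc$plan_devery[plp] == 0L
    req_n[ip] <- ifelse(dn, cc$plan_ncount[plp], 0)
    req_d[ip] <- ifelse(dd, cc$plan_dcount[plp], 0)
    new_n[ip] <- pmax(0, req_n[ip] - st$cd_held_n[j[ip]])
    new_d[ip] <- pmax(0, req_d[ip] - st$cd_held_d[j[ip]])
    due_hold_n[ip] <- dn & cc$plan_nhold[plp]
    due_hold_d[ip] <- dd & cc$plan_dhold[plp]
    for (d in seq_len(cc$n_drugs)) {
      ev <- cc$plan_every[plp, d]
      due <- ev > 0L & progp %% pmax(ev, 1L) == 0L
      dem_drug[ip[due], d] <- cc$plan_dose[plp[due], d]
    }
  }

  if (!cc$multi) {
    pat_n <- new_n
    pat_d <- new_d
    pat_drug <- dem_drug
    p_c <- st$cd_p[j]
  } else {
    grp <- st$cd_pat[j]
    agg <- rowsum(cbind(new_n, new_d, dem_drug, log1p(-st$cd_p[j])), grp)
    pat_n <- agg[, 1]
    pat_d <- agg[, 2]
    pat_drug <- agg[, 2L + seq_len(cc$n_drugs), drop = FALSE]
    p_c <- -expm1(agg[, ncol(agg)])
  }

  s <- current_shift(st)
  avail_n <- max(0, cc$shift_nurses[s] - st$held_n_total)
  avail_d <- max(0, cc$shift_doctors[s] - st$held_d_total)
  stock <- st$stocks

  drug_need <- if (cc$n_drugs > 0) rowSums(pat_drug) else numeric(length(act))
  need_any <- pat_n > 0 | pat_d > 0 | drug_need > 0
  treated <- !need_any # zero-demand cycles are trivially treated

  # patients whose demand exceeds even the cycle-opening resources can be
  # refused without entering the greedy pass (resources only shrink)
  feasible0 <- pat_n <= avail_n & pat_d <= avail_d
  if (cc$n_drugs > 0) {
    for (d in seq_len(cc$n_drugs)) {
      feasible0 <- feasible0 & pat_drug[, d] <= stock[d]
    }
  }
  cand <- which(need_any & feasible0)
  if (length(cand) > 0L) {
    ord <- cand[order(-p_c[cand], st$adm_cycle[act[cand]], act[cand])]
    refused <- NULL
    for (i in ord) {
      dvec <- c(pat_n[i], pat_d[i], pat_drug[i, ])
      if (!is.null(refused)) {
        dominated <- FALSE
        for (r in seq_len(nrow(refused))) {
          if (all(dvec >= refused[r, ])) {
            dominated <- TRUE
            break
          }
        }
        if (dominated) next
      }
      if (pat_n[i] <= avail_n && pat_d[i] <= avail_d &&
          all(pat_drug[i, ] <= stock)) {
        treated[i] <- TRUE
        avail_n <- avail_n - pat_n[i]
        avail_d <- avail_d - pat_d[i]
        stock <- stock - pat_drug[i, ]
        st$dispensed <- st$dispensed + pat_drug[i, ]
      } else {
        refused <- rbind(refused, dvec)
      }
    }
  }

  # reserve holding staff acquired (or re-confirmed) this cycle
  if (!cc$multi) {
    tr_cond <- treated
  } else {
    tr_cond <- treated[match(st$cd_pat[j], act)]
  }
  hn <- which(tr_cond & due_hold_n & new_n > 0)
  if (length(hn)) {
    st$held_n_total <- st$held_n_total + as.integer(round(sum(new_n[hn])))
    st$cd_held_n[j[hn]] <- as.integer(req_n[hn])
  }
  hd <- which(tr_cond & due_hold_d & new_d > 0)
  if (length(hd)) {
    st$held_d_total <- st$held_d_total + as.integer(round(sum(new_d[hd])))
    st$cd_held_d[j[hd]] <- as.integer(req_d[hd])
  }

  st$stocks <- stock
  st$treated <- act[treated]
  st$untreated <- act[!treated]
  invisible(st)
}

#' Probability dynamics step
#'
#' Treated patients: every condition improves by its plan's efficacy
#' (`p <- p (1 - eta)`), plan progress advances one cycle, and the untreated
#' counter resets. Untreated patients: the untreated counter increments and
#' every condition with positive probability worsens by
#' `p <- p^(rate / (rate + c))`.
#'
#' @param state A `ward_state` after [allocate_resources()]; modified in
#'   place.
#' @return The state, invisibly.
#' @export
apply_dynamics <- function(state) {
  st <- state
  cc <- st$cc
  tr <- st$treated
  if (length(tr)) {
    jt <- sequence(nvec = st$cond_n[tr], from = st$cond_start[tr])
    plt <- st$cd_plan[jt]
    on <- plt > 0L
    jon <- jt[on]
    st$cd_p[jon] <- st$cd_p[jon] * (1 - cc$plan_eta[plt[on]])
    st$cd_prog[jon] <- st$cd_prog[jon] + 1L
    st$untreated_c[tr] <- 0L
  }
  un <- st$untreated
  if (length(un)) {
    st$untreated_c[un] <- st$untreated_c[un] + 1L
    ju <- sequence(nvec = st$cond_n[un], from = st$cond_start[un])
    ju <- ju[st$cd_p[ju] > 0 & st$cd_comp[ju] > 0L]
    if (length(ju)) {
      rate <- cc$det_rate[st$cd_comp[ju]]
      cu <- st$untreated_c[st$cd_pat[ju]]
      st$cd_p[ju] <- st$cd_p[ju]^(rate / (rate + cu))
    }
  }
  invisible(st)
}

#' Survival evaluation step
#'
#' Rescales each patient's composite probability of mortality to the current
#' cycle via `p = 1 - (1 - p_c)^(1/n)` (with `n` the cycles left in her
#' active plan chain, floored at 1) and updates her cumulative survival
#' product. A patient dies on the first cycle her lifetime uniform variate
#' exceeds that product — distributionally identical to drawing a fresh
#' uniform against the scaled probability each cycle. Deaths release all held
#' staff immediately and are attributed to the condition with the largest
#' individual probability of mortality.
#'
#' @param state A `ward_state` after [apply_dynamics()]; modified in place.
#' @return The state, invisibly.
#' @export
evaluate_survival <- function(state) {
  st <- state
  refresh_active(st)
  act <- st$act
  if (length(act) == 0L) return(invisible(st))
  cc <- st$cc
  j <- st$act_cond
  pl <- st$cd_plan[j]
  rem <- numeric(length(j))
  on <- pl > 0L
  rem[on] <- cc$plan_chain[pl[on]] - st$cd_prog[j[on]]

  if (!cc$multi) {
    p_c <- st$cd_p[j]
    n_rem <- pmax(1, rem)
  } else {
    grp <- st$cd_pat[j]
    p_c <- -expm1(as.vector(rowsum(log1p(-st$cd_p[j]), grp)))
    n_rem <- pmax(1, vapply(split(rem, grp), max, numeric(1)))
  }
  p_sc <- -expm1(log1p(-p_c) / n_rem)
  st$Scum[act] <- st$Scum[act] * (1 - p_sc)
  die <- st$U[act] > st$Scum[act]
  if (any(die)) {
    dead <- act[die]
    for (i in dead) {
      jr <- st$cond_start[i] + seq_len(st$cond_n[i]) - 1L
      st$held_n_total <- st$held_n_total - sum(st$cd_held_n[jr])
      st$held_d_total <- st$held_d_total - sum(st$cd_held_d[jr])
      st$cd_held_n[jr] <- 0L
      st$cd_held_d[jr] <- 0L
      comp <- st$cd_comp[jr[which.max(st$cd_p[jr])]]
      if (comp > 0L) {
        st$deaths_by_comp[comp] <- st$deaths_by_comp[comp] + 1L
      }
      st$ev_death_cycle <- c(st$ev_death_cycle, st$cycle)
      st$ev_death_pat <- c(st$ev_death_pat, i)
      st$ev_death_comp <- c(st$ev_death_comp, comp)
    }
    st$alive[dead] <- FALSE
    st$in_ward[dead] <- FALSE
    st$deaths <- st$deaths + length(dead)
    st$act <- act[!die]
    st$act_dirty <- TRUE
  }
  invisible(st)
}

#' Restock and advance step
#'
#' Restocks the inventory at multiples of the restock interval (when
#' enabled), records the end-of-cycle trajectory row, and advances the clock.
#' Shift changes need no explicit action: staff totals and the admission
#' probability are looked up from the schedule each cycle, with held staff
#' carried over and pool availability recomputed.
#'
#' @param state A `ward_state`; modified in place.
#' @return The state, invisibly.
#' @export
restock_and_advance <- function(state) {
  st <- state
  cc <- st$cc
  t <- st$cycle
  if (cc$restock_enabled && t %% cc$restock_interval == 0L) {
    st$stocks <- st$stocks + cc$restock_amounts
    st$restocked <- st$restocked + cc$restock_amounts
    st$ev_restock_cycle <- c(st$ev_restock_cycle, t)
  }
  if (st$record && t <= st$horizon) {
    st$tr_census[t] <- length(st$act)
    st$tr_deaths[t] <- st$deaths
    st$tr_adm[t] <- st$admissions
    st$tr_stock[t, ] <- st$stocks
  }
  st$cycle <- t + 1L
  invisible(st)
}

#' Advance the ward one full cycle
#'
#' Runs the steps in their fixed order: admission, plan assignment,
#' allocation, dynamics, survival, restock/advance.
#'
#' @param state A `ward_state`; modified in place.
#' @return The state, invisibly.
#' @export
ward_cycle <- function(state) {
  step_admission(state)
  assign_plans(state)
  allocate_resources(state)
  apply_dynamics(state)
  evaluate_survival(state)
  restock_and_advance(state)
  invisible(state)
}

trial_summary_row <- function(st, seed, config) {
  horizon_days <- st$horizon / config$cycles_per_day
  census <- st$tr_census[seq_len(min(st$horizon, st$cycle - 1L))]
  tibble::tibble(
    seed = as.integer(seed),
    admissions = st$admissions,
    complicated = st$n_complicated,
    deaths = st$deaths,
    discharges = st$discharges,
    in_ward_end = length(st$act),
    admissions_per_month = st$admissions / horizon_days * 30,
    mortality_rate_complicated_pct =
      if (st$n_complicated > 0) 100 * st$deaths / st$n_complicated
      else NA_real_,
    census_mean = if (length(census)) mean(census) else NA_real_,
    census_sd = if (length(census) > 1) stats::sd(census) else NA_real_
  )
}

trial_per_complication <- function(st) {
  cases <- as.integer(st$adm_by_comp)
  deaths <- as.integer(st$deaths_by_comp)
  tibble::tibble(
    complication = st$cc$comp_names,
    cases = cases,
    deaths = deaths,
    cfr_pct = ifelse(cases > 0, 100 * deaths / cases, NA_real_),
    incidence_pct = if (st$admissions > 0) 100 * cases / st$admissions
    else NA_real_
  )
}

#' Run one simulated trial
#'
#' Seeds the RNG, builds an empty ward from the configuration and executes
#' the four-step cycle for the configured horizon. Output is bit-identical
#' for identical `(config, seed)`.
#'
#' @param config A validated `ward_config`.
#' @param seed Integer seed for this trial.
#' @param keep_trajectories Keep the per-cycle census/death/stock
#'   trajectories in the result (default `TRUE`).
#' @param keep_events Keep the death/discharge/restock event log (default
#'   `TRUE`).
#' @return A `ward_trial`: list with `summary` (one-row tibble),
#'   `per_complication` (tibble), `trajectories` (tibble or `NULL`),
#'   `events` (list of tibbles or `NULL`), `seed`, and `config_hash`.
#' @examples
#' cfg <- default_mmh_config(horizon_days = 2)
#' tr <- run_trial(cfg, seed = 1)
#' tr$summary
#' @export
run_trial <- function(config, seed, keep_trajectories = TRUE,
                      keep_events = TRUE) {
  set.seed(as.integer(seed))
  st <- new_ward_state(config, record = TRUE)
  for (t in seq_len(st$horizon)) ward_cycle(st)

  trajectories <- NULL
  if (keep_trajectories) {
    trajectories <- tibble::tibble(
      cycle = seq_len(st$horizon),
      census = st$tr_census,
      deaths_cum = st$tr_deaths,
      admissions_cum = st$tr_adm
    )
    for (d in st$cc$drugs) {
      trajectories[[paste0("stock_", d)]] <- st$tr_stock[, d]
    }
  }
  events <- NULL
  if (keep_events) {
    events <- list(
      deaths = tibble::tibble(
        cycle = st$ev_death_cycle,
        patient = st$ev_death_pat,
        complication = ifelse(st$ev_death_comp > 0L,
                              st$cc$comp_names[pmax(st$ev_death_comp, 1L)],
                              "uncomplicated")
      ),
      discharges = tibble::tibble(cycle = st$ev_disc_cycle,
                                  patient = st$ev_disc_pat),
      restocks = tibble::tibble(cycle = st$ev_restock_cycle)
    )
  }
  structure(
    list(
      seed = as.integer(seed),
      summary = trial_summary_row(st, seed, config),
      per_complication = trial_per_complication(st),
      trajectories = trajectories,
      events = events,
      ledger = list(
        initial_stocks = stats::setNames(
          unlist(config$inventory$stocks)[st$cc$drugs], st$cc$drugs),
        restocked = st$restocked,
        dispensed = st$dispensed,
        final_stocks = st$stocks
      ),
      config_hash = config_hash(config)
    ),
    class = "ward_trial"
  )
}

#' @export
print.ward_trial <- function(x, ...) {
  cat(sprintf("<ward_trial> seed %d: %d admissions, %d deaths, %d discharges\n",
              x$seed, x$summary$admissions, x$summary$deaths,
              x$summary$discharges))
  invisible(x)
}

#' Run replicate trials
#'
#' Trial `i` uses seed `base_seed + i`; trials are independent and the
#' per-trial summaries are aggregated (mean, sd, quartiles of deaths).
#'
#' @param config A validated `ward_config`.
#' @param n_trials Number of replicates; defaults to `config$n_trials` (50 in
#'   the shipped baseline).
#' @param base_seed Base seed; defaults to `config$base_seed`.
#' @param keep_trajectories Keep per-cycle trajectories for every trial
#'   (default `FALSE`; memory).
#' @return A `ward_trials` object: `summary` (tibble, one row per trial),
#'   `per_complication` (tibble, one row per trial x complication),
#'   `aggregate` (one-row tibble of across-trial statistics), `trials` (list
#'   of `ward_trial`).
#' @examples
#' cfg <- default_mmh_config(horizon_days = 2)
#' res <- run_trials(cfg, n_trials = 2)
#' tidy(res)
#' @export
run_trials <- function(config, n_trials = config$n_trials,
                       base_seed = config$base_seed,
                       keep_trajectories = FALSE) {
  stopifnot(n_trials >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_trials)
  trials <- lapply(seeds, function(s) {
    run_trial(config, s, keep_trajectories = keep_trajectories)
  })
  summary <- dplyr::bind_rows(lapply(trials, `[[`, "summary")) |>
    dplyr::mutate(trial = dplyr::row_number(), .before = 1)
  per_comp <- dplyr::bind_rows(
    lapply(seq_along(trials), function(i) {
      dplyr::mutate(trials[[i]]$per_complication, trial = i, .before = 1)
    })
  )
  structure(
    list(
      summary = summary,
      per_complication = per_comp,
      aggregate = aggregate_trials(summary, per_comp),
      trials = trials,
      seeds = seeds,
      config_hash = config_hash(config)
    ),
    class = "ward_trials"
  )
}

aggregate_trials <- function(summary, per_comp) {
  q <- stats::quantile(summary$deaths, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(
    n_trials = nrow(summary),
    deaths_mean = mean(summary$deaths),
    deaths_sd = stats::sd(summary$deaths),
    deaths_q1 = q[1],
    deaths_median = q[2],
    deaths_q3 = q[3],
    admissions_per_month_mean = mean(summary$admissions_per_month),
    mortality_rate_complicated_pct_mean =
      mean(summary$mortality_rate_complicated_pct, na.rm = TRUE),
    census_mean = mean(summary$census_mean, na.rm = TRUE),
    census_sd_mean = mean(summary$census_sd, na.rm = TRUE)
  )
}

#' @export
print.ward_trials <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<ward_trials> %d trials: deaths %.2f +/- %.2f (median %g)\n",
              a$n_trials, a$deaths_mean, a$deaths_sd, a$deaths_median))
  cat(sprintf("  admissions/month %.1f, census %.1f, mortality (complicated) %.3g%%\n",
              a$admissions_per_month_mean, a$census_mean,
              a$mortality_rate_complicated_pct_mean))
  invisible(x)
}
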