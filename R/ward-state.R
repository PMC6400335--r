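#' Ward state
#'
#' A `ward_state` is the complete simulation state at a cycle boundary: the
#' patient cohort (per-condition mortality probabilities, plan progress,
#' untreated-cycle counters, held staff), the staff pool, the medicine
#' inventory, cumulative tallies and an event log. It is implemented as an
#' environment so the per-cycle step functions can update it in place; all
#' step functions also return the state invisibly so calls can be chained.
#'
#' @name ward_state
NULL

compile_config <- function(config) {
  cpd <- config$cycles_per_day
  sh <- config$shifts
  # map cycle-of-day (0-based) to shift row: each shift runs from its start
  # to the next shift's start, wrapping around midnight
  ord <- order(sh$start_cycle)
  sh <- sh[ord, ]
  shift_of_cod <- integer(cpd)
  starts <- sh$start_cycle
  n_sh <- nrow(sh)
  for (i in seq_len(n_sh)) {
    from <- starts[i]
    to <- if (i < n_sh) starts[i + 1] - 1L else cpd - 1L
    shift_of_cod[(from:to) + 1L] <- i
  }
  if (starts[1] > 0) shift_of_cod[1:starts[1]] <- n_sh # wrap before first start

  pl <- config$plans
  plan_idx <- stats::setNames(seq_len(nrow(pl)), pl$id)
  succ <- ifelse(is.na(pl$successor), 0L, plan_idx[pl$successor])
  drugs <- names(config$inventory$stocks)
  nd <- length(drugs)
  dose <- matrix(0, nrow(pl), nd, dimnames = list(pl$id, drugs))
  every <- matrix(0L, nrow(pl), nd, dimnames = list(pl$id, drugs))
  for (i in seq_len(nrow(pl))) {
    for (d in names(pl$drugs[[i]])) {
      dose[i, d] <- pl$drugs[[i]][[d]]$dose
      every[i, d] <- as.integer(pl$drugs[[i]][[d]]$every)
    }
  }
  chain <- plan_chain_lengths(pl)

  co <- config$complications
  k <- nrow(co)
  sev_lo <- stats::pnorm(0, co$severity_mean, co$severity_sd)
  sev_hi <- stats::pnorm(1, co$severity_mean, co$severity_sd)

  list(
    cpd = cpd,
    multi = config$multi_morbidity,
    shift_of_cod = shift_of_cod,
    shift_nurses = as.integer(sh$nurses),
    shift_doctors = as.integer(sh$doctors),
    shift_padm = sh$admission_prob,
    shift_names = sh$name,
    plan_ids = pl$id,
    plan_dur = as.integer(pl$duration),
    plan_eta = ifelse(is.na(pl$efficacy), 0, pl$efficacy),
    plan_succ = as.integer(succ),
    plan_chain = as.numeric(chain),
    plan_ncount = as.integer(pl$nurse_count),
    plan_nevery = as.integer(pl$nurse_every),
    plan_nhold = pl$nurse_hold,
    plan_dcount = as.integer(pl$doctor_count),
    plan_devery = as.integer(pl$doctor_every),
    plan_dhold = pl$doctor_hold,
    plan_dose = dose,
    plan_every = every,
    drugs = drugs,
    n_drugs = nd,
    comp_names = co$name,
    n_comp = k,
    inc_frac = co$incidence_pct / 100,
    cum_inc = cumsum(co$incidence_pct / 100),
    sev_mean = co$severity_mean,
    sev_sd = co$severity_sd,
    sev_lo = sev_lo,
    sev_hi = sev_hi,
    det_rate = co$deterioration_rate,
    entry_plan = as.integer(plan_idx[co$entry_plan]),
    uncomp_plan = as.integer(plan_idx[[config$uncomplicated_entry_plan]]),
    # fixed number of uniforms consumed every cycle regardless of outcome,
    # so replicate streams stay aligned across scenarios (common random
    # numbers): admission draw, assignment draw(s), severity draw(s), and
    # the patient's lifetime survival variate
    draws_per_cycle = if (config$multi_morbidity) 2L * k + 2L else 4L,
    restock_interval = config$inventory$restock_interval_cycles,
    restock_amounts = {
      ra <- stats::setNames(numeric(nd), drugs)
      amt <- config$inventory$restock_amounts
      ra[names(amt)] <- unlist(amt)
      ra
    },
    restock_enabled = isTRUE(config$inventory$restock_enabled)
  )
}

#' Create an empty ward state from a configuration
#'
#' @param config A validated `ward_config`.
#' @param record If `TRUE`, allocate per-cycle trajectory buffers for
#'   `horizon` cycles (census, cumulative deaths/admissions, stocks).
#' @param horizon_cycles Number of cycles the trajectory buffers should hold;
#'   defaults to the config horizon.
#' @return A `ward_state` environment at cycle 1 with an empty cohort.
#' @export
new_ward_state <- function(config, record = TRUE, horizon_cycles = NULL) {
  validate_config(config)
  cc <- compile_config(config)
  if (is.null(horizon_cycles)) {
    horizon_cycles <- config$horizon_days * config$cycles_per_day
  }
  cap <- 1024L
  st <- new.env(parent = emptyenv())
  st$cc <- cc
  st$config <- config
  st$cycle <- 1L
  st$horizon <- as.integer(horizon_cycles)

  # patient arrays
  st$n_pat <- 0L
  st$adm_cycle <- integer(cap)
  st$alive <- logical(cap)
  st$in_ward <- logical(cap)
  st$U <- numeric(cap)       # lifetime survival variate, drawn at admission
  st$Scum <- numeric(cap)    # running product of per-cycle survival probs
  st$untreated_c <- integer(cap)
  st$cond_start <- integer(cap)
  st$cond_n <- integer(cap)

  # condition arrays (parallel, contiguous per patient)
  st$n_cond <- 0L
  st$cd_pat <- integer(cap)
  st$cd_comp <- integer(cap)   # 0 = uncomplicated delivery
  st$cd_p <- numeric(cap)
  st$cd_plan <- integer(cap)   # 0 = chain complete
  st$cd_prog <- integer(cap)
  st$cd_held_n <- integer(cap)
  st$cd_held_d <- integer(cap)

  st$act <- integer(0)       # in-ward patient ids, increasing
  st$act_cond <- integer(0)
  st$act_dirty <- FALSE

  st$held_n_total <- 0L
  st$held_d_total <- 0L
  st$stocks <- {
    s <- stats::setNames(numeric(cc$n_drugs), cc$drugs)
    s[names(config$inventory$stocks)] <- unlist(config$inventory$stocks)
    s
  }
  st$dispensed <- stats::setNames(numeric(cc$n_drugs), cc$drugs)
  st$restocked <- stats::setNames(numeric(cc$n_drugs), cc$drugs)

  st$admissions <- 0L
  st$n_complicated <- 0L
  st$discharges <- 0L
  st$deaths <- 0L
  st$adm_by_comp <- stats::setNames(integer(cc$n_comp), cc$comp_names)
  st$deaths_by_comp <- stats::setNames(integer(cc$n_comp), cc$comp_names)

  st$treated <- integer(0)
  st$untreated <- integer(0)

  # event log (growing vectors)
  st$ev_death_cycle <- integer(0)
  st$ev_death_pat <- integer(0)
  st$ev_death_comp <- integer(0)
  st$ev_disc_cycle <- integer(0)
  st$ev_disc_pat <- integer(0)
  st$ev_restock_cycle <- integer(0)

  st$record <- isTRUE(record)
  if (st$record) {
    st$tr_census <- integer(horizon_cycles)
    st$tr_deaths <- integer(horizon_cycles)
    st$tr_adm <- integer(horizon_cycles)
    st$tr_stock <- matrix(0, horizon_cycles, cc$n_drugs,
                          dimnames = list(NULL, cc$drugs))
  }
  class(st) <- "ward_state"
  st
}

#' @export
print.ward_state <- function(x, ...) {
  cat(sprintf(
    "<ward_state> cycle %d: %d in ward, %d admitted, %d deaths, %d discharged\n",
    x$cycle, length(x$act), x$admissions, x$deaths, x$discharges))
  cat(sprintf("  stocks: %s\n",
              paste(sprintf("%s=%.4g", names(x$stocks), x$stocks),
                    collapse = ", ")))
  invisible(x)
}

grow <- function(v, n_needed) {
  if (length(v) >= n_needed) return(v)
  new_len <- max(2L * length(v), n_needed, 64L)
  if (is.matrix(v)) {
    out <- matrix(vector(mode(v), 1L), new_len, ncol(v),
                  dimnames = list(NULL, colnames(v)))
    out[seq_len(nrow(v)), ] <- v
    return(out)
  }
  out <- vector(mode(v), new_len)
  out[seq_along(v)] <- v
  out
}

ensure_pat_capacity <- function(st, n_extra) {
  need <- st$n_pat + n_extra
  if (need > length(st$adm_cycle)) {
    for (f in c("adm_cycle", "alive", "in_ward", "U", "Scum", "untreated_c",
                "cond_start", "cond_n")) {
      st[[f]] <- grow(st[[f]], need)
    }
  }
  need <- st$n_cond + n_extra * max(1L, st$cc$n_comp)
  if (need > length(st$cd_pat)) {
    for (f in c("cd_pat", "cd_comp", "cd_p", "cd_plan", "cd_prog",
                "cd_held_n", "cd_held_d")) {
      st[[f]] <- grow(st[[f]], need)
    }
  }
  invisible(st)
}

refresh_active <- function(st) {
  if (st$act_dirty) {
    st$act_cond <- sequence(nvec = st$cond_n[st$act],
                            from = st$cond_start[st$act])
    st$act_dirty <- FALSE
  }
  invisible(st)
}

current_shift <- function(st) {
  st$cc$shift_of_cod[((st$cycle - 1L) %% st$cc$cpd) + 1L]
}

#' Staff pool snapshot
#'
#' Totals, held and available counts for the shift active at the state's
#' current cycle. Available staff are recomputed as on-shift total minus
#' staff held with patients (floored at zero when a shift change leaves more
#' staff held than the incoming shift provides).
#'
#' @param state A `ward_state`.
#' @return Tibble with one row per staff type.
#' @export
ward_staff <- function(state) {
  s <- current_shift(state)
  tot_n <- state$cc$shift_nurses[s]
  tot_d <- state$cc$shift_doctors[s]
  tibble::tibble(
    staff = c("nurse", "doctor"),
    on_shift_total = c(tot_n, tot_d),
    held = c(state$held_n_total, state$held_d_total),
    available = c(max(0L, tot_n - state$held_n_total),
                  max(0L, tot_d - state$held_d_total))
  )
}

add_patient <- function(st, comps, severities, U, plan_override = NULL) {
  ensure_pat_capacity(st, 1L)
  i <- st$n_pat + 1L
  st$n_pat <- i
  st$adm_cycle[i] <- st$cycle
  st$alive[i] <- TRUE
  st$in_ward[i] <- TRUE
  st$U[i] <- U
  st$Scum[i] <- 1
  st$untreated_c[i] <- 0L

  n_cond <- max(1L, length(comps))
  j0 <- st$n_cond
  st$cond_start[i] <- j0 + 1L
  st$cond_n[i] <- n_cond
  if (length(comps) == 0L) {
    j <- j0 + 1L
    st$cd_pat[j] <- i
    st$cd_comp[j] <- 0L
    st$cd_p[j] <- 0
    st$cd_plan[j] <- if (is.null(plan_override)) st$cc$uncomp_plan else
      plan_override
    st$cd_prog[j] <- 0L
    st$cd_held_n[j] <- 0L
    st$cd_held_d[j] <- 0L
  } else {
    for (q in seq_along(comps)) {
      j <- j0 + q
      st$cd_pat[j] <- i
      st$cd_comp[j] <- comps[q]
      st$cd_p[j] <- severities[q]
      st$cd_plan[j] <- if (is.null(plan_override)) {
        st$cc$entry_plan[comps[q]]
      } else plan_override
      st$cd_prog[j] <- 0L
      st$cd_held_n[j] <- 0L
      st$cd_held_d[j] <- 0L
    }
    st$n_complicated <- st$n_complicated + 1L
    st$adm_by_comp[comps] <- st$adm_by_comp[comps] + 1L
  }
  st$n_cond <- j0 + n_cond
  st$admissions <- st$admissions + 1L
  st$act <- c(st$act, i)
  st$act_dirty <- TRUE
  invisible(i)
}

#' Build a hand-specified mini-cohort
#'
#' Creates a ward state populated with `n` patients already in the ward —
#' no admission randomness — for unit testing allocation and survival.
#' Patient `i` carries the complication named in `complication[i]` at
#' severity `severities[i]` (use `NA` for an uncomplicated delivery).
#'
#' @param config A `ward_config`.
#' @param severities Numeric vector of per-patient mortality probabilities
#'   (`NA` = uncomplicated, probability 0).
#' @param complication Character vector of complication names, recycled;
#'   ignored (treated as uncomplicated) where `severities` is `NA`.
#' @param U Optional per-patient survival variates in (0,1); default 0.5.
#' @param record Allocate trajectory buffers (default `FALSE`).
#' @param horizon_cycles Buffer length when recording.
#' @return A `ward_state` with the cohort admitted at cycle 1.
#' @export
toy_cohort <- function(config, severities,
                       complication = config$complications$name[1],
                       U = NULL, record = FALSE, horizon_cycles = 1000L) {
  st <- new_ward_state(config, record = record,
                       horizon_cycles = horizon_cycles)
  n <- length(severities)
  complication <- rep_len(complication, n)
  if (is.null(U)) U <- rep(0.5, n)
  comp_idx <- match(complication, st$cc$comp_names)
  for (i in seq_len(n)) {
    if (is.na(severities[i])) {
      add_patient(st, integer(0), numeric(0), U[i])
    } else {
      add_patient(st, comp_idx[i], severities[i], U[i])
    }
  }
  refresh_active(st)
  st
}
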