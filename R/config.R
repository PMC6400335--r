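#' Ward simulation configuration
#'
#' A `ward_config` bundles everything a simulation run needs: the shift
#' schedule (staff totals and admission probability per shift), the
#' complication mix (incidence, severity distribution, deterioration rate and
#' entry treatment plan per complication), the treatment-plan table (resource
#' demands, durations, efficacies, successor links), the medicine inventory
#' and restock rule, and run-level settings (horizon, trials, seed).
#'
#' Configurations are plain lists with tibble components so they print and
#' manipulate naturally; [load_config()] / [write_config()] round-trip them
#' through JSON.
#'
#' @name ward_config
NULL

CYCLES_PER_DAY <- 96L

config_fields <- c(
  "schema_version", "horizon_days", "n_trials", "base_seed", "cycles_per_day",
  "multi_morbidity", "uncomplicated_pct", "uncomplicated_entry_plan",
  "shifts", "complications", "plans", "inventory"
)

#' Assemble a ward configuration
#'
#' Low-level constructor; most users start from [default_mmh_config()] or
#' [load_config()]. All parts are validated with [validate_config()].
#'
#' @param shifts Tibble with columns `name`, `start_cycle` (cycle of day the
#'   shift begins, 0-based), `nurses`, `doctors`, `admission_prob`.
#' @param complications Tibble with columns `name`, `incidence_pct`,
#'   `severity_mean`, `smo_mortality`, `severity_sd`, `deterioration_rate`,
#'   `entry_plan`, `illustrative`.
#' @param plans Tibble with columns `id`, `duration`, `efficacy`, `successor`
#'   (`NA` for terminal plans), `nurse_count`, `nurse_every`, `nurse_hold`,
#'   `doctor_count`, `doctor_every`, `doctor_hold`, and a `drugs` list-column
#'   (named list `drug -> list(dose, every)` per plan).
#' @param inventory List with `stocks` (named numeric, packs),
#'   `restock_interval_cycles`, `restock_amounts` (named numeric),
#'   `restock_enabled`, `units` (named character, informational).
#' @param uncomplicated_pct Percentage of admissions with an uncomplicated
#'   delivery; together with complication incidences must total 100.
#' @param uncomplicated_entry_plan Plan id assigned to uncomplicated
#'   deliveries.
#' @param horizon_days Simulated horizon in days (default 90).
#' @param n_trials Default number of replicate trials (default 50).
#' @param base_seed Default base seed for replicate trials.
#' @param multi_morbidity If `TRUE`, complications are assigned independently
#'   so a patient may carry several; default `FALSE` (at most one).
#' @param cycles_per_day Cycles per simulated day; 96 fifteen-minute cycles.
#' @return A validated `ward_config` object.
#' @export
ward_config <- function(shifts, complications, plans, inventory,
                        uncomplicated_pct, uncomplicated_entry_plan,
                        horizon_days = 90, n_trials = 50, base_seed = 1L,
                        multi_morbidity = FALSE,
                        cycles_per_day = CYCLES_PER_DAY) {
  cfg <- structure(
    list(
      schema_version = 1L,
      horizon_days = as.integer(horizon_days),
      n_trials = as.integer(n_trials),
      base_seed = as.integer(base_seed),
      cycles_per_day = as.integer(cycles_per_day),
      multi_morbidity = isTRUE(multi_morbidity),
      uncomplicated_pct = as.numeric(uncomplicated_pct),
      uncomplicated_entry_plan = as.character(uncomplicated_entry_plan),
      shifts = tibble::as_tibble(shifts),
      complications = tibble::as_tibble(complications),
      plans = tibble::as_tibble(plans),
      inventory = inventory
    ),
    class = "ward_config"
  )
  validate_config(cfg)
  cfg
}

#' @export
print.ward_config <- function(x, ...) {
  cat("<ward_config>\n")
  cat(sprintf("  horizon: %d days (%d cycles), %d trials, base seed %d\n",
              x$horizon_days, x$horizon_days * x$cycles_per_day,
              x$n_trials, x$base_seed))
  cat(sprintf("  shifts: %s\n",
              paste(sprintf("%s(%dN/%dD, p=%.3g)", x$shifts$name,
                            x$shifts$nurses, x$shifts$doctors,
                            x$shifts$admission_prob), collapse = ", ")))
  cat(sprintf("  complications: %s (uncomplicated %.4g%%)\n",
              paste(sprintf("%s %.3g%%", x$complications$name,
                            x$complications$incidence_pct), collapse = ", "),
              x$uncomplicated_pct))
  cat(sprintf("  plans: %d; drugs: %s\n", nrow(x$plans),
              paste(sprintf("%s=%.4g packs", names(x$inventory$stocks),
                            unlist(x$inventory$stocks)), collapse = ", ")))
  invisible(x)
}

plan_chain_lengths <- function(plans) {
  # total cycles in the chain rooted at each plan; NA marks a cycle in the graph
  n <- nrow(plans)
  idx <- stats::setNames(seq_len(n), plans$id)
  total <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    seen <- integer(0)
    j <- i
    acc <- 0
    repeat {
      if (j %in% seen) {
        acc <- NA_real_
        break
      }
      seen <- c(seen, j)
      acc <- acc + plans$duration[j]
      s <- plans$successor[j]
      if (is.na(s)) break
      j <- idx[[s]]
      if (is.null(j)) break
    }
    total[i] <- acc
  }
  total
}

collect_errors <- function() {
  errs <- character(0)
  list(
    add = function(path, msg) errs <<- c(errs, sprintf("%s: %s", path, msg)),
    get = function() errs
  )
}

#' Validate a ward configuration
#'
#' Checks every structural invariant of the configuration — probabilities in
#' range, incidences plus the uncomplicated fraction totalling 100, every
#' referenced plan existing, successor chains acyclic, non-negative stocks and
#' demands, shifts partitioning the day — and fails with the full list of
#' violations, each prefixed by the field path.
#'
#' @param config A `ward_config` (or untrusted list shaped like one).
#' @return The config, invisibly, if valid; otherwise an error listing every
#'   violation.
#' @export
validate_config <- function(config) {
  ce <- collect_errors()
  add <- ce$add

  extra <- setdiff(names(config), config_fields)
  if (length(extra) > 0) {
    add("$", sprintf("unknown field(s): %s", paste(extra, collapse = ", ")))
  }
  missing <- setdiff(config_fields, names(config))
  if (length(missing) > 0) {
    add("$", sprintf("missing field(s): %s", paste(missing, collapse = ", ")))
    stop("invalid configuration:\n  ",
         paste(ce$get(), collapse = "\n  "), call. = FALSE)
  }
  if (!identical(as.integer(config$schema_version), 1L)) {
    add("$schema_version", "must be 1")
  }
  if (config$horizon_days < 1) add("$horizon_days", "must be >= 1")
  if (config$n_trials < 1) add("$n_trials", "must be >= 1")
  if (config$cycles_per_day < 1) add("$cycles_per_day", "must be >= 1")

  sh <- config$shifts
  need <- c("name", "start_cycle", "nurses", "doctors", "admission_prob")
  if (!all(need %in% names(sh)) || nrow(sh) < 1) {
    add("$shifts", sprintf("needs columns %s", paste(need, collapse = ", ")))
  } else {
    if (any(sh$admission_prob < 0 | sh$admission_prob > 1)) {
      add("$shifts$admission_prob", "must lie in [0, 1]")
    }
    if (any(sh$nurses < 0) || any(sh$doctors < 0)) {
      add("$shifts", "staff counts must be non-negative")
    }
    if (any(sh$start_cycle < 0 | sh$start_cycle >= config$cycles_per_day) ||
        anyDuplicated(sh$start_cycle)) {
      add("$shifts$start_cycle",
          sprintf("must be distinct cycles in [0, %d)", config$cycles_per_day))
    }
  }

  pl <- config$plans
  need <- c("id", "duration", "efficacy", "successor", "nurse_count",
            "nurse_every", "nurse_hold", "doctor_count", "doctor_every",
            "doctor_hold", "drugs")
  if (!all(need %in% names(pl)) || nrow(pl) < 1) {
    add("$plans", sprintf("needs columns %s", paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(pl$id)) add("$plans$id", "plan ids must be unique")
    if (any(pl$duration < 1)) add("$plans$duration", "must be >= 1")
    if (any(!is.na(pl$efficacy) & (pl$efficacy < 0 | pl$efficacy > 1))) {
      add("$plans$efficacy", "must lie in [0, 1]")
    }
    if (any(pl$nurse_count < 0) || any(pl$doctor_count < 0)) {
      add("$plans", "staff counts must be non-negative")
    }
    if (any(pl$nurse_every < 1) || any(pl$doctor_every < 1)) {
      add("$plans", "visit frequencies must be >= 1 cycle")
    }
    bad_succ <- !is.na(pl$successor) & !(pl$successor %in% pl$id)
    if (any(bad_succ)) {
      add("$plans$successor", sprintf("unknown plan id(s): %s",
          paste(pl$successor[bad_succ], collapse = ", ")))
    }
    if (!any(bad_succ) && anyNA(plan_chain_lengths(pl))) {
      add("$plans$successor", "successor chains must be acyclic")
    }
    for (i in seq_len(nrow(pl))) {
      dr <- pl$drugs[[i]]
      for (d in names(dr)) {
        if (!d %in% names(config$inventory$stocks)) {
          add(sprintf("$plans[%s]$drugs$%s", pl$id[i], d),
              "drug not present in inventory stocks")
        }
        if (dr[[d]]$dose < 0) {
          add(sprintf("$plans[%s]$drugs$%s$dose", pl$id[i], d),
              "must be non-negative")
        }
        if (dr[[d]]$every < 1) {
          add(sprintf("$plans[%s]$drugs$%s$every", pl$id[i], d),
              "must be >= 1 cycle")
        }
      }
    }
  }

  co <- config$complications
  need <- c("name", "incidence_pct", "severity_mean", "smo_mortality",
            "severity_sd", "deterioration_rate", "entry_plan", "illustrative")
  if (!all(need %in% names(co))) {
    add("$complications", sprintf("needs columns %s",
                                  paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(co$name)) add("$complications$name", "must be unique")
    if (any(co$incidence_pct < 0)) add("$complications$incidence_pct",
                                       "must be non-negative")
    tot <- sum(co$incidence_pct) + config$uncomplicated_pct
    if (abs(tot - 100) > 1e-9) {
      add("$complications$incidence_pct",
          sprintf("incidences + uncomplicated_pct must total 100 (got %.10g)",
                  tot))
    }
    if (any(co$severity_mean <= 0 | co$severity_mean >= 1)) {
      add("$complications$severity_mean", "must lie in (0, 1)")
    }
    if (any(co$smo_mortality <= co$severity_mean)) {
      add("$complications$smo_mortality", "must exceed severity_mean")
    }
    if (any(co$severity_sd <= 0)) {
      add("$complications$severity_sd", "must be positive")
    }
    if (any(co$deterioration_rate <= 0)) {
      add("$complications$deterioration_rate", "must be positive")
    }
    if (nrow(config$plans) > 0) {
      bad <- !(co$entry_plan %in% config$plans$id)
      if (any(bad)) add("$complications$entry_plan",
                        sprintf("unknown plan id(s): %s",
                                paste(co$entry_plan[bad], collapse = ", ")))
    }
  }
  if (config$uncomplicated_pct < 0 || config$uncomplicated_pct > 100) {
    add("$uncomplicated_pct", "must lie in [0, 100]")
  }
  if (nrow(config$plans) > 0 &&
      !(config$uncomplicated_entry_plan %in% config$plans$id)) {
    add("$uncomplicated_entry_plan", "unknown plan id")
  }

  inv <- config$inventory
  need <- c("stocks", "restock_interval_cycles", "restock_amounts",
            "restock_enabled", "units")
  if (!all(need %in% names(inv))) {
    add("$inventory", sprintf("needs fields %s", paste(need, collapse = ", ")))
  } else {
    if (any(unlist(inv$stocks) < 0)) add("$inventory$stocks",
                                         "must be non-negative")
    if (inv$restock_interval_cycles < 1) {
      add("$inventory$restock_interval_cycles", "must be >= 1")
    }
    if (any(unlist(inv$restock_amounts) < 0)) {
      add("$inventory$restock_amounts", "must be non-negative")
    }
    miss <- setdiff(names(inv$restock_amounts), names(inv$stocks))
    if (length(miss) > 0) {
      add("$inventory$restock_amounts",
          sprintf("drug(s) not in stocks: %s", paste(miss, collapse = ", ")))
    }
  }

  errs <- ce$get()
  if (length(errs) > 0) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(config)
}

config_to_list <- function(config) {
  pl <- config$plans
  plans <- lapply(seq_len(nrow(pl)), function(i) {
    drugs <- lapply(pl$drugs[[i]], function(d) {
      list(dose = d$dose, every = as.integer(d$every))
    })
    list(
      id = pl$id[i],
      duration = as.integer(pl$duration[i]),
      efficacy = pl$efficacy[i],
      successor = if (is.na(pl$successor[i])) NULL else pl$successor[i],
      nurse_count = as.integer(pl$nurse_count[i]),
      nurse_every = as.integer(pl$nurse_every[i]),
      nurse_hold = pl$nurse_hold[i],
      doctor_count = as.integer(pl$doctor_count[i]),
      doctor_every = as.integer(pl$doctor_every[i]),
      doctor_hold = pl$doctor_hold[i],
      drugs = drugs
    )
  })
  co <- config$complications
  comps <- lapply(seq_len(nrow(co)), function(i) {
    list(
      name = co$name[i],
      incidence_pct = co$incidence_pct[i],
      severity_mean = co$severity_mean[i],
      smo_mortality = co$smo_mortality[i],
      severity_sd = co$severity_sd[i],
      deterioration_rate = co$deterioration_rate[i],
      entry_plan = co$entry_plan[i],
      illustrative = co$illustrative[i]
    )
  })
  sh <- config$shifts
  shifts <- lapply(seq_len(nrow(sh)), function(i) {
    list(
      name = sh$name[i],
      start_cycle = as.integer(sh$start_cycle[i]),
      nurses = as.integer(sh$nurses[i]),
      doctors = as.integer(sh$doctors[i]),
      admission_prob = sh$admission_prob[i]
    )
  })
  list(
    schema_version = 1L,
    horizon_days = config$horizon_days,
    n_trials = config$n_trials,
    base_seed = config$base_seed,
    cycles_per_day = config$cycles_per_day,
    multi_morbidity = config$multi_morbidity,
    uncomplicated_pct = config$uncomplicated_pct,
    uncomplicated_entry_plan = config$uncomplicated_entry_plan,
    shifts = shifts,
    complications = comps,
    plans = plans,
    inventory = list(
      stocks = as.list(config$inventory$stocks),
      restock_interval_cycles =
        as.integer(config$inventory$restock_interval_cycles),
      restock_amounts = as.list(config$inventory$restock_amounts),
      restock_enabled = config$inventory$restock_enabled,
      units = as.list(config$inventory$units)
    )
  )
}

list_to_config <- function(x) {
  row_bind <- function(items, fields, defaults = list()) {
    rows <- lapply(items, function(it) {
      for (f in names(defaults)) if (is.null(it[[f]])) it[[f]] <- defaults[[f]]
      tibble::as_tibble(it[fields])
    })
    dplyr::bind_rows(rows)
  }
  plans <- dplyr::bind_rows(lapply(x$plans, function(p) {
    drugs <- lapply(p$drugs, function(d) list(dose = d$dose,
                                              every = as.integer(d$every)))
    tibble::tibble(
      id = p$id, duration = as.integer(p$duration),
      efficacy = if (is.null(p$efficacy)) NA_real_ else p$efficacy,
      successor = if (is.null(p$successor)) NA_character_ else p$successor,
      nurse_count = as.integer(p$nurse_count),
      nurse_every = as.integer(p$nurse_every),
      nurse_hold = isTRUE(p$nurse_hold),
      doctor_count = as.integer(p$doctor_count),
      doctor_every = as.integer(p$doctor_every),
      doctor_hold = isTRUE(p$doctor_hold),
      drugs = list(drugs)
    )
  }))
  comps <- row_bind(x$complications,
                    c("name", "incidence_pct", "severity_mean",
                      "smo_mortality", "severity_sd", "deterioration_rate",
                      "entry_plan", "illustrative"),
                    defaults = list(illustrative = FALSE))
  shifts <- row_bind(x$shifts,
                     c("name", "start_cycle", "nurses", "doctors",
                       "admission_prob"))
  ward_config(
    shifts = shifts,
    complications = comps,
    plans = plans,
    inventory = list(
      stocks = unlist(x$inventory$stocks),
      restock_interval_cycles = as.integer(x$inventory$restock_interval_cycles),
      restock_amounts = unlist(x$inventory$restock_amounts),
      restock_enabled = isTRUE(x$inventory$restock_enabled),
      units = unlist(x$inventory$units)
    ),
    uncomplicated_pct = x$uncomplicated_pct,
    uncomplicated_entry_plan = x$uncomplicated_entry_plan,
    horizon_days = x$horizon_days %||% 90,
    n_trials = x$n_trials %||% 50,
    base_seed = x$base_seed %||% 1L,
    multi_morbidity = isTRUE(x$multi_morbidity),
    cycles_per_day = x$cycles_per_day %||% CYCLES_PER_DAY
  )
}

#' Read and validate a ward configuration from JSON
#'
#' Parses a JSON configuration file, injects defaults (90-day horizon, 50
#' trials, monthly restocking) and validates every invariant, reporting all
#' violations at once with field paths.
#'
#' @param path Path to a JSON configuration file.
#' @return A validated `ward_config`.
#' @seealso [write_config()], [default_mmh_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  extra <- setdiff(names(x), config_fields)
  if (length(extra) > 0) {
    stop("invalid configuration:\n  $: unknown field(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  list_to_config(x)
}

#' Write a ward configuration to JSON
#'
#' Serialises the configuration with a fixed field order and full numeric
#' precision, so write -> read -> write is byte-identical.
#'
#' @param config A `ward_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  json <- jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Hash of a configuration
#'
#' Stable content hash of the canonical JSON serialisation; recorded in every
#' results document so outputs can be traced to their exact inputs.
#'
#' @param config A `ward_config`.
#' @return A hex string.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE,
                           digits = NA, null = "null")
  rlang::hash(as.character(json))
}
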