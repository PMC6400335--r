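#' Scenario sweeps
#'
#' Batch experiments over the three policy levers the model is built to
#' interrogate: medicine stocks and restocking cadence, staffing levels
#' (uniform grids and per-shift patterns), and patient influx. Every sweep
#' returns a tidy tibble with one row per cell per trial (class
#' `ward_sweep`), with a cell-level summary in `attr(x, "summary")` and, for
#' shift patterns, pairwise Welch tests in `attr(x, "comparisons")`. All
#' cells reuse the same seed block (common random numbers), so paired
#' contrasts between cells are sharpened and results are independent of the
#' order cells are run in.
#'
#' @name scenarios
NULL

new_ward_sweep <- function(rows, kind, summary, comparisons = NULL) {
  out <- tibble::as_tibble(rows)
  class(out) <- c("ward_sweep", class(out))
  attr(out, "kind") <- kind
  attr(out, "summary") <- summary
  if (!is.null(comparisons)) attr(out, "comparisons") <- comparisons
  out
}

run_sweep_cells <- function(cells, configs, n_trials, base_seed, kind) {
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    res <- run_trials(configs[[i]], n_trials = n_trials,
                      base_seed = base_seed)
    sm <- res$summary[, c("trial", "seed", "deaths", "admissions",
                          "complicated", "mortality_rate_complicated_pct",
                          "census_mean")]
    rows[[i]] <- dplyr::bind_cols(cells[rep(i, nrow(sm)), , drop = FALSE], sm)
  }
  rows <- dplyr::bind_rows(rows)
  keys <- names(cells)
  summary <- rows |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      deaths_mean = mean(.data$deaths),
      deaths_sd = stats::sd(.data$deaths),
      deaths_median = stats::median(.data$deaths),
      deaths_q1 = stats::quantile(.data$deaths, 0.25),
      deaths_q3 = stats::quantile(.data$deaths, 0.75),
      mortality_rate_complicated_pct_mean =
        mean(.data$mortality_rate_complicated_pct, na.rm = TRUE),
      .groups = "drop"
    )
  new_ward_sweep(rows, kind, summary)
}

#' Sweep initial medicine stock and restocking cadence
#'
#' Varies the initial stock of one medicine and compares monthly restocking
#' (by the same amount) to no restocking, holding the other medicine fixed:
#' when sweeping oxytocin, hydralazine is pinned at 11 packs with no
#' restocking; when sweeping hydralazine, oxytocin is pinned at 200 packs
#' with no restocking.
#'
#' @param config Base `ward_config`.
#' @param drug `"oxytocin"` or `"hydralazine"`.
#' @param stocks Initial stock grid (packs). Defaults: oxytocin
#'   `c(0, 50, 100, 150, 200, 250)`; hydralazine `c(0, 5, 10, 15, 20, 25)`.
#' @param restock Logical vector of restocking regimes to cross with the
#'   stock grid (default both `TRUE` and `FALSE`).
#' @param n_trials Trials per cell (default `config$n_trials`).
#' @param base_seed Common seed block (default `config$base_seed`).
#' @return A `ward_sweep` tibble (one row per cell per trial).
#' @export
sweep_medication <- function(config, drug = c("oxytocin", "hydralazine"),
                             stocks = NULL, restock = c(TRUE, FALSE),
                             n_trials = config$n_trials,
                             base_seed = config$base_seed) {
  drug <- match.arg(drug)
  if (!drug %in% names(config$inventory$stocks)) {
    stop("drug not in inventory: ", drug, call. = FALSE)
  }
  if (is.null(stocks)) {
    stocks <- if (drug == "oxytocin") c(0, 50, 100, 150, 200, 250)
    else c(0, 5, 10, 15, 20, 25)
  }
  other <- setdiff(names(config$inventory$stocks), drug)
  fixed <- c(oxytocin = 200, hydralazine = 11)

  cells <- tidyr::expand_grid(drug = drug, stock = stocks, restock = restock)
  configs <- purrr::pmap(cells, function(drug, stock, restock) {
    cfg <- config
    cfg$inventory$stocks[[drug]] <- stock
    cfg$inventory$restock_amounts[[drug]] <- if (restock) stock else 0
    for (o in other) {
      if (o %in% names(fixed)) cfg$inventory$stocks[[o]] <- fixed[[o]]
      cfg$inventory$restock_amounts[[o]] <- 0
    }
    cfg$inventory$restock_enabled <- TRUE
    cfg
  })
  run_sweep_cells(cells, configs, n_trials, base_seed, kind = "medication")
}

#' Sweep a uniform nurse x doctor staffing grid
#'
#' Staffing is held constant across all shifts at each (nurses, doctors)
#' combination and the mean number of maternal deaths per cell is computed
#' over replicate trials.
#'
#' @param config Base `ward_config`.
#' @param nurses,doctors Integer grids (default `0:10` each).
#' @param n_trials Trials per cell.
#' @param base_seed Common seed block.
#' @return A `ward_sweep` tibble.
#' @export
sweep_staffing <- function(config, nurses = 0:10, doctors = 0:10,
                           n_trials = config$n_trials,
                           base_seed = config$base_seed) {
  cells <- tidyr::expand_grid(nurses = as.integer(nurses),
                              doctors = as.integer(doctors))
  configs <- purrr::pmap(cells, function(nurses, doctors) {
    cfg <- config
    cfg$shifts$nurses <- rep(nurses, nrow(cfg$shifts))
    cfg$shifts$doctors <- rep(doctors, nrow(cfg$shifts))
    cfg
  })
  run_sweep_cells(cells, configs, n_trials, base_seed, kind = "staffing")
}

#' Default shift-staffing patterns for [sweep_shift_patterns()]
#'
#' The current roster plus three variants: one fewer nurse and doctor on
#' every shift (floored at zero), five nurses on all shifts, and three
#' doctors on all shifts.
#'
#' @param config A `ward_config` supplying the current shift table.
#' @return Named list of shift tibbles.
#' @export
default_shift_patterns <- function(config) {
  sh <- config$shifts
  list(
    current = sh,
    one_fewer_each = dplyr::mutate(sh,
                                   nurses = pmax(0L, .data$nurses - 1L),
                                   doctors = pmax(0L, .data$doctors - 1L)),
    five_nurses_all_shifts = dplyr::mutate(sh, nurses = 5L),
    three_doctors_all_shifts = dplyr::mutate(sh, doctors = 3L)
  )
}

#' Sweep named per-shift staffing patterns
#'
#' Compares alternative shift staffing distributions against the current
#' one. Defaults: the current distribution, one fewer nurse and doctor on
#' every shift, five nurses on all shifts, and three doctors on all shifts.
#' Per-trial death counts are compared pairwise between patterns with a
#' two-tailed Welch t-test; the tests are reported, not adjudicated.
#'
#' @param config Base `ward_config`.
#' @param patterns Named list of shift tibbles (columns as
#'   `config$shifts`); default [default_shift_patterns()].
#' @param n_trials Trials per pattern.
#' @param base_seed Common seed block.
#' @return A `ward_sweep` tibble with a `comparisons` attribute (tibble of
#'   pairwise Welch tests).
#' @export
sweep_shift_patterns <- function(config, patterns = NULL,
                                 n_trials = config$n_trials,
                                 base_seed = config$base_seed) {
  if (is.null(patterns)) patterns <- default_shift_patterns(config)
  stopifnot(length(names(patterns)) == length(patterns))
  cells <- tibble::tibble(pattern = names(patterns))
  configs <- lapply(patterns, function(p) {
    cfg <- config
    p <- tibble::as_tibble(p)
    stopifnot(nrow(p) == nrow(cfg$shifts))
    cfg$shifts$nurses <- as.integer(p$nurses)
    cfg$shifts$doctors <- as.integer(p$doctors)
    cfg
  })
  sw <- run_sweep_cells(cells, configs, n_trials, base_seed, kind = "shifts")

  pats <- names(patterns)
  comp <- list()
  if (length(pats) > 1 && n_trials > 1) {
    for (i in seq_along(pats)[-length(pats)]) {
      for (jj in seq((i + 1), length(pats))) {
        x <- sw$deaths[sw$pattern == pats[i]]
        y <- sw$deaths[sw$pattern == pats[jj]]
        tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
        comp[[length(comp) + 1L]] <- tibble::tibble(
          pattern_a = pats[i], pattern_b = pats[jj],
          deaths_mean_a = mean(x), deaths_mean_b = mean(y),
          statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
          df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
          p_value = if (is.null(tt)) NA_real_ else tt$p.value
        )
      }
    }
  }
  attr(sw, "comparisons") <- dplyr::bind_rows(comp)
  sw
}

#' Sweep the patient-influx multiplier
#'
#' Scales every shift's admission probability by a common multiplier and
#' reports the mortality rate among patients with potentially
#' life-threatening complications at each level. Probabilities that would
#' exceed 1 are clipped with a warning.
#'
#' @param config Base `ward_config`.
#' @param multipliers Numeric multipliers (default `c(0.5, 1, 1.5)`).
#' @param n_trials Trials per cell.
#' @param base_seed Common seed block.
#' @return A `ward_sweep` tibble.
#' @export
sweep_admission <- function(config, multipliers = c(0.5, 1, 1.5),
                            n_trials = config$n_trials,
                            base_seed = config$base_seed) {
  cells <- tibble::tibble(multiplier = multipliers)
  configs <- lapply(multipliers, function(m) {
    cfg <- config
    p <- cfg$shifts$admission_prob * m
    if (any(p > 1)) {
      warning("admission probability clipped at 1 for multiplier ", m,
              call. = FALSE)
      p <- pmin(p, 1)
    }
    cfg$shifts$admission_prob <- p
    cfg
  })
  run_sweep_cells(cells, configs, n_trials, base_seed, kind = "admission")
}

#' Summary statistics across replicate trials
#'
#' The outcome measures of a batch of trials: maternal deaths per trial with
#' mean/sd/quartiles, mortality rate among complicated patients (% of fatal
#' cases in that cohort), case fatality rate per complication (% of fatal
#' cases for the complication), incidence per complication (% of admissions
#' with the complication), mean daily census, and admissions normalised per
#' 30-day month. Rates over empty cohorts are reported as missing, not 0.
#'
#' @param trials A `ward_trials` object (from [run_trials()]) or a list of
#'   `ward_trial` objects.
#' @return A list of tibbles: `overall` (one row), `deaths` (one row per
#'   trial), `per_complication` (one row per complication).
#' @export
summarize_trials <- function(trials) {
  if (inherits(trials, "ward_trials")) {
    summary <- trials$summary
    per_comp <- trials$per_complication
  } else {
    trials <- if (inherits(trials, "ward_trial")) list(trials) else trials
    summary <- dplyr::bind_rows(lapply(trials, `[[`, "summary")) |>
      dplyr::mutate(trial = dplyr::row_number(), .before = 1)
    per_comp <- dplyr::bind_rows(lapply(seq_along(trials), function(i) {
      dplyr::mutate(trials[[i]]$per_complication, trial = i, .before = 1)
    }))
  }
  overall <- aggregate_trials(summary, per_comp)
  pc <- per_comp |>
    dplyr::group_by(.data$complication) |>
    dplyr::summarise(
      cases_total = sum(.data$cases),
      deaths_total = sum(.data$deaths),
      cfr_pct_mean = mean(.data$cfr_pct, na.rm = TRUE),
      cfr_pct_pooled = ifelse(sum(.data$cases) > 0,
                              100 * sum(.data$deaths) / sum(.data$cases),
                              NA_real_),
      incidence_pct_mean = mean(.data$incidence_pct, na.rm = TRUE),
      .groups = "drop"
    )
  pc$cfr_pct_mean[is.nan(pc$cfr_pct_mean)] <- NA_real_
  pc$incidence_pct_mean[is.nan(pc$incidence_pct_mean)] <- NA_real_
  list(
    overall = overall,
    deaths = summary[, c("trial", "seed", "deaths")],
    per_complication = pc
  )
}
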