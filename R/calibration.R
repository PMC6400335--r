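#' Calibration of the ward model
#'
#' Calibration fixes the model's free constants in three layers:
#' severity-distribution standard deviations follow analytically from the SMO
#' anchor ([derive_severity_sd()]); treatment efficacies follow analytically
#' from the rule that complete treatment drives the mean severity to the
#' 1e-10 floor by the end of the plan chain ([calibrate_efficacy()]); and
#' per-complication deterioration rates are the only simulated fit — a
#' monotone bisection on log-lambda against the simulated case fatality rate,
#' using common random numbers across evaluations. Complication incidence
#' rates are inputs (the admission mixture), never fitted.
#'
#' @name calibration
NULL

#' Specify calibration targets
#'
#' @param cfr_pct Named numeric vector: target case fatality rate (%) per
#'   complication name. Values must lie strictly inside (0, 100).
#' @param incidence_pct Optional named numeric vector of target incidence
#'   rates (%); used only for reporting (incidence is an input, not fitted).
#' @param smo_mortality Optional probability overriding the configuration's
#'   per-complication SMO mortality anchors.
#' @param tolerance_pct Relative tolerance (%) on the achieved CFR at which
#'   the bisection stops (default 10).
#' @param mc_trials Replicate trials per objective evaluation (default 20).
#' @param horizon_days Simulated horizon per evaluation (default 30).
#' @param lambda_bounds Bracket for the deterioration rate (default
#'   `c(1e-2, 1e4)`).
#' @param max_iter Bisection iteration cap per complication (default 25).
#' @return A `calibration_targets` object.
#' @export
calibration_targets <- function(cfr_pct, incidence_pct = NULL,
                                smo_mortality = NULL, tolerance_pct = 10,
                                mc_trials = 20, horizon_days = 30,
                                lambda_bounds = c(1e-2, 1e4), max_iter = 25) {
  if (is.null(names(cfr_pct)) || any(!nzchar(names(cfr_pct)))) {
    stop("`cfr_pct` must be named by complication", call. = FALSE)
  }
  if (any(cfr_pct <= 0 | cfr_pct >= 100)) {
    stop("target case fatality rates must lie strictly inside (0, 100): ",
         "a deterioration rate cannot drive the CFR to exactly 0 while the ",
         "mean severity is positive", call. = FALSE)
  }
  if (tolerance_pct <= 0) stop("`tolerance_pct` must be positive",
                               call. = FALSE)
  structure(
    list(cfr_pct = cfr_pct, incidence_pct = incidence_pct,
         smo_mortality = smo_mortality, tolerance_pct = tolerance_pct,
         mc_trials = as.integer(mc_trials),
         horizon_days = as.integer(horizon_days),
         lambda_bounds = lambda_bounds, max_iter = as.integer(max_iter)),
    class = "calibration_targets"
  )
}

set_lambda <- function(config, comp, lambda) {
  config$complications$deterioration_rate[
    config$complications$name == comp] <- lambda
  config
}

pooled_cfr <- function(config, comp, targets, base_seed) {
  # pooled (deaths / cases) over replicate trials; common seeds across
  # evaluations sharpen the monotone objective
  cfg <- config
  cfg$horizon_days <- targets$horizon_days
  res <- run_trials(cfg, n_trials = targets$mc_trials, base_seed = base_seed)
  pc <- res$per_complication[res$per_complication$complication == comp, ]
  cases <- sum(pc$cases)
  if (cases == 0) return(NA_real_)
  100 * sum(pc$deaths) / cases
}

#' Fit deterioration rates to target case fatality rates
#'
#' For each targeted complication in turn, bisects the deterioration rate on
#' a log scale against the simulated (pooled) case fatality rate, holding the
#' other complications at their current rates. The simulated CFR is strictly
#' non-increasing in the rate (a larger rate means slower worsening), so the
#' objective is monotone up to Monte-Carlo noise; identical seeds are reused
#' for every evaluation. A target outside the CFRs attainable within the
#' bracket is flagged `converged = FALSE` with the bracket endpoint values.
#'
#' @param config A validated `ward_config` with efficacies already set.
#' @param targets A [calibration_targets()] object.
#' @param base_seed Seed block used for every objective evaluation; defaults
#'   to `config$base_seed`.
#' @return A `ward_calibration`: `config` (rates updated), `rates` (tibble
#'   with fitted lambda, achieved and target CFR, convergence flag), `trace`
#'   (tibble of every evaluation).
#' @export
fit_deterioration_rates <- function(config, targets,
                                    base_seed = config$base_seed) {
  stopifnot(inherits(targets, "calibration_targets"))
  validate_config(config)
  comps <- names(targets$cfr_pct)
  unknown <- setdiff(comps, config$complications$name)
  if (length(unknown) > 0) {
    stop("targets name unknown complication(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lo_l <- log10(targets$lambda_bounds[1])
  hi_l <- log10(targets$lambda_bounds[2])
  trace <- list()
  rows <- list()
  cfg <- config
  for (comp in comps) {
    target <- targets$cfr_pct[[comp]]
    note <- NA_character_
    f <- function(loglam) {
      cfr <- pooled_cfr(set_lambda(cfg, comp, 10^loglam), comp, targets,
                        base_seed)
      trace[[length(trace) + 1L]] <<- tibble::tibble(
        complication = comp, lambda = 10^loglam, cfr_pct = cfr)
      cfr
    }
    cfr_lo <- f(lo_l)  # fast deterioration: highest CFR
    cfr_hi <- f(hi_l)  # slow deterioration: lowest CFR
    converged <- FALSE
    if (is.na(cfr_lo) || is.na(cfr_hi)) {
      lam <- NA_real_
      achieved <- NA_real_
      note <- "no cases simulated; increase horizon or incidence"
    } else if (target > cfr_lo || target < cfr_hi) {
      lam <- NA_real_
      achieved <- NA_real_
      note <- sprintf(
        "target %.3g%% outside attainable CFR range [%.3g%%, %.3g%%] over lambda bracket",
        target, cfr_hi, cfr_lo)
    } else {
      a <- lo_l
      b <- hi_l
      lam <- 10^((a + b) / 2)
      achieved <- NA_real_
      for (it in seq_len(targets$max_iter)) {
        mid <- (a + b) / 2
        achieved <- f(mid)
        lam <- 10^mid
        if (!is.na(achieved) &&
            abs(achieved - target) <= targets$tolerance_pct / 100 * target) {
          converged <- TRUE
          break
        }
        # CFR decreasing in lambda: too-high CFR means lambda too small
        if (is.na(achieved) || achieved > target) a <- mid else b <- mid
      }
      if (!converged) {
        note <- sprintf("iteration cap reached; achieved %.3g%% vs target %.3g%%",
                        achieved, target)
      }
      cfg <- set_lambda(cfg, comp, lam)
    }
    rows[[comp]] <- tibble::tibble(
      complication = comp, lambda = lam,
      achieved_cfr_pct = achieved, target_cfr_pct = target,
      cfr_at_bracket = list(c(low_lambda = cfr_lo, high_lambda = cfr_hi)),
      converged = converged, note = note)
  }
  structure(
    list(config = cfg,
         rates = dplyr::bind_rows(rows),
         trace = dplyr::bind_rows(trace),
         targets = targets,
         base_seed = as.integer(base_seed)),
    class = "ward_calibration"
  )
}

#' @export
print.ward_calibration <- function(x, ...) {
  cat("<ward_calibration>\n")
  print(x$rates[, c("complication", "lambda", "achieved_cfr_pct",
                    "target_cfr_pct", "converged")])
  invisible(x)
}

#' Build a fully calibrated configuration
#'
#' Applies the three calibration layers to a raw configuration: severity
#' standard deviations from the SMO anchor, plan-chain efficacies from the
#' 1e-10 decay rule, and deterioration rates fitted to the target case
#' fatality rates. The returned config carries a `calibration` attribute
#' recording the provenance of every fitted value.
#'
#' @param raw_config A validated `ward_config`.
#' @param targets A [calibration_targets()] object; must cover every
#'   complication to be fitted.
#' @param base_seed Seed block for the deterioration fit.
#' @return A calibrated `ward_config`.
#' @export
build_calibrated_config <- function(raw_config, targets,
                                    base_seed = raw_config$base_seed) {
  validate_config(raw_config)
  cfg <- raw_config
  if (!is.null(targets$smo_mortality)) {
    cfg$complications$smo_mortality <- targets$smo_mortality
  }
  if (any(is.na(cfg$complications$smo_mortality))) {
    stop("smo_mortality missing: supply it in the config or the targets",
         call. = FALSE)
  }
  cfg$complications$severity_sd <- derive_severity_sd(
    cfg$complications$severity_mean, cfg$complications$smo_mortality)

  chain_total <- stats::setNames(plan_chain_lengths(cfg$plans), cfg$plans$id)
  for (i in seq_len(nrow(cfg$complications))) {
    eta <- calibrate_efficacy(cfg$complications$severity_mean[i],
                              chain_total[[cfg$complications$entry_plan[i]]])
    pid <- cfg$complications$entry_plan[i]
    while (!is.na(pid)) {
      cfg$plans$efficacy[cfg$plans$id == pid] <- eta
      pid <- cfg$plans$successor[cfg$plans$id == pid]
    }
  }
  fit <- fit_deterioration_rates(cfg, targets, base_seed = base_seed)
  out <- fit$config
  attr(out, "calibration") <- list(
    targets = targets,
    rates = fit$rates,
    base_seed = fit$base_seed,
    efficacies = stats::setNames(out$plans$efficacy, out$plans$id),
    severity_sd = stats::setNames(out$complications$severity_sd,
                                  out$complications$name)
  )
  out
}

#' Compare a calibrated model against its targets
#'
#' Runs replicate trials under the given configuration and summarises, per
#' complication, the distribution of simulated case fatality and incidence
#' rates (median, quartiles, 1.5-IQR whiskers, outlier count, mean including
#' outliers) next to the targets.
#'
#' @param config A `ward_config` (typically calibrated).
#' @param targets A [calibration_targets()] object (targets echoed in the
#'   report; `NULL` allowed).
#' @param n_trials Replicates (default `config$n_trials`).
#' @param base_seed Base seed (default `config$base_seed`).
#' @return A tibble, one row per complication x metric (cfr, incidence).
#' @export
calibration_report <- function(config, targets = NULL,
                               n_trials = config$n_trials,
                               base_seed = config$base_seed) {
  res <- run_trials(config, n_trials = n_trials, base_seed = base_seed)
  box <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(tibble::tibble(mean = NA_real_, median = NA_real_,
                            q1 = NA_real_, q3 = NA_real_,
                            whisker_low = NA_real_, whisker_high = NA_real_,
                            n_outliers = NA_integer_, n_trials_defined = 0L))
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    in_fence <- x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr
    tibble::tibble(mean = mean(x), median = q[2], q1 = q[1], q3 = q[3],
                   whisker_low = min(x[in_fence]),
                   whisker_high = max(x[in_fence]),
                   n_outliers = sum(!in_fence),
                   n_trials_defined = length(x))
  }
  pc <- res$per_complication
  out <- list()
  for (comp in unique(pc$complication)) {
    sub <- pc[pc$complication == comp, ]
    cfr <- dplyr::mutate(box(sub$cfr_pct), complication = comp,
                         metric = "cfr_pct",
                         target = unname((targets$cfr_pct %||% c())[comp] %|NA|%
                           NA_real_), .before = 1)
    inc <- dplyr::mutate(box(sub$incidence_pct), complication = comp,
                         metric = "incidence_pct",
                         target = unname((targets$incidence_pct %||% c())[comp] %|NA|%
                           NA_real_), .before = 1)
    out[[comp]] <- dplyr::bind_rows(cfr, inc)
  }
  dplyr::bind_rows(out)
}

`%|NA|%` <- function(x, y) if (is.null(x) || length(x) == 0) y else x
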