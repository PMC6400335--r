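#' Probability arithmetic for ward mortality dynamics
#'
#' The simulator tracks, for every potentially life-threatening complication a
#' patient carries, a probability of mortality on `[0, 1)` interpreted as the
#' chance the condition kills the patient over her remaining hospital stay.
#' The functions in this file are the closed-form pieces of that bookkeeping:
#' combining per-condition probabilities, rescaling a stay-long probability to
#' a single 15-minute cycle, geometric improvement under treatment, and
#' gamma-function deterioration in its absence.
#'
#' @name mortality-math
#' @keywords internal
NULL

check_prob <- function(p, what = "probability", allow_one = FALSE) {
  if (!is.numeric(p) || anyNA(p)) {
    stop(sprintf("`%s` must be numeric and non-missing", what), call. = FALSE)
  }
  hi_bad <- if (allow_one) any(p > 1) else any(p >= 1)
  if (any(p < 0) || hi_bad) {
    stop(sprintf("`%s` must lie in [0, 1%s", what,
                 if (allow_one) "]" else ")"), call. = FALSE)
  }
  invisible(p)
}

#' Composite probability of mortality across simultaneous conditions
#'
#' Combines per-condition mortality probabilities under the assumption that
#' each condition contributes independently to the patient's survival: the
#' patient survives only if she survives every condition, so
#' `p_c = 1 - prod(1 - p_k)`. An empty input (no complications) gives 0.
#'
#' @param p Numeric vector of per-condition mortality probabilities in `[0, 1)`.
#' @return A single probability in `[0, 1)`, at least `max(p)`.
#' @examples
#' composite_mortality(c(0.5, 0.5)) # 0.75
#' composite_mortality(numeric(0))  # 0
#' @export
composite_mortality <- function(p) {
  check_prob(p, "p")
  if (length(p) == 0L) return(0)
  # log1p form keeps precision when probabilities are tiny
  -expm1(sum(log1p(-p)))
}

#' Per-cycle mortality from a stay-long mortality probability
#'
#' A patient's composite probability of mortality `p_c` is her chance of dying
#' at some point during the `n` cycles left in her stay. The per-cycle hazard
#' `p` applied independently each cycle must satisfy `(1 - p)^n = 1 - p_c`,
#' giving `p = 1 - (1 - p_c)^(1/n)`.
#'
#' @param p_c Stay-long mortality probability in `[0, 1)`. Vectorised.
#' @param n_remaining Number of remaining cycles, a positive integer.
#' @return Per-cycle mortality probability.
#' @examples
#' scaled_cycle_mortality(0.75, 2) # 0.5
#' @export
scaled_cycle_mortality <- function(p_c, n_remaining) {
  check_prob(p_c, "p_c")
  if (any(n_remaining < 1) || any(n_remaining != floor(n_remaining))) {
    stop("`n_remaining` must be a positive integer", call. = FALSE)
  }
  -expm1(log1p(-p_c) / n_remaining)
}

#' One cycle of treatment: geometric decay of mortality probability
#'
#' Each treated cycle multiplies the condition's mortality probability by the
#' decay constant `(1 - efficacy)`: `p <- p * (1 - efficacy)`.
#'
#' @param p Mortality probability in `[0, 1)`. Vectorised.
#' @param efficacy Treatment efficacy in `[0, 1]`; 1 cures instantly, 0 holds
#'   the probability constant.
#' @return Updated probability `p * (1 - efficacy)`.
#' @examples
#' apply_treatment_cycle(0.4, 0.5) # 0.2
#' @export
apply_treatment_cycle <- function(p, efficacy) {
  check_prob(p, "p")
  check_prob(efficacy, "efficacy", allow_one = TRUE)
  p * (1 - efficacy)
}

#' Closed form for repeated treatment cycles
#'
#' After `cycles` consecutive treated cycles the probability equals
#' `p0 * (1 - efficacy)^cycles`, the closed form of iterating
#' [apply_treatment_cycle()].
#'
#' @param p0 Starting mortality probability in `[0, 1)`.
#' @param efficacy Treatment efficacy in `[0, 1]`.
#' @param cycles Non-negative integer count of treated cycles. Vectorised.
#' @return Probability after `cycles` treated cycles.
#' @examples
#' treatment_closed_form(0.4, 0.5, 3) # 0.05
#' @export
treatment_closed_form <- function(p0, efficacy, cycles) {
  check_prob(p0, "p0")
  check_prob(efficacy, "efficacy", allow_one = TRUE)
  if (any(cycles < 0) || any(cycles != floor(cycles))) {
    stop("`cycles` must be a non-negative integer", call. = FALSE)
  }
  # log1p avoids re-rounding (1 - efficacy); for efficacy = 1 the decay is
  # exact zero after any positive number of cycles
  out <- p0 * exp(cycles * log1p(-efficacy))
  ifelse(efficacy == 1 & cycles > 0, 0, ifelse(cycles == 0, p0, out))
}

#' One cycle of deterioration without treatment
#'
#' An untreated condition worsens each cycle as `p <- p^(rate / (rate + c))`
#' where `rate` is the complication's deterioration rate (larger = slower
#' worsening) and `c` counts consecutive untreated cycles, starting at 1 on
#' the first untreated cycle. Since the exponent is below 1 and `p < 1`, the
#' update is strictly increasing yet never reaches 1. A probability of exactly
#' 0 (the uncomplicated baseline) stays 0.
#'
#' @param p Mortality probability in `[0, 1)`. Vectorised.
#' @param rate Deterioration rate, a positive real.
#' @param untreated_cycles Count of consecutive untreated cycles including the
#'   current one; at least 1.
#' @return Worsened probability, still below 1.
#' @examples
#' apply_deterioration_cycle(0.5, 1, 1) # 0.5^(1/2)
#' @export
apply_deterioration_cycle <- function(p, rate, untreated_cycles) {
  check_prob(p, "p")
  if (any(rate <= 0)) stop("`rate` must be positive", call. = FALSE)
  if (any(untreated_cycles < 1)) {
    stop("`untreated_cycles` must be >= 1 for the current untreated cycle",
         call. = FALSE)
  }
  # clamp to the largest double below 1: the sequence approaches but never
  # attains 1, and downstream arithmetic requires p < 1
  pmin(p^(rate / (rate + untreated_cycles)), 1 - .Machine$double.eps / 2)
}

#' Closed form for repeated untreated cycles
#'
#' Composing the per-cycle update for `c = 1, ..., cycles` raises the starting
#' probability to the exponent
#' `prod(rate / (rate + c)) = rate^cycles * Gamma(rate + 1) / Gamma(rate + cycles + 1)`,
#' producing the sigmoidal rise of mortality probability toward (but never
#' reaching) 1. The exponent is evaluated in log-gamma space so large `cycles`
#' or `rate` do not overflow.
#'
#' @param p0 Mortality probability on the first untreated cycle, in `[0, 1)`.
#' @param rate Deterioration rate, positive.
#' @param cycles Non-negative integer count of untreated cycles. Vectorised.
#' @return Probability after `cycles` untreated cycles; equals `p0` at
#'   `cycles = 0` and tends to 1 as `cycles` grows (for `p0 > 0`).
#' @examples
#' deterioration_closed_form(0.5, 1, 2) # 0.5^(1/6)
#' @export
deterioration_closed_form <- function(p0, rate, cycles) {
  check_prob(p0, "p0")
  if (any(rate <= 0)) stop("`rate` must be positive", call. = FALSE)
  if (any(cycles < 0) || any(cycles != floor(cycles))) {
    stop("`cycles` must be a non-negative integer", call. = FALSE)
  }
  log_expo <- cycles * log(rate) + lgamma(rate + 1) - lgamma(rate + cycles + 1)
  pmin(p0^exp(log_expo), 1 - .Machine$double.eps / 2)
}

#' Sample admission severities from a truncated normal distribution
#'
#' Each complication's severity distribution is a normal distribution centred
#' on the complication's mean probability of mortality (its case fatality
#' rate), truncated to the unit interval so that draws are valid
#' probabilities. Sampling is by inverse CDF on the truncated quantile range:
#' exact, rejection-free, and reproducible under `set.seed()`.
#'
#' @param n Number of draws, or (when `u` is given) ignored.
#' @param mean Mean of the untruncated normal (per-complication case fatality
#'   rate).
#' @param sd Standard deviation of the untruncated normal; positive.
#' @param u Optional vector of uniforms in (0, 1) to transform; by default
#'   `n` fresh uniforms are drawn from the session RNG stream.
#' @return Numeric vector of severities strictly inside (0, 1).
#' @examples
#' set.seed(1)
#' sample_severity(3, mean = 0.1, sd = 0.05)
#' @export
sample_severity <- function(n, mean, sd, u = NULL) {
  if (any(sd <= 0)) stop("`sd` must be positive", call. = FALSE)
  if (is.null(u)) u <- stats::runif(n)
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  x <- stats::qnorm(lo + u * (hi - lo), mean, sd)
  # clamp away from the endpoints: probabilities of exactly 0/1 are reserved
  pmin(pmax(x, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' Standard deviation of a severity distribution from its SMO anchor
#'
#' The upper 2.5% tail of each severity distribution (two standard deviations
#' above the mean) is pinned to the probability of dying once classified as a
#' severe maternal outcome (SMO) patient, so `sd = (smo_mortality - mean) / 2`.
#'
#' @param mean Mean severity (case fatality rate), a probability.
#' @param smo_mortality Probability of death given SMO classification; must
#'   exceed `mean`.
#' @return The implied standard deviation.
#' @examples
#' derive_severity_sd(0.10, 0.30) # 0.10
#' @export
derive_severity_sd <- function(mean, smo_mortality) {
  check_prob(mean, "mean")
  check_prob(smo_mortality, "smo_mortality", allow_one = TRUE)
  if (any(smo_mortality <= mean)) {
    stop("`smo_mortality` must exceed `mean`: the SMO anchor sits two ",
         "standard deviations above the mean severity", call. = FALSE)
  }
  (smo_mortality - mean) / 2
}

#' Solve a treatment plan's efficacy from its duration
#'
#' Treatment efficacies are calibrated so that with complete, timely treatment
#' a condition's mean probability of mortality decays to a numerical floor
#' (default `1e-10`) by the end of the plan: solving
#' `mean_severity * (1 - efficacy)^duration = floor` gives
#' `efficacy = 1 - (floor / mean_severity)^(1/duration)`.
#'
#' @param mean_severity Mean severity (starting probability), above `floor`.
#' @param duration_cycles Plan duration in treated cycles, a positive integer.
#' @param floor Target probability at completion; default `1e-10`.
#' @return Efficacy in (0, 1).
#' @examples
#' calibrate_efficacy(0.1, 9) # 0.9
#' @export
calibrate_efficacy <- function(mean_severity, duration_cycles, floor = 1e-10) {
  check_prob(mean_severity, "mean_severity")
  if (any(floor <= 0) || any(floor >= mean_severity)) {
    stop("`floor` must satisfy 0 < floor < mean_severity", call. = FALSE)
  }
  if (any(duration_cycles < 1) || any(duration_cycles != trunc(duration_cycles))) {
    stop("`duration_cycles` must be a positive integer", call. = FALSE)
  }
  -expm1(log(floor / mean_severity) / duration_cycles)
}
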