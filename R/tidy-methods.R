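#' Broom-style accessors and plots
#'
#' `tidy()` returns the observation-level tibble of a result (per trial, per
#' cell x trial, per fitted rate), `glance()` the one-row summary, and
#' `autoplot()` a ggplot of the result's natural display.
#'
#' @name tidy-methods
NULL

#' @rdname tidy-methods
#' @param x A result object.
#' @param ... Unused.
#' @export
tidy.ward_trial <- function(x, ...) x$summary

#' @rdname tidy-methods
#' @export
glance.ward_trial <- function(x, ...) x$summary

#' @rdname tidy-methods
#' @export
tidy.ward_trials <- function(x, ...) x$summary

#' @rdname tidy-methods
#' @export
glance.ward_trials <- function(x, ...) x$aggregate

#' @rdname tidy-methods
#' @export
tidy.ward_sweep <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ward_sweep")
  attr(out, "summary") <- NULL
  attr(out, "kind") <- NULL
  attr(out, "comparisons") <- NULL
  out
}

#' @rdname tidy-methods
#' @export
glance.ward_sweep <- function(x, ...) attr(x, "summary")

#' @rdname tidy-methods
#' @export
tidy.ward_calibration <- function(x, ...) {
  x$rates[, c("complication", "lambda", "achieved_cfr_pct",
              "target_cfr_pct", "converged", "note")]
}

#' @rdname tidy-methods
#' @export
glance.ward_calibration <- function(x, ...) {
  tibble::tibble(
    n_complications = nrow(x$rates),
    n_converged = sum(x$rates$converged),
    n_evaluations = nrow(x$trace),
    mc_trials = x$targets$mc_trials,
    horizon_days = x$targets$horizon_days
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname tidy-methods
#' @param object A result object.
#' @export
autoplot.ward_trial <- function(object, ...) {
  if (is.null(object$trajectories)) {
    stop("trial was run without trajectories", call. = FALSE)
  }
  long <- tidyr::pivot_longer(object$trajectories, -"cycle",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$series), scales = "free_y") +
    ggplot2::labs(x = "cycle (15 min)", y = NULL,
                  title = sprintf("Ward trajectories (seed %d)", object$seed))
}

#' @rdname tidy-methods
#' @export
autoplot.ward_trials <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = "", y = .data$deaths)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "maternal deaths per trial",
                  title = sprintf("Deaths over %d trials",
                                  nrow(object$summary)))
}

#' @rdname tidy-methods
#' @export
autoplot.ward_sweep <- function(object, ...) {
  kind <- attr(object, "kind")
  s <- attr(object, "summary")
  switch(
    kind,
    medication = ggplot2::ggplot(
      s, ggplot2::aes(x = .data$stock, y = .data$deaths_mean,
                      colour = .data$restock)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "initial stock (packs)", y = "mean maternal deaths",
                    colour = "monthly restock",
                    title = paste("Medicine availability:",
                                  unique(s$drug))),
    staffing = ggplot2::ggplot(
      s, ggplot2::aes(x = .data$nurses, y = .data$doctors,
                      fill = .data$deaths_mean)) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = "nurses per shift", y = "doctors per shift",
                    fill = "mean deaths", title = "Staffing grid"),
    shifts = ggplot2::ggplot(
      object, ggplot2::aes(x = .data$pattern, y = .data$deaths)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = NULL, y = "maternal deaths per trial",
                    title = "Shift staffing patterns"),
    admission = ggplot2::ggplot(
      s, ggplot2::aes(x = .data$multiplier,
                      y = .data$mortality_rate_complicated_pct_mean)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "admission-rate multiplier",
                    y = "mortality rate, complicated patients (%)",
                    title = "Patient influx"),
    stop("unknown sweep kind: ", kind, call. = FALSE)
  )
}
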