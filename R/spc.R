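#' Control limits for a Shewhart-style chart
#'
#' @param center In-control mean of the charted statistic.
#' @param sigma In-control standard deviation (> 0).
#' @param multiplier Width of the limits in sigmas (default 3).
#'
#' @return An object of class `control_limits` with `lower`/`upper` fields.
#' @examples
#' control_limits(0.9, 0.02)
#' @export
control_limits <- function(center, sigma, multiplier = 3) {
  assert_scalar_number(center, "center")
  assert_scalar_number(sigma, "sigma")
  assert_scalar_number(multiplier, "multiplier")
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (multiplier <= 0) abort("`multiplier` must be positive.")
  structure(
    list(center = center, sigma = sigma, multiplier = multiplier,
         lower = center - multiplier * sigma,
         upper = center + multiplier * sigma),
    class = "control_limits"
  )
}

#' @export
print.control_limits <- function(x, ...) {
  cat(sprintf("<control_limits> center %.6g, sigma %.6g, [%.6g, %.6g] (%gσ)\n",
              x$center, x$sigma, x$lower, x$upper, x$multiplier))
  invisible(x)
}

#' Flag values outside the control limits
#'
#' A value is out of control iff it lies strictly beyond the limits; values
#' exactly on a limit are in control ("deviating beyond the range" means
#' exceedance, not contact).
#'
#' @param value Numeric vector of charted values (must be finite).
#' @param limits A [control_limits()] object.
#' @return A logical vector, `TRUE` where out of control.
#' @export
three_sigma_flag <- function(value, limits) {
  stopifnot(inherits(limits, "control_limits"))
  if (!is.numeric(value) || any(!is.finite(value))) {
    abort("`value` must be finite.")
  }
  value < limits$lower | value > limits$upper
}

#' Two-of-three run rule at the 2-sigma limits
#'
#' Supplementary sensitivity rule: signals when at least two of three
#' consecutive chart values fall beyond the same-side 2-sigma limit (derived
#' from the limits' center and sigma regardless of the chart's own
#' multiplier).
#'
#' @param values Exactly three consecutive chart values.
#' @param limits A [control_limits()] object.
#' @return `TRUE` if the rule fires.
#' @export
run_rule_two_of_three <- function(values, limits) {
  stopifnot(inherits(limits, "control_limits"))
  if (length(values) != 3L || any(!is.finite(values))) {
    abort("`values` must be exactly three finite chart values.")
  }
  hi <- limits$center + 2 * limits$sigma
  lo <- limits$center - 2 * limits$sigma
  sum(values > hi) >= 2L || sum(values < lo) >= 2L
}

#' CUSUM parameters
#'
#' Tabular CUSUM for the charted statistic: allowance `k` (slack per step,
#' default `sigma / 2`) and decision interval `h` (alarm threshold, default
#' `4 * sigma`). Larger `k`/`h` trade detection delay for fewer false alarms.
#'
#' @param mu0 In-control mean of the charted statistic.
#' @param sigma In-control standard deviation (> 0).
#' @param k Allowance (>= 0).
#' @param h Decision interval (> 0).
#' @return An object of class `cusum_params`.
#' @export
cusum_params <- function(mu0, sigma, k = sigma / 2, h = 4 * sigma) {
  assert_scalar_number(mu0, "mu0")
  assert_scalar_number(sigma, "sigma")
  assert_scalar_number(k, "k")
  assert_scalar_number(h, "h")
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (k < 0) abort("`k` must be >= 0.")
  if (h <= 0) abort("`h` must be positive.")
  structure(list(mu0 = mu0, sigma = sigma, k = k, h = h),
            class = "cusum_params")
}

#' @export
print.cusum_params <- function(x, ...) {
  cat(sprintf("<cusum_params> mu0 %.6g, sigma %.6g, k %.6g, h %.6g\n",
              x$mu0, x$sigma, x$k, x$h))
  invisible(x)
}

#' Fresh CUSUM state
#'
#' @return A `cusum_state` with both cumulative sums at zero.
#' @export
cusum_state <- function() {
  structure(list(s_plus = 0, s_minus = 0, step_index = 0L,
                 alarm_high = FALSE, alarm_low = FALSE),
            class = "cusum_state")
}

#' One CUSUM step
#'
#' Applies the tabular CUSUM recursion to one observation `x`:
#' `S+ <- max(0, S+ + x - mu0 - k)` and `S- <- min(0, S- + x - mu0 + k)`.
#' The high-side alarm fires when `S+ > h`; since `S-` is kept non-positive,
#' the low-side alarm fires when `|S-| > h` (the low-side signal crossing the
#' negative threshold `-h`).
#'
#' @param state A `cusum_state`.
#' @param x Observed value (finite).
#' @param params A [cusum_params()] object.
#' @return The updated `cusum_state`.
#' @examples
#' p <- cusum_params(mu0 = 0, sigma = 1)
#' cusum_update(cusum_state(), 2, p)
#' @export
cusum_update <- function(state, x, params) {
  stopifnot(inherits(state, "cusum_state"), inherits(params, "cusum_params"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort("`x` must be a single finite value.")
  }
  state$s_plus <- max(0, state$s_plus + x - params$mu0 - params$k)
  state$s_minus <- min(0, state$s_minus + x - params$mu0 + params$k)
  state$step_index <- state$step_index + 1L
  state$alarm_high <- state$s_plus > params$h
  state$alarm_low <- abs(state$s_minus) > params$h
  state
}

#' Run a CUSUM chart over a whole series
#'
#' Folds [cusum_update()] over the series from the zero state. The state is
#' not reset after an alarm, so a sustained shift keeps signalling; all alarm
#' steps are reported.
#'
#' @param series Nonempty numeric vector of charted values.
#' @param params A [cusum_params()] object.
#' @return A tibble of class `cusum_run` with columns `step`, `x`, `s_plus`,
#'   `s_minus`, `alarm_high`, `alarm_low`, `alarm`; the parameters and the
#'   alarm step indices are attached as attributes `params` / `alarm_steps`.
#' @export
cusum_run <- function(series, params) {
  stopifnot(inherits(params, "cusum_params"))
  if (length(series) == 0L) abort("`series` must be nonempty.")
  if (any(!is.finite(series))) abort("`series` must be finite.")
  n <- length(series)
  s_plus <- numeric(n)
  s_minus <- numeric(n)
  sp <- 0
  sm <- 0
  for (i in seq_len(n)) {
    sp <- max(0, sp + series[i] - params$mu0 - params$k)
    sm <- min(0, sm + series[i] - params$mu0 + params$k)
    s_plus[i] <- sp
    s_minus[i] <- sm
  }
  out <- tibble::tibble(
    step = seq_len(n), x = as.numeric(series),
    s_plus = s_plus, s_minus = s_minus,
    alarm_high = s_plus > params$h,
    alarm_low = abs(s_minus) > params$h
  )
  out$alarm <- out$alarm_high | out$alarm_low
  structure(out, params = params, alarm_steps = out$step[out$alarm],
            class = c("cusum_run", class(out)))
}

#' @export
tidy.cusum_run <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.cusum_run <- function(x, ...) {
  steps <- attr(x, "alarm_steps")
  p <- attr(x, "params")
  tibble::tibble(
    n_steps = nrow(x),
    n_alarms = length(steps),
    first_alarm_step = if (length(steps)) steps[1L] else NA_integer_,
    k = p$k, h = p$h, mu0 = p$mu0, sigma = p$sigma
  )
}

#' Write a chart trajectory with a JSON parameter sidecar
#'
#' @param run A [cusum_run()] result.
#' @param path CSV path; parameters are echoed to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_chart_csv <- function(run, path) {
  readr::write_csv(tibble::as_tibble(run), path)
  p <- attr(run, "params")
  if (!is.null(p)) {
    jsonlite::write_json(unclass(p), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
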