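#' Aggregate a scored stream into a daily metric series
#'
#' Each day's batch is summarized by the arithmetic mean of the per-image OOD
#' metric, so the whole day is charted as a single value; the per-image table
#' is retained as an attribute.
#'
#' @param scored A scored stream tibble (with `day` and `metric` columns).
#' @param allow_gaps If `FALSE` (default), a missing day inside the monitored
#'   range is an error; set `TRUE` for deliberately sparse streams.
#'
#' @return A tibble of class `metric_series` with columns `day`,
#'   `daily_mean`, `n_images`.
#' @export
daily_aggregate <- function(scored, allow_gaps = FALSE) {
  if (!all(c("day", "metric") %in% names(scored))) {
    abort("`scored` must have `day` and `metric` columns.")
  }
  if (nrow(scored) == 0L) abort("`scored` has no records.")
  if (any(!is.finite(scored$metric))) abort("`metric` must be finite.")
  daily <- scored |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(daily_mean = mean(.data$metric),
                     n_images = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$day)
  full <- seq(min(daily$day), max(daily$day))
  if (!allow_gaps && !identical(as.integer(daily$day), as.integer(full))) {
    missing_days <- setdiff(full, daily$day)
    abort(sprintf(
      "day(s) %s have zero records; days must be contiguous (or pass allow_gaps = TRUE).",
      paste(head(missing_days, 5L), collapse = ", ")))
  }
  structure(daily, per_image = scored,
            class = c("metric_series", class(daily)))
}

#' Monitor a stream: per-image 3σ flags, daily chart, CUSUM drift detection
#'
#' Runs the full monitoring pipeline against a fitted reference profile:
#' (1) each image's OOD metric is flagged against the profile's
#' `metric_mean ± multiplier * metric_std` limits; (2) daily mean metrics are
#' charted against the same per-image limits (the default; pass
#' `tighten_daily_limits = TRUE` to shrink sigma by `sqrt(batch)` for the
#' daily chart); (3) a CUSUM over the daily means detects sustained drift.
#'
#' `cusum_scale` sets the sigma in which the CUSUM allowance `k` and decision
#' interval `h` are expressed: `"per-image"` (default) uses the profile's raw
#' per-image `metric_std`, so defaults `k = σ/2`, `h = 4σ` tolerate sporadic
#' single-digit OOD percentages while flagging sustained contamination;
#' `"daily-mean"` divides by `sqrt(batch_size)`, making `k`, `h` multiples of
#' the daily mean's own in-control standard deviation (far more sensitive).
#'
#' @param stream A stream tibble; either already scored (has a `metric`
#'   column) or raw with feature columns, in which case it is scored against
#'   `profile` first.
#' @param profile A [fit_reference()] profile with `metric_std > 0`.
#' @param multiplier Control-limit width in sigmas (default 3).
#' @param cusum_scale `"per-image"` or `"daily-mean"` (see above).
#' @param k,h CUSUM allowance and decision interval in the chosen sigma scale
#'   as factors: defaults `k_factor = 0.5`, `h_factor = 4`.
#' @param k_factor,h_factor Numeric factors multiplying the chart sigma.
#' @param tighten_daily_limits Use `sqrt(batch)`-tightened limits for the
#'   daily 3σ chart.
#' @param allow_gaps Passed to [daily_aggregate()].
#'
#' @return An object of class `monitor_report`: a list with `per_image`
#'   (tibble with `flagged`), `daily` (tibble with daily mean, 3σ flag and
#'   CUSUM columns plus `alarm_side`), `image_limits`, `daily_limits`,
#'   `cusum` ([cusum_run()] result), `cusum_alarm_days`, `first_alarm_day`
#'   and `config`.
#' @examples
#' sc <- ct_drift_scenario(seed = 1)
#' ref <- sample_cluster(sc$id_cluster, n = 1000, seed = 99)
#' prof <- fit_reference(ref, metric = "cosine")
#' rep <- monitor_stream(generate_stream(sc), prof)
#' rep$first_alarm_day
#' @export
monitor_stream <- function(stream, profile, multiplier = 3,
                           cusum_scale = c("per-image", "daily-mean"),
                           k_factor = 0.5, h_factor = 4,
                           tighten_daily_limits = FALSE,
                           allow_gaps = FALSE) {
  stopifnot(inherits(profile, "ref_profile"))
  cusum_scale <- match.arg(cusum_scale)
  if (!is.finite(profile$metric_std) || profile$metric_std <= 0) {
    abort("profile has non-positive metric_std; control limits undefined.")
  }
  scored <- if ("metric" %in% names(stream)) stream else
    score_stream(stream, profile)
  image_limits <- control_limits(profile$metric_mean, profile$metric_std,
                                 multiplier)
  per_image <- dplyr::mutate(
    scored, flagged = three_sigma_flag(.data$metric, image_limits))
  daily <- daily_aggregate(scored, allow_gaps = allow_gaps)
  batch <- stats::median(daily$n_images)
  daily_limits <- if (tighten_daily_limits) {
    control_limits(profile$metric_mean,
                   profile$metric_std / sqrt(batch), multiplier)
  } else {
    image_limits
  }
  sigma_chart <- switch(cusum_scale,
                        "per-image" = profile$metric_std,
                        "daily-mean" = profile$metric_std / sqrt(batch))
  params <- cusum_params(mu0 = profile$metric_mean, sigma = sigma_chart,
                         k = k_factor * sigma_chart,
                         h = h_factor * sigma_chart)
  cus <- cusum_run(daily$daily_mean, params)
  daily_out <- daily |>
    dplyr::mutate(
      flagged = three_sigma_flag(.data$daily_mean, daily_limits),
      s_plus = cus$s_plus, s_minus = cus$s_minus,
      alarm_high = cus$alarm_high, alarm_low = cus$alarm_low,
      alarm = cus$alarm,
      alarm_side = dplyr::case_when(
        cus$alarm_high & cus$alarm_low ~ "both",
        cus$alarm_high ~ "high",
        cus$alarm_low ~ "low",
        TRUE ~ NA_character_
      )
    )
  alarm_days <- daily_out$day[daily_out$alarm]
  structure(
    list(
      per_image = per_image,
      daily = daily_out,
      image_limits = image_limits,
      daily_limits = daily_limits,
      cusum = cus,
      cusum_alarm_days = alarm_days,
      first_alarm_day = if (length(alarm_days)) min(alarm_days) else
        NA_integer_,
      config = list(metric_name = profile$metric_name,
                    multiplier = multiplier, cusum_scale = cusum_scale,
                    k_factor = k_factor, h_factor = h_factor, k = params$k,
                    h = params$h, mu0 = params$mu0, sigma = params$sigma,
                    tighten_daily_limits = tighten_daily_limits,
                    batch_size = batch)
    ),
    class = "monitor_report"
  )
}

#' @export
print.monitor_report <- function(x, ...) {
  cat(sprintf(
    "<monitor_report> %d days, %d images, metric %s\n",
    nrow(x$daily), nrow(x$per_image), x$config$metric_name))
  cat(sprintf("  per-image flags: %d (%.3f%%)\n", sum(x$per_image$flagged),
              100 * mean(x$per_image$flagged)))
  cat(sprintf("  daily 3σ flags: %s\n",
              paste(x$daily$day[x$daily$flagged], collapse = ", ")))
  cat(sprintf("  CUSUM alarm days: %s (first: %s)\n",
              paste(x$cusum_alarm_days, collapse = ", "),
              x$first_alarm_day))
  invisible(x)
}

#' @export
glance.monitor_report <- function(x, ...) {
  tibble::tibble(
    n_days = nrow(x$daily),
    n_images = nrow(x$per_image),
    image_flag_rate = mean(x$per_image$flagged),
    n_daily_flags = sum(x$daily$flagged),
    n_cusum_alarms = length(x$cusum_alarm_days),
    first_alarm_day = x$first_alarm_day
  )
}

#' @export
tidy.monitor_report <- function(x, ...) {
  x$daily
}

#' Detection delay of a monitor report relative to a known shift day
#'
#' The delay is `first alarm on/after shift_day - shift_day`; alarms strictly
#' before the shift are false alarms and are reported separately. When no
#' alarm occurs on/after the shift, the delay is `NA` (a missed detection).
#'
#' @param report A [monitor_stream()] report.
#' @param shift_day First day of the drifted regime.
#' @return A one-row tibble: `shift_day`, `first_alarm_day`, `delay`,
#'   `n_false_alarms`, and list-column `false_alarm_days`.
#' @export
detection_delay <- function(report, shift_day) {
  stopifnot(inherits(report, "monitor_report"))
  days <- report$daily$day
  if (shift_day < min(days) || shift_day > max(days)) {
    abort("`shift_day` must lie within the monitored range.")
  }
  alarms <- report$cusum_alarm_days
  false_alarms <- alarms[alarms < shift_day]
  post <- alarms[alarms >= shift_day]
  tibble::tibble(
    shift_day = as.integer(shift_day),
    first_alarm_day = if (length(post)) as.integer(post[1L]) else NA_integer_,
    delay = if (length(post)) as.integer(post[1L] - shift_day) else
      NA_integer_,
    n_false_alarms = length(false_alarms),
    false_alarm_days = list(as.integer(false_alarms))
  )
}

#' Write a monitor report to JSON plus chart CSVs
#'
#' @param report A [monitor_stream()] report.
#' @param path JSON path for the report summary; per-image and daily chart
#'   CSVs are written alongside with suffixes `-images.csv` / `-daily.csv`.
#' @return `path`, invisibly.
#' @export
write_monitor_report <- function(report, path) {
  stopifnot(inherits(report, "monitor_report"))
  stem <- sub("\\.json$", "", path)
  readr::write_csv(report$per_image, paste0(stem, "-images.csv"))
  readr::write_csv(report$daily, paste0(stem, "-daily.csv"))
  obj <- list(
    config = report$config,
    image_limits = unclass(report$image_limits),
    daily_limits = unclass(report$daily_limits),
    daily_three_sigma_flag_days = report$daily$day[report$daily$flagged],
    cusum_alarm_days = report$cusum_alarm_days,
    first_alarm_day = report$first_alarm_day,
    n_image_flags = sum(report$per_image$flagged),
    image_flag_rate = mean(report$per_image$flagged)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
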