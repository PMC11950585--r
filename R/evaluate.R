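#' Confusion statistics for OOD flags against ground truth
#'
#' Sensitivity is the fraction of truly OOD images that were flagged;
#' specificity the fraction of truly in-distribution images left unflagged.
#'
#' @param data A data frame holding flags and truth labels (e.g. the
#'   `per_image` table of a [monitor_stream()] report).
#' @param flag_col,truth_col Column names (flag logical; truth `"ID"`/`"OOD"`).
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`,
#'   `n_ood`, `n_id`.
#' @examples
#' confusion_stats(tibble::tibble(
#'   flagged = c(TRUE, FALSE, FALSE, TRUE),
#'   truth_label = c("OOD", "OOD", "ID", "ID")))
#' @export
confusion_stats <- function(data, flag_col = "flagged",
                            truth_col = "truth_label") {
  flags <- data[[flag_col]]
  truth <- data[[truth_col]]
  if (is.null(flags) || is.null(truth)) {
    abort(sprintf("`data` must have `%s` and `%s` columns.",
                  flag_col, truth_col))
  }
  if (length(flags) != length(truth)) {
    abort("flags and truth labels must have equal length.")
  }
  is_ood <- as.character(truth) == "OOD"
  if (!any(is_ood)) abort("no OOD truth labels: sensitivity undefined.")
  if (all(is_ood)) abort("no ID truth labels: specificity undefined.")
  flags <- as.logical(flags)
  tibble::tibble(
    sensitivity = mean(flags[is_ood]),
    specificity = mean(!flags[!is_ood]),
    accuracy = mean(flags == is_ood),
    n_ood = sum(is_ood),
    n_id = sum(!is_ood)
  )
}

#' Bootstrap confidence intervals for detection performance
#'
#' Replicates the evaluation protocol of drawing `n_bootstrap` subsets of
#' size `subset_size` uniformly with replacement, computing sensitivity,
#' specificity and accuracy on each, and reporting the 2.5/97.5 percentile
#' interval around the full-population point estimates. A replicate missing
#' a truth class is redrawn (counted; at most 10 attempts per replicate).
#'
#' @inheritParams confusion_stats
#' @param n_bootstrap Number of bootstrap replicates (default 100).
#' @param subset_size Images per replicate (default 500; clipped with a
#'   warning if larger than the population).
#' @param seed Integer seed; the report is reproducible from it.
#' @return An object of class `detection_report`.
#' @export
bootstrap_ci <- function(data, n_bootstrap = 100L, subset_size = 500L,
                         seed = 1L, flag_col = "flagged",
                         truth_col = "truth_label") {
  point <- confusion_stats(data, flag_col, truth_col)
  n <- nrow(data)
  if (subset_size > n) {
    warn(sprintf("subset_size %d exceeds population %d; clipping.",
                 subset_size, n))
    subset_size <- n
  }
  is_ood <- as.character(data[[truth_col]]) == "OOD"
  flags <- as.logical(data[[flag_col]])
  n_redraws <- 0L
  reps <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(n_bootstrap), function(b) {
      for (attempt in seq_len(10L)) {
        idx <- sample.int(n, subset_size, replace = TRUE)
        if (any(is_ood[idx]) && !all(is_ood[idx])) {
          if (attempt > 1L) n_redraws <<- n_redraws + (attempt - 1L)
          o <- is_ood[idx]
          f <- flags[idx]
          return(c(sensitivity = mean(f[o]), specificity = mean(!f[!o]),
                   accuracy = mean(f == o)))
        }
      }
      abort("replicate kept missing a truth class after 10 attempts.")
    })
  })
  boot <- do.call(rbind, reps)
  ci <- apply(boot, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(
    list(
      estimates = tibble::tibble(
        statistic = c("sensitivity", "specificity", "accuracy"),
        estimate = c(point$sensitivity, point$specificity, point$accuracy),
        ci_low = unname(ci[1L, ]), ci_high = unname(ci[2L, ])
      ),
      replicates = tibble::as_tibble(as.data.frame(boot)),
      n_bootstrap = as.integer(n_bootstrap),
      subset_size = as.integer(subset_size),
      n_population = n, n_redraws = n_redraws, seed = as.integer(seed)
    ),
    class = "detection_report"
  )
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> n=%d bootstrap over subsets of %d (pop %d)\n",
              x$n_bootstrap, x$subset_size, x$n_population))
  e <- x$estimates
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-12s %.3f [%.3f-%.3f]\n", e$statistic[i], e$estimate[i],
                e$ci_low[i], e$ci_high[i]))
  }
  invisible(x)
}

#' @export
tidy.detection_report <- function(x, ...) {
  x$estimates
}

#' @export
glance.detection_report <- function(x, ...) {
  e <- x$estimates
  tibble::tibble(
    sensitivity = e$estimate[e$statistic == "sensitivity"],
    specificity = e$estimate[e$statistic == "specificity"],
    accuracy = e$estimate[e$statistic == "accuracy"],
    n_bootstrap = x$n_bootstrap, subset_size = x$subset_size,
    n_redraws = x$n_redraws
  )
}

#' Write a detection report as JSON
#' @param report A [bootstrap_ci()] report.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_detection_report <- function(report, path) {
  stopifnot(inherits(report, "detection_report"))
  jsonlite::write_json(
    list(estimates = report$estimates, n_bootstrap = report$n_bootstrap,
         subset_size = report$subset_size, n_population = report$n_population,
         n_redraws = report$n_redraws, seed = report$seed),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Sensitivity at a matched specificity
#'
#' Thresholds the per-image metric at the quantile of the ID score
#' distribution achieving the requested specificity and reports the fraction
#' of OOD scores beyond it. `direction = "low"` treats low scores as OOD
#' (cosine similarity); `"high"` treats high scores as OOD (Mahalanobis).
#'
#' @param id_scores,ood_scores Per-image metric values by truth class.
#' @param specificity Target specificity in (0, 1).
#' @param direction `"low"` or `"high"`.
#' @return Sensitivity at the matched operating point.
#' @export
sensitivity_at_specificity <- function(id_scores, ood_scores,
                                       specificity = 0.9,
                                       direction = c("low", "high")) {
  direction <- match.arg(direction)
  if (specificity <= 0 || specificity >= 1) {
    abort("`specificity` must be in (0, 1).")
  }
  if (direction == "low") {
    thr <- quantile(id_scores, 1 - specificity, names = FALSE, type = 7)
    mean(ood_scores < thr)
  } else {
    thr <- quantile(id_scores, specificity, names = FALSE, type = 7)
    mean(ood_scores > thr)
  }
}

#' Sweep CUSUM parameters over replicated drift scenarios
#'
#' For each parameter setting, runs `n_replicates` seeded end-to-end
#' simulations of the scenario (fresh reference fit, stream generation,
#' monitoring) and tabulates the median detection delay, the miss rate and
#' the pre-shift false-alarm probability. Replicate seeds are shared across
#' settings, so the comparison between settings is paired.
#'
#' @param scenario A [drift_scenario()] template; the sweep re-seeds it per
#'   replicate. The shift day is the start of the last phase.
#' @param grid A data frame of settings with columns among `k_factor`,
#'   `h_factor` (missing columns take the defaults 0.5 / 4).
#' @param n_replicates Replicates per setting.
#' @param n_reference In-distribution images used to fit each replicate's
#'   reference profile.
#' @param metric `"cosine"` or `"mahalanobis"`.
#' @param seed Integer master seed.
#' @param cusum_scale Passed to [monitor_stream()].
#' @return A tibble with one row per setting: the grid columns plus
#'   `median_delay`, `miss_rate`, `preshift_false_alarm_rate`,
#'   `n_replicates`.
#' @export
scenario_sweep <- function(scenario, grid = tibble::tibble(k_factor = 0.5),
                           n_replicates = 20L, n_reference = 2000L,
                           metric = c("cosine", "mahalanobis"), seed = 1L,
                           cusum_scale = "per-image") {
  stopifnot(inherits(scenario, "drift_scenario"))
  metric <- match.arg(metric)
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0L) abort("`grid` must be nonempty.")
  if (!"k_factor" %in% names(grid)) grid$k_factor <- 0.5
  if (!"h_factor" %in% names(grid)) grid$h_factor <- 4
  shift_day <- max(scenario$phases$start_day)
  replicate_inputs <- purrr::map(seq_len(n_replicates), function(r) {
    sc <- scenario
    sc$seed <- derive_seed(seed, r)
    ref <- sample_cluster(sc$id_cluster, n_reference,
                          seed = derive_seed(seed, 100000 + r))
    list(stream = generate_stream(sc),
         profile = fit_reference(ref, metric = metric))
  })
  purrr::pmap_dfr(grid, function(k_factor, h_factor, ...) {
    res <- purrr::map_dfr(replicate_inputs, function(inp) {
      rep <- monitor_stream(inp$stream, inp$profile,
                            cusum_scale = cusum_scale,
                            k_factor = k_factor, h_factor = h_factor)
      detection_delay(rep, shift_day)
    })
    tibble::tibble(
      k_factor = k_factor, h_factor = h_factor,
      median_delay = if (all(is.na(res$delay))) NA_real_ else
        median(res$delay, na.rm = TRUE),
      miss_rate = mean(is.na(res$delay)),
      preshift_false_alarm_rate = mean(res$n_false_alarms > 0),
      n_replicates = as.integer(n_replicates)
    )
  })
}
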