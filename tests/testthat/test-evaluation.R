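test_that("confusion statistics match the 2x2 table", {
  perfect <- tibble::tibble(flagged = c(TRUE, TRUE, FALSE),
                            truth_label = c("OOD", "OOD", "ID"))
  expect_equal(unlist(confusion_stats(perfect)[1:3]),
               c(sensitivity = 1, specificity = 1, accuracy = 1))

  all_flagged <- tibble::tibble(flagged = TRUE,
                                truth_label = c("OOD", "ID"))
  cs <- confusion_stats(all_flagged)
  expect_equal(cs$sensitivity, 1)
  expect_equal(cs$specificity, 0)

  mixed <- tibble::tibble(flagged = c(TRUE, FALSE, FALSE, TRUE),
                          truth_label = c("OOD", "OOD", "ID", "ID"))
  expect_equal(unlist(confusion_stats(mixed)[1:3]),
               c(sensitivity = 0.5, specificity = 0.5, accuracy = 0.5))

  expect_error(confusion_stats(tibble::tibble(flagged = TRUE,
                                              truth_label = "ID")),
               "OOD")
  expect_error(confusion_stats(tibble::tibble(flagged = TRUE,
                                              truth_label = "OOD")),
               "ID")

  # random pairs vs an exhaustive count oracle
  set.seed(20)
  for (r in 1:20) {
    n <- 50
    d <- tibble::tibble(flagged = runif(n) < 0.4,
                        truth_label = ifelse(runif(n) < 0.5, "OOD", "ID"))
    if (length(unique(d$truth_label)) < 2) next
    cs <- confusion_stats(d)
    tp <- sum(d$flagged & d$truth_label == "OOD")
    fn <- sum(!d$flagged & d$truth_label == "OOD")
    tn <- sum(!d$flagged & d$truth_label == "ID")
    fp <- sum(d$flagged & d$truth_label == "ID")
    expect_equal(cs$sensitivity, tp / (tp + fn))
    expect_equal(cs$specificity, tn / (tn + fp))
    expect_equal(cs$accuracy, (tp + tn) / n)
  }
})

test_that("bootstrap reports are reproducible and degenerate-safe", {
  pop <- tibble::tibble(
    truth_label = rep(c("OOD", "ID"), each = 400),
    flagged = rep(c(TRUE, FALSE), each = 400))
  rep1 <- bootstrap_ci(pop, n_bootstrap = 50, subset_size = 100, seed = 3)
  expect_equal(rep1$estimates$ci_low, c(1, 1, 1))
  expect_equal(rep1$estimates$ci_high, c(1, 1, 1))

  rep2 <- bootstrap_ci(pop, n_bootstrap = 50, subset_size = 100, seed = 3)
  expect_identical(rep1$estimates, rep2$estimates)

  expect_warning(bootstrap_ci(pop, n_bootstrap = 5, subset_size = 5000,
                              seed = 1), "clipping")

  t <- tidy(rep1)
  expect_equal(t$statistic, c("sensitivity", "specificity", "accuracy"))
  expect_true(all(t$ci_low <= t$estimate & t$estimate <= t$ci_high))
})

test_that("bootstrap CIs shrink with subset size and cover known rates", {
  # deterministic population: sensitivity 0.9, specificity 0.8 exactly
  n_ood <- 3000
  n_id <- 7000
  pop <- tibble::tibble(
    truth_label = c(rep("OOD", n_ood), rep("ID", n_id)),
    flagged = c(rep(c(TRUE, FALSE), c(0.9 * n_ood, 0.1 * n_ood)),
                rep(c(TRUE, FALSE), c(0.2 * n_id, 0.8 * n_id))))

  width <- function(subset_size, seed) {
    e <- bootstrap_ci(pop, n_bootstrap = 60, subset_size = subset_size,
                      seed = seed)$estimates
    mean(e$ci_high - e$ci_low)
  }
  expect_lt(width(5000, 5), width(500, 5))

  covered <- vapply(1:50, function(s) {
    e <- bootstrap_ci(pop, n_bootstrap = 100, subset_size = 500,
                      seed = s)$estimates
    sens <- e[e$statistic == "sensitivity", ]
    spec <- e[e$statistic == "specificity", ]
    sens$ci_low <= 0.9 && 0.9 <= sens$ci_high &&
      spec$ci_low <= 0.8 && 0.8 <= spec$ci_high
  }, logical(1))
  expect_gte(sum(covered), 44)
})

test_that("sensitivity at matched specificity thresholds correctly", {
  id <- seq(0, 1, length.out = 101)    # uniform grid of ID scores
  ood <- rep(0.05, 50)
  expect_equal(sensitivity_at_specificity(id, ood, 0.9, "low"), 1)
  expect_equal(sensitivity_at_specificity(id, ood, 0.99, "low"), 0)
  expect_error(sensitivity_at_specificity(id, ood, 1.5), "specificity")
})

test_that("scenario_sweep tabulates delay, misses and false alarms", {
  sc <- tiny_scenario(seed = 1, n_days = 12, batch = 40)
  sc$phases <- tibble::tibble(start_day = c(1L, 7L), end_day = c(6L, 12L),
                              rate_low = c(0, 0.1), rate_high = c(0, 0.15))
  res <- scenario_sweep(sc, grid = tibble::tibble(k_factor = 0.5),
                        n_replicates = 5, n_reference = 400, seed = 2)
  expect_equal(nrow(res), 1L)
  expect_true(is.finite(res$median_delay))
  expect_true(res$miss_rate >= 0 && res$miss_rate <= 1)
  expect_true(res$preshift_false_alarm_rate >= 0 &&
                res$preshift_false_alarm_rate <= 1)

  res_k <- scenario_sweep(sc,
                          grid = tibble::tibble(k_factor = c(0.25, 0.5, 1)),
                          n_replicates = 8, n_reference = 400, seed = 3)
  # paired replicates: alarms can only get rarer / later as k grows
  expect_true(all(diff(res_k$preshift_false_alarm_rate) <= 0))
  delays <- res_k$median_delay
  expect_true(all(diff(delays[!is.na(delays)]) >= 0))
})
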