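scored_fixture <- function(seed = 1L, n_days = 5L, batch = 20L) {
  sc <- tiny_scenario(seed = seed, n_days = n_days, batch = batch)
  prof <- fit_reference(sample_cluster(sc$id_cluster, 400, seed = 99),
                        metric = "cosine")
  list(scored = score_stream(generate_stream(sc), prof), profile = prof)
}

test_that("daily aggregation is the groupwise mean", {
  one_day <- tibble::tibble(day = c(1L, 1L), metric = c(0.8, 1.0))
  expect_equal(daily_aggregate(one_day)$daily_mean, 0.9)

  const <- tibble::tibble(day = rep(1:3, each = 4), metric = 0.7)
  expect_equal(daily_aggregate(const)$daily_mean, rep(0.7, 3))

  fx <- scored_fixture()
  agg <- daily_aggregate(fx$scored)
  oracle <- tapply(fx$scored$metric, fx$scored$day, mean)
  expect_equal(agg$daily_mean, as.numeric(oracle[as.character(agg$day)]))
  expect_equal(agg$n_images, rep(20L, 5))

  gappy <- tibble::tibble(day = c(1L, 3L), metric = c(0.5, 0.6))
  expect_error(daily_aggregate(gappy), "zero records")
  expect_equal(nrow(daily_aggregate(gappy, allow_gaps = TRUE)), 2L)
})

test_that("monitoring decomposes into independent per-record flags", {
  fx <- scored_fixture(seed = 3)
  report <- monitor_stream(fx$scored, fx$profile)
  lim <- control_limits(fx$profile$metric_mean, fx$profile$metric_std, 3)
  expect_identical(report$per_image$flagged,
                   three_sigma_flag(fx$scored$metric, lim))
})

test_that("a stream at the reference mean vector never flags", {
  prof <- fit_reference(sample_cluster(cluster_spec(4, mean = 3), 400,
                                       seed = 4), metric = "cosine")
  mu <- prof$mean_vector
  stream <- tibble::tibble(day = rep(1:3, each = 5),
                           image_id = sprintf("i%02d", 1:15),
                           f0 = mu[1], f1 = mu[2], f2 = mu[3], f3 = mu[4])
  report <- monitor_stream(stream, prof)
  expect_equal(sum(report$per_image$flagged), 0L)
  expect_equal(sum(report$daily$flagged), 0L)
  expect_equal(length(report$cusum_alarm_days), 0L)
  expect_true(is.na(report$first_alarm_day))
})

test_that("pure in-distribution streams stay in control", {
  alarms <- vapply(1:20, function(r) {
    sc <- tiny_scenario(seed = r, n_days = 20, batch = 50)
    prof <- fit_reference(sample_cluster(sc$id_cluster, 1000,
                                         seed = 1000 + r), "cosine")
    report <- monitor_stream(generate_stream(sc), prof)
    length(report$cusum_alarm_days) > 0
  }, logical(1))
  expect_lte(sum(alarms), 1)
})

test_that("the CT-analogue drift is caught low-side shortly after day 31", {
  sc <- ct_drift_scenario(seed = 1)
  prof <- fit_reference(sample_cluster(sc$id_cluster, 2000, seed = 77),
                        metric = "cosine")
  report <- monitor_stream(generate_stream(sc), prof)
  expect_gte(report$first_alarm_day, 31L)
  expect_lte(report$first_alarm_day, 36L)
  first <- report$daily[report$daily$day == report$first_alarm_day, ]
  expect_equal(first$alarm_side, "low")
  # daily averaging obscures the shift on the plain 3-sigma chart
  expect_lt(sum(report$daily$flagged), 5L)
})

test_that("cusum scale conventions set the chart sigma as documented", {
  fx <- scored_fixture(seed = 5)
  raw <- monitor_stream(fx$scored, fx$profile, cusum_scale = "per-image")
  expect_equal(raw$config$sigma, fx$profile$metric_std)
  scaled <- monitor_stream(fx$scored, fx$profile, cusum_scale = "daily-mean")
  expect_equal(scaled$config$sigma, fx$profile$metric_std / sqrt(20))
  tight <- monitor_stream(fx$scored, fx$profile, tighten_daily_limits = TRUE)
  expect_equal(tight$daily_limits$sigma, fx$profile$metric_std / sqrt(20))
})

test_that("detection delay arithmetic handles false alarms and misses", {
  fake_report <- function(alarm_days) {
    structure(list(daily = tibble::tibble(day = 1:60),
                   cusum_alarm_days = alarm_days),
              class = "monitor_report")
  }
  d <- detection_delay(fake_report(c(33L, 35L)), 31)
  expect_equal(d$delay, 2L)
  expect_equal(d$n_false_alarms, 0L)

  d2 <- detection_delay(fake_report(integer(0)), 31)
  expect_true(is.na(d2$delay))
  expect_equal(d2$n_false_alarms, 0L)

  d3 <- detection_delay(fake_report(c(10L, 35L)), 31)
  expect_equal(d3$n_false_alarms, 1L)
  expect_equal(d3$false_alarm_days[[1]], 10L)
  expect_equal(d3$delay, 4L)

  expect_error(detection_delay(fake_report(integer(0)), 61), "range")
})

test_that("null drift (OOD cluster equal to ID) rarely alarms", {
  alarms <- vapply(1:20, function(r) {
    id <- cluster_spec(4, mean = 3, scale = 1)
    sc <- drift_scenario(
      n_days = 20, batch_size = 50,
      phases = tibble::tibble(start_day = c(1L, 11L), end_day = c(10L, 20L),
                              rate_low = c(0, 0.03), rate_high = c(0.01, 0.05)),
      id_cluster = id,
      ood_clusters = list(cluster_spec(4, mean = 3, scale = 1,
                                       label = "OOD")),
      seed = r)
    prof <- fit_reference(sample_cluster(id, 1000, seed = 2000 + r),
                          "cosine")
    length(monitor_stream(generate_stream(sc), prof)$cusum_alarm_days) > 0
  }, logical(1))
  expect_lte(mean(alarms), 0.1)
})

test_that("monitor reports summarize and serialize", {
  fx <- scored_fixture(seed = 6)
  report <- monitor_stream(fx$scored, fx$profile)
  g <- glance(report)
  expect_equal(g$n_days, 5L)
  expect_equal(g$n_images, 100L)

  path <- tempfile(fileext = ".json")
  write_monitor_report(report, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.json$", "-daily.csv", path)))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$n_image_flags, sum(report$per_image$flagged))

  expect_s3_class(autoplot(report, "cusum"), "ggplot")
  expect_s3_class(autoplot(report, "daily"), "ggplot")
  expect_s3_class(autoplot(report, "images"), "ggplot")
})
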