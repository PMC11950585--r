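# Shared fixture builders; everything is generated in code at test time.

# A small, fast drift scenario with a clearly separated OOD cluster.
tiny_scenario <- function(seed = 1L, n_days = 6L, batch = 20L,
                          rate_low = 0, rate_high = 0, dim = 4L) {
  id <- cluster_spec(dim, mean = rep(3, dim), scale = 1, label = "ID")
  ood <- cluster_spec(dim, mean = c(rep(3, dim / 2), rep(-3, dim / 2)),
                      scale = 1, label = "OOD")
  drift_scenario(
    n_days = n_days, batch_size = batch,
    phases = tibble::tibble(start_day = 1L, end_day = n_days,
                            rate_low = rate_low, rate_high = rate_high),
    id_cluster = id, ood_clusters = list(ood), seed = seed
  )
}

# Build a ref_profile with exact mean/covariance (bypassing fitting) so
# closed-form identities can be checked against a prescribed S.
manual_profile <- function(mu, S, metric = "mahalanobis",
                           metric_mean = 1, metric_std = 0.5) {
  structure(
    list(mean_vector = mu, covariance = S, covariance_chol = chol(S),
         metric_name = metric, metric_mean = metric_mean,
         metric_std = metric_std, n_reference = 2L, regularization = 0,
         dim = length(mu)),
    class = "ref_profile"
  )
}

# Independent brute-force tabular CUSUM recursion (the oracle).
cusum_oracle <- function(series, mu0, k, h) {
  sp <- numeric(length(series))
  sm <- numeric(length(series))
  prev_p <- 0
  prev_m <- 0
  for (i in seq_along(series)) {
    prev_p <- max(0, prev_p + series[i] - mu0 - k)
    prev_m <- min(0, prev_m + series[i] - mu0 + k)
    sp[i] <- prev_p
    sm[i] <- prev_m
  }
  list(s_plus = sp, s_minus = sm,
       alarm = sp > h | abs(sm) > h)
}
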