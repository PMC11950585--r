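test_that("cosine similarity matches its geometric identities", {
  expect_equal(cosine_similarity(c(3, 4), c(3, 4)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero-magnitude")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "equal length")

  set.seed(1)
  for (i in 1:200) {
    a <- rnorm(sample(2:10, 1))
    b <- rnorm(length(a))
    cs <- cosine_similarity(a, b)
    expect_true(cs >= -1 - 1e-12 && cs <= 1 + 1e-12)
    expect_equal(cosine_similarity(a, a), 1.0)
    # scale invariance for positive scalings
    expect_equal(cosine_similarity(3.7 * a, 0.2 * b), cs)
  }
})

test_that("mahalanobis distance matches closed forms and a solve oracle", {
  prof <- manual_profile(c(0, 0), diag(c(4, 1)))
  expect_equal(mahalanobis_distance(c(0, 0), prof), 0.0)
  expect_equal(mahalanobis_distance(c(2, 0), prof), 1.0)

  # identity covariance reduces to Euclidean distance
  prof_id <- manual_profile(c(1, -1, 2), diag(3))
  set.seed(2)
  for (i in 1:100) {
    x <- rnorm(3, sd = 3)
    expect_equal(mahalanobis_distance(x, prof_id),
                 sqrt(sum((x - prof_id$mean_vector)^2)))
  }

  # random problems vs an explicit-inverse oracle
  set.seed(3)
  for (i in 1:20) {
    p <- sample(2:10, 1)
    A <- matrix(rnorm(p * p), p)
    S <- crossprod(A) + diag(p)
    mu <- rnorm(p)
    prof_r <- manual_profile(mu, S)
    x <- rnorm(p)
    oracle <- sqrt(drop(t(x - mu) %*% solve(S) %*% (x - mu)))
    expect_equal(mahalanobis_distance(x, prof_r), oracle, tolerance = 1e-8)
  }

  expect_error(mahalanobis_distance(c(1, 2, 3), prof), "dimension mismatch")
})

test_that("mahalanobis is invariant under invertible linear maps", {
  set.seed(4)
  X <- matrix(rnorm(60 * 3), 60, 3)
  for (i in 1:10) {
    A <- matrix(rnorm(9), 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3)
    p1 <- fit_reference(X, metric = "mahalanobis", regularization = 0)
    p2 <- fit_reference(X %*% t(A), metric = "mahalanobis",
                        regularization = 0)
    x <- rnorm(3)
    expect_equal(mahalanobis_distance(x, p1),
                 mahalanobis_distance(drop(A %*% x), p2),
                 tolerance = 1e-8)
  }
})

test_that("fit_reference recovers the generating cluster at large n", {
  two <- matrix(c(2, 0, 1, 1), 2, 2, byrow = TRUE)
  colnames(two) <- c("f0", "f1")
  prof2 <- fit_reference(tibble::as_tibble(two), metric = "cosine")
  expect_equal(unname(prof2$mean_vector), c(1.5, 0.5))

  mu_star <- c(1, 2, -1, 0)
  emb <- sample_cluster(cluster_spec(4, mean = mu_star, scale = 1),
                        n = 10000, seed = 5)
  prof <- fit_reference(emb, metric = "mahalanobis")
  expect_true(all(abs(prof$mean_vector - mu_star) < 0.05))
  expect_true(all(abs(prof$covariance - diag(4)) < 0.1))
  expect_equal(prof$n_reference, 10000L)

  dup <- matrix(1, 5, 3)
  expect_error(fit_reference(dup, regularization = 0), "degenerate")
})

test_that("score_stream preserves order and flags zero embeddings", {
  prof <- fit_reference(
    sample_cluster(cluster_spec(4, mean = 3), 500, seed = 6),
    metric = "cosine")

  empty <- tibble::tibble(day = integer(), image_id = character(),
                          f0 = numeric(), f1 = numeric(), f2 = numeric(),
                          f3 = numeric())
  expect_equal(nrow(score_stream(empty, prof)), 0L)

  at_mean <- tibble::tibble(image_id = c("a", "b"),
                            f0 = prof$mean_vector[1], f1 = prof$mean_vector[2],
                            f2 = prof$mean_vector[3], f3 = prof$mean_vector[4])
  expect_equal(score_stream(at_mean, prof)$metric, c(1, 1))

  md_prof <- fit_reference(
    sample_cluster(cluster_spec(4, mean = 3), 500, seed = 6),
    metric = "mahalanobis")
  expect_equal(score_stream(at_mean, md_prof)$metric, c(0, 0),
               tolerance = 1e-6)

  zero <- tibble::tibble(image_id = "bad", f0 = 0, f1 = 0, f2 = 0, f3 = 0)
  expect_error(score_stream(zero, prof), "bad")

  # well-separated clusters score lower cosine for OOD
  sc <- tiny_scenario(seed = 7, n_days = 2, batch = 50, rate_low = 0.5,
                      rate_high = 0.5)
  scored <- score_stream(generate_stream(sc), prof)
  expect_gt(mean(scored$metric[scored$truth_label == "ID"]),
            mean(scored$metric[scored$truth_label == "OOD"]))
})

test_that("reference profiles round-trip through JSON", {
  emb <- sample_cluster(cluster_spec(3, mean = c(2, -1, 4)), 200, seed = 8)
  prof <- fit_reference(emb, metric = "mahalanobis")
  path <- tempfile(fileext = ".json")
  write_reference_profile(prof, path)
  back <- read_reference_profile(path)
  expect_equal(back$mean_vector, unname(prof$mean_vector))
  expect_equal(back$covariance, unname(prof$covariance))
  expect_equal(back$metric_mean, prof$metric_mean)
  expect_equal(back$metric_std, prof$metric_std)
  x <- c(1, 1, 1)
  expect_equal(mahalanobis_distance(x, back),
               mahalanobis_distance(x, prof), tolerance = 1e-12)
})
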