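#' Fit an in-distribution reference profile
#'
#' Computes everything the monitoring charts need from in-distribution
#' embeddings: the mean feature vector (the reference point all test images
#' are compared against), the sample covariance with a small ridge
#' regularization (for Mahalanobis distances), and the mean and standard
#' deviation of the chosen OOD metric over the reference images themselves
#' (which set the control limits).
#'
#' @param embeddings A tibble/data frame with feature columns `f0 ...`
#'   (extra columns are ignored), or a numeric matrix. At least 2 rows.
#' @param metric `"cosine"` or `"mahalanobis"`.
#' @param regularization Ridge added to the covariance diagonal; default
#'   `1e-6 * trace(S)/p`, enough to make the system solvable without moving
#'   the large eigenvalues.
#'
#' @return An object of class `ref_profile`.
#' @examples
#' emb <- sample_cluster(cluster_spec(4, mean = 2), n = 500, seed = 1)
#' prof <- fit_reference(emb, metric = "cosine")
#' glance(prof)
#' @export
fit_reference <- function(embeddings, metric = c("cosine", "mahalanobis"),
                          regularization = NULL) {
  metric <- match.arg(metric)
  X <- if (is.matrix(embeddings)) embeddings else feature_matrix(embeddings)
  if (nrow(X) < 2L) abort("need at least 2 reference embeddings.")
  if (any(!is.finite(X))) abort("embeddings contain non-finite values.")
  p <- ncol(X)
  mu <- colMeans(X)
  S <- cov(X)
  reg <- regularization %||% (1e-6 * sum(diag(S)) / p)
  if (reg < 0) abort("`regularization` must be >= 0.")
  Sreg <- S + diag(reg, p)
  R <- tryCatch(chol(Sreg), error = function(e) NULL)
  if (is.null(R)) {
    abort(paste("degenerate reference profile: covariance is not positive",
                "definite even after regularization; control limits",
                "undefined. Add variation or increase `regularization`."))
  }
  profile <- structure(
    list(mean_vector = mu, covariance = S, covariance_chol = R,
         metric_name = metric, metric_mean = NA_real_,
         metric_std = NA_real_, n_reference = nrow(X),
         regularization = reg, dim = p),
    class = "ref_profile"
  )
  vals <- metric_values(X, profile)
  profile$metric_mean <- mean(vals)
  profile$metric_std <- sd(vals)
  if (!is.finite(profile$metric_std) || profile$metric_std <= 0) {
    abort(paste("degenerate reference profile: all reference images have",
                "identical metric values, so sigma = 0 and control limits",
                "are undefined."))
  }
  profile
}

#' @export
print.ref_profile <- function(x, ...) {
  cat(sprintf(
    "<ref_profile> metric %s over %d reference images (dim %d)\n",
    x$metric_name, x$n_reference, x$dim))
  cat(sprintf("  metric mean %.6g, sd %.6g, ridge %.3g\n",
              x$metric_mean, x$metric_std, x$regularization))
  invisible(x)
}

#' Cosine similarity between two feature vectors
#'
#' `dot(a, b) / (|a| |b|)`: 1 for identical orientation, 0 for orthogonal,
#' -1 for diametrically opposed vectors.
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return A number in \[-1, 1\].
#' @examples
#' cosine_similarity(c(3, 4), c(3, 4))
#' cosine_similarity(c(1, 0), c(0, 1))
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    abort("cosine similarity undefined for zero-magnitude vectors.")
  }
  sum(a * b) / (na * nb)
}

#' Mahalanobis distance of feature vectors from a reference profile
#'
#' `sqrt((x - mu)' S^{-1} (x - mu))` with `mu` and the (regularized)
#' covariance `S` taken from the profile; solved through the stored Cholesky
#' factor, never by forming an explicit inverse.
#'
#' @param x A numeric vector, or a matrix/tibble of row vectors.
#' @param profile A [fit_reference()] profile.
#' @return Nonnegative distance(s), one per row of `x`.
#' @export
mahalanobis_distance <- function(x, profile) {
  stopifnot(inherits(profile, "ref_profile"))
  X <- if (is.matrix(x)) x else if (is.data.frame(x)) feature_matrix(x) else
    matrix(x, nrow = 1L)
  if (ncol(X) != profile$dim) {
    abort(sprintf("dimension mismatch: x has %d features, profile has %d.",
                  ncol(X), profile$dim))
  }
  xc <- t(X) - profile$mean_vector
  u <- backsolve(profile$covariance_chol, xc, transpose = TRUE)
  d <- sqrt(colSums(u^2))
  if (is.matrix(x) || is.data.frame(x)) d else d[[1L]]
}

# Metric values of a feature matrix against a profile (vectorized).
metric_values <- function(X, profile) {
  if (profile$metric_name == "cosine") {
    norms <- sqrt(rowSums(X^2))
    mu_norm <- sqrt(sum(profile$mean_vector^2))
    if (mu_norm == 0) {
      abort("cosine similarity undefined: reference mean vector is zero.")
    }
    bad <- which(norms == 0)
    if (length(bad) > 0L) {
      abort(sprintf("cosine similarity undefined for zero embeddings (rows %s).",
                    paste(head(bad, 3L), collapse = ", ")))
    }
    as.vector(X %*% profile$mean_vector) / (norms * mu_norm)
  } else {
    mahalanobis_distance(X, profile)
  }
}

#' Score a stream of images against a reference profile
#'
#' Appends the profile's OOD metric (cosine similarity or Mahalanobis
#' distance to the reference mean) as a `metric` column, one value per
#' record, preserving order.
#'
#' @param stream A stream tibble with feature columns `f0 ...` (e.g. from
#'   [generate_stream()] or [extract_features()]).
#' @param profile A [fit_reference()] profile.
#' @return `stream` with a `metric` column appended.
#' @export
score_stream <- function(stream, profile) {
  stopifnot(inherits(profile, "ref_profile"))
  if (nrow(stream) == 0L) {
    return(dplyr::mutate(stream, metric = numeric(0)))
  }
  X <- feature_matrix(stream)
  if (ncol(X) != profile$dim) {
    abort(sprintf("stream has %d features but profile expects %d.",
                  ncol(X), profile$dim))
  }
  if (profile$metric_name == "cosine") {
    norms <- sqrt(rowSums(X^2))
    if (any(norms == 0)) {
      ids <- if ("image_id" %in% names(stream)) {
        stream$image_id[norms == 0]
      } else {
        which(norms == 0)
      }
      abort(sprintf("zero-magnitude embedding for image(s): %s",
                    paste(head(ids, 3L), collapse = ", ")))
    }
  }
  dplyr::mutate(stream, metric = metric_values(X, profile))
}

#' Serialize a reference profile to JSON (and back)
#'
#' Vectors and matrices are written as nested arrays at full precision so a
#' monitoring process can load the profile fitted elsewhere.
#'
#' @param profile A [fit_reference()] profile.
#' @param path File path.
#' @return `write_reference_profile` returns `path` invisibly;
#'   `read_reference_profile` returns the profile.
#' @export
write_reference_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ref_profile"))
  obj <- list(
    mean_vector = profile$mean_vector,
    covariance = profile$covariance,
    metric_name = profile$metric_name,
    metric_mean = profile$metric_mean,
    metric_std = profile$metric_std,
    n_reference = profile$n_reference,
    regularization = profile$regularization,
    dim = profile$dim
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_reference_profile
#' @export
read_reference_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- as.matrix(obj$covariance)
  p <- obj$dim
  Sreg <- S + diag(obj$regularization, p)
  structure(
    list(mean_vector = as.numeric(obj$mean_vector), covariance = S,
         covariance_chol = chol(Sreg), metric_name = obj$metric_name,
         metric_mean = obj$metric_mean, metric_std = obj$metric_std,
         n_reference = obj$n_reference,
         regularization = obj$regularization, dim = p),
    class = "ref_profile"
  )
}

#' @export
tidy.ref_profile <- function(x, ...) {
  tibble::tibble(
    feature = feature_names(x$dim),
    mean = x$mean_vector,
    variance = diag(x$covariance)
  )
}

#' @export
glance.ref_profile <- function(x, ...) {
  tibble::tibble(
    metric_name = x$metric_name,
    metric_mean = x$metric_mean,
    metric_std = x$metric_std,
    n_reference = x$n_reference,
    dim = x$dim,
    regularization = x$regularization
  )
}
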