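#' Basic image statistics with texture summaries
#'
#' The insufficient-by-design baseline feature vector: four intensity moments
#' (mean, population standard deviation, skewness, excess kurtosis) plus
#' eight gray-level co-occurrence (GLCM-style) texture summaries computed
#' from a symmetric co-occurrence matrix over right and down neighbours at 8
#' gray levels: contrast, dissimilarity, homogeneity, energy, entropy,
#' correlation, maximum probability and cluster shade.
#'
#' For a constant image the standard deviation is 0 and skewness, kurtosis
#' and correlation are defined as 0 so that downstream control limits never
#' see non-finite values.
#'
#' @param image A non-empty numeric matrix of pixel intensities.
#' @param levels Number of gray levels for quantization (default 8).
#'
#' @return A named numeric vector of length 12.
#' @examples
#' basic_image_stats(matrix(0:1, 4, 4))
#' @export
basic_image_stats <- function(image, levels = 8L) {
  if (!is.numeric(image) || length(image) == 0L) {
    abort("`image` must be a non-empty numeric array.")
  }
  image <- as.matrix(image)
  x <- as.vector(image)
  m <- mean(x)
  v <- mean((x - m)^2)
  s <- sqrt(v)
  if (s > 0) {
    skew <- mean((x - m)^3) / s^3
    kurt <- mean((x - m)^4) / s^4 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  c(mean = m, sd = s, skewness = skew, kurtosis = kurt,
    glcm_summaries(image, levels))
}

# Symmetric gray-level co-occurrence matrix over offsets (0,1) and (1,0),
# normalized to a joint probability table.
glcm_matrix <- function(image, levels = 8L) {
  rng <- range(image)
  q <- if (rng[2] > rng[1]) {
    pmin(floor((image - rng[1]) / (rng[2] - rng[1]) * levels), levels - 1L)
  } else {
    matrix(0L, nrow(image), ncol(image))
  }
  P <- matrix(0, levels, levels)
  tally <- function(a, b) {
    t <- table(factor(a, levels = 0:(levels - 1L)),
               factor(b, levels = 0:(levels - 1L)))
    P + t + t(t)
  }
  if (ncol(q) > 1L) {
    P <- tally(q[, -ncol(q)], q[, -1L])
  }
  if (nrow(q) > 1L) {
    P <- tally(q[-nrow(q), ], q[-1L, ])
  }
  P / sum(P)
}

glcm_summaries <- function(image, levels = 8L) {
  P <- glcm_matrix(image, levels)
  i <- matrix(0:(levels - 1L), levels, levels)
  j <- t(i)
  pi_marg <- rowSums(P)
  mu_i <- sum(0:(levels - 1L) * pi_marg)
  var_i <- sum((0:(levels - 1L) - mu_i)^2 * pi_marg)
  corr <- if (var_i > 0) sum(P * (i - mu_i) * (j - mu_i)) / var_i else 0
  nz <- P > 0
  c(
    glcm_contrast = sum(P * (i - j)^2),
    glcm_dissimilarity = sum(P * abs(i - j)),
    glcm_homogeneity = sum(P / (1 + (i - j)^2)),
    glcm_energy = sum(P^2),
    glcm_entropy = -sum(P[nz] * log(P[nz])),
    glcm_correlation = corr,
    glcm_max_prob = max(P),
    glcm_cluster_shade = sum(P * ((i - mu_i) + (j - mu_i))^3)
  )
}

#' Create a feature extractor
#'
#' Four interchangeable ways to turn small grayscale images into feature
#' vectors: the image-statistics baseline (always fitted), an unsupervised
#' autoencoder, a supervised binary-cross-entropy classifier, and a
#' contrastive encoder trained with a pairwise margin objective. Learned
#' extractors must be fitted with [fit_extractor()] before use.
#'
#' @param mode One of `"stats_baseline"`, `"autoencoder"`, `"supervised_bce"`,
#'   `"contrastive"`.
#' @param dim Embedding dimensionality for learned extractors (default 32;
#'   the stats baseline always yields 12 features).
#' @param epochs Training epochs (<= 10 keeps CPU fits fast).
#' @param learning_rate SGD learning rate (mode-specific default).
#' @param embedding_layer `"penultimate"` (hidden activations, default) or
#'   `"logits"` (pre-sigmoid output; supervised BCE only).
#' @param margin Margin of the contrastive objective.
#' @param seed Integer seed making fitting deterministic.
#'
#' @return An object of class `feature_extractor`.
#' @seealso [fit_extractor()], [extract_features()]
#' @export
feature_extractor <- function(mode = c("stats_baseline", "autoencoder",
                                       "supervised_bce", "contrastive"),
                              dim = 32L, epochs = 8L, learning_rate = NULL,
                              embedding_layer = c("penultimate", "logits"),
                              margin = 2, seed = 1L) {
  mode <- match.arg(mode)
  embedding_layer <- match.arg(embedding_layer)
  if (embedding_layer == "logits" && mode != "supervised_bce") {
    abort("`embedding_layer = \"logits\"` is only meaningful for supervised_bce.")
  }
  learning_rate <- learning_rate %||%
    switch(mode, autoencoder = 1.0, supervised_bce = 0.3, contrastive = 0.05,
           stats_baseline = NA_real_)
  structure(
    list(mode = mode, dim = if (mode == "stats_baseline") 12L else
           as.integer(dim),
         epochs = as.integer(epochs), learning_rate = learning_rate,
         embedding_layer = embedding_layer, margin = margin,
         seed = as.integer(seed),
         fitted = mode == "stats_baseline",
         net = NULL, loss_trace = NULL, final_loss = NULL),
    class = "feature_extractor"
  )
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("<feature_extractor> mode %s, dim %d, %s\n", x$mode, x$dim,
              if (x$fitted) "fitted" else "unfitted"))
  if (!is.null(x$final_loss)) {
    cat(sprintf("  final training loss: %.6g\n", x$final_loss))
  }
  invisible(x)
}

#' Fit a feature extractor on training images
#'
#' @param extractor A [feature_extractor()].
#' @param images List of numeric image matrices (all the same size).
#' @param labels Binary labels (0/1, logical, or `"ID"`/`"OOD"`) — required
#'   for `supervised_bce` and `contrastive`, ignored otherwise.
#'
#' @return The fitted extractor, carrying its per-epoch loss trace.
#' @export
fit_extractor <- function(extractor, images, labels = NULL) {
  stopifnot(inherits(extractor, "feature_extractor"))
  if (extractor$mode == "stats_baseline") {
    return(extractor)
  }
  X <- images_to_matrix(images)
  if (nrow(X) == 0L) abort("`images` must be non-empty for fitting.")
  if (extractor$mode %in% c("supervised_bce", "contrastive")) {
    if (is.null(labels)) {
      abort(sprintf("`labels` are required to fit a %s extractor.",
                    extractor$mode))
    }
    y <- as_binary_labels(labels)
    if (length(y) != nrow(X)) abort("`labels` must match `images` in length.")
  }
  fit <- withr::with_seed(extractor$seed, switch(
    extractor$mode,
    autoencoder = train_autoencoder(X, extractor$dim, extractor$epochs,
                                    extractor$learning_rate),
    supervised_bce = train_bce(X, y, extractor$dim, extractor$epochs,
                               extractor$learning_rate),
    contrastive = train_contrastive(X, y, extractor$dim, extractor$epochs,
                                    extractor$learning_rate,
                                    margin = extractor$margin)
  ))
  extractor$net <- fit$net
  extractor$out_act <- fit$out_act
  extractor$loss_trace <- fit$loss_trace
  extractor$final_loss <- fit$loss_trace[length(fit$loss_trace)]
  extractor$fitted <- TRUE
  extractor
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.numeric(as.character(labels) == "OOD")
  } else {
    as.numeric(labels != 0)
  }
}

#' Extract feature vectors from images
#'
#' Extraction is pure: the same extractor and images always give the same
#' embedding matrix, with rows in input order.
#'
#' @param extractor A fitted [feature_extractor()].
#' @param images List of numeric image matrices (may be empty).
#' @param image_ids Optional identifiers aligned with `images`.
#'
#' @return A tibble with columns `image_id` and `f0 ... f{dim-1}`.
#' @export
extract_features <- function(extractor, images, image_ids = NULL) {
  stopifnot(inherits(extractor, "feature_extractor"))
  if (!extractor$fitted) {
    abort("extractor is not fitted; call fit_extractor() first.")
  }
  image_ids <- image_ids %||% sprintf("img%04d", seq_along(images))
  if (length(images) == 0L) {
    emb <- matrix(numeric(0), 0L, extractor$dim)
  } else if (extractor$mode == "stats_baseline") {
    emb <- do.call(rbind, lapply(images, basic_image_stats))
  } else {
    X <- images_to_matrix(images)
    fwd <- dense2_forward(extractor$net, X, extractor$out_act)
    emb <- if (extractor$mode == "supervised_bce") {
      if (extractor$embedding_layer == "logits") fwd$Z else fwd$H
    } else if (extractor$mode == "autoencoder") {
      fwd$H
    } else {
      fwd$out
    }
  }
  if (any(!is.finite(emb))) {
    abort("extractor produced non-finite feature values.")
  }
  out <- tibble::as_tibble(as.data.frame(unname(emb)))
  names(out) <- feature_names(ncol(emb))
  dplyr::bind_cols(tibble::tibble(image_id = image_ids), out)
}
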