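#' Describe a Gaussian feature cluster
#'
#' A cluster is a diagonal multivariate Gaussian in feature space standing in
#' for the embedding distribution of one image population (for example axial
#' CT slices as the in-distribution cluster, and out-of-plane slices as a
#' shifted out-of-distribution cluster).
#'
#' @param dim Feature dimensionality (positive integer).
#' @param mean Cluster mean; length 1 (recycled) or `dim`.
#' @param scale Per-dimension standard deviation; positive, length 1 or `dim`.
#' @param label `"ID"` (in-distribution) or `"OOD"`.
#' @param subtype Free-text subtype tag (e.g. `"non-axial"`).
#'
#' @return An object of class `cluster_spec`.
#' @examples
#' cluster_spec(2, mean = c(0, 0), scale = 1, label = "ID")
#' @export
cluster_spec <- function(dim, mean = 0, scale = 1, label = c("ID", "OOD"),
                         subtype = "") {
  label <- match.arg(label)
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1 || dim != round(dim)) {
    abort("`dim` must be a positive integer.")
  }
  dim <- as.integer(dim)
  mean <- rep_len(as.numeric(mean), dim)
  scale <- rep_len(as.numeric(scale), dim)
  if (any(!is.finite(mean))) abort("`mean` must be finite.")
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    abort("`scale` must be positive elementwise.")
  }
  structure(
    list(dim = dim, mean = mean, scale = scale, label = label,
         subtype = subtype),
    class = "cluster_spec"
  )
}

#' @export
print.cluster_spec <- function(x, ...) {
  cat(sprintf("<cluster_spec> %s%s, dim %d, |mean| %.3g, scale [%.3g, %.3g]\n",
              x$label, if (nzchar(x$subtype)) paste0("/", x$subtype) else "",
              x$dim, sqrt(sum(x$mean^2)), min(x$scale), max(x$scale)))
  invisible(x)
}

#' Declare a simulated monitored stream with injected drift
#'
#' A drift scenario describes `n_days` of monitoring with `batch_size` images
#' per day. Each day belongs to exactly one phase; the day's OOD fraction is
#' drawn uniformly from the phase's rate interval and converted to a whole
#' image count. Increasing the rate interval in a later phase injects data
#' drift into the stream.
#'
#' @param n_days Number of monitored days.
#' @param batch_size Images per day.
#' @param phases Data frame with columns `start_day`, `end_day`, `rate_low`,
#'   `rate_high` (rates as fractions in \[0, 1\]) tiling `1..n_days` without
#'   overlap.
#' @param id_cluster In-distribution [cluster_spec()].
#' @param ood_clusters A single OOD [cluster_spec()] or a non-empty list of
#'   them; when several are given each OOD image picks one uniformly.
#' @param seed Integer seed; the stream is fully reproducible from it, and
#'   each day's data is derived from its own substream so it is invariant to
#'   changes affecting other days only.
#' @param rate_model `"per-day"` draws one OOD rate per day and rounds
#'   `rate * batch_size` to a whole count (round-half-to-even); `"per-image"`
#'   draws the day's rate, then flips an independent coin per image.
#'
#' @return An object of class `drift_scenario`.
#' @seealso [generate_stream()], [ct_drift_scenario()]
#' @export
drift_scenario <- function(n_days, batch_size, phases, id_cluster,
                           ood_clusters, seed = 1L,
                           rate_model = c("per-day", "per-image")) {
  rate_model <- match.arg(rate_model)
  if (!is.numeric(n_days) || n_days < 1) abort("`n_days` must be >= 1.")
  if (!is.numeric(batch_size) || batch_size < 1) {
    abort("`batch_size` must be >= 1.")
  }
  n_days <- as.integer(n_days)
  batch_size <- as.integer(batch_size)
  phases <- tibble::as_tibble(phases)
  needed <- c("start_day", "end_day", "rate_low", "rate_high")
  if (!all(needed %in% names(phases))) {
    abort(paste("`phases` needs columns:", paste(needed, collapse = ", ")))
  }
  phases <- dplyr::arrange(phases, .data$start_day)
  covered <- unlist(purrr::map2(phases$start_day, phases$end_day, seq))
  if (!identical(sort(covered), seq_len(n_days))) {
    abort("`phases` must tile days 1..n_days without gaps or overlap.")
  }
  bad <- phases$rate_low < 0 | phases$rate_high > 1 |
    phases$rate_low > phases$rate_high
  if (any(bad)) {
    abort("phase rates must satisfy 0 <= rate_low <= rate_high <= 1.")
  }
  if (inherits(ood_clusters, "cluster_spec")) ood_clusters <- list(ood_clusters)
  if (length(ood_clusters) == 0L) abort("`ood_clusters` must be non-empty.")
  stopifnot(inherits(id_cluster, "cluster_spec"))
  dims <- vapply(ood_clusters, function(s) s$dim, integer(1))
  if (any(dims != id_cluster$dim)) {
    abort("all clusters must share the same feature dimensionality.")
  }
  structure(
    list(n_days = n_days, batch_size = batch_size, phases = phases,
         id_cluster = id_cluster, ood_clusters = ood_clusters,
         seed = as.integer(seed), rate_model = rate_model),
    class = "drift_scenario"
  )
}

#' @export
print.drift_scenario <- function(x, ...) {
  cat(sprintf("<drift_scenario> %d days x %d images/day, dim %d, seed %d\n",
              x$n_days, x$batch_size, x$id_cluster$dim, x$seed))
  print(as.data.frame(x$phases), row.names = FALSE)
  invisible(x)
}

#' Preset scenarios mirroring the CT and CXR monitoring simulations
#'
#' Two months of monitoring (60 days, 100 images/day): during the first month
#' the daily OOD rate is uniform on 0-1%; from day 31 it rises to uniform on
#' 3-5% (`ct_drift_scenario`, the axial vs. non-axial CT analogue) or 2-4%
#' (`cxr_drift_scenario`, the CXR analogue). The in-distribution cluster is
#' N(mean = rep(3.5, dim), I); the OOD cluster mean has half its signs
#' flipped, making it orthogonal to the ID mean so OOD embeddings are well
#' separated in cosine similarity while staying at the ID norm.
#'
#' @param seed Integer seed.
#' @param dim Feature dimensionality (even; default 8).
#' @param phase2_range Length-2 fraction interval for the drifted phase.
#' @return A [drift_scenario()].
#' @export
ct_drift_scenario <- function(seed = 1L, dim = 8L,
                              phase2_range = c(0.03, 0.05)) {
  stopifnot(dim >= 2, dim %% 2 == 0, length(phase2_range) == 2)
  id <- cluster_spec(dim, mean = rep(3.5, dim), scale = 1, label = "ID",
                     subtype = "axial-like")
  ood <- cluster_spec(dim,
                      mean = c(rep(3.5, dim / 2), rep(-3.5, dim / 2)),
                      scale = 1, label = "OOD", subtype = "non-axial-like")
  drift_scenario(
    n_days = 60L, batch_size = 100L,
    phases = tibble::tibble(
      start_day = c(1L, 31L), end_day = c(30L, 60L),
      rate_low = c(0, phase2_range[1]), rate_high = c(0.01, phase2_range[2])
    ),
    id_cluster = id, ood_clusters = list(ood), seed = seed
  )
}

#' @rdname ct_drift_scenario
#' @export
cxr_drift_scenario <- function(seed = 1L, dim = 8L) {
  ct_drift_scenario(seed = seed, dim = dim, phase2_range = c(0.02, 0.04))
}

#' Sample feature vectors from a cluster
#'
#' @param spec A [cluster_spec()].
#' @param n Number of vectors to draw (may be 0).
#' @param seed Integer seed; identical seed gives identical output.
#'
#' @return A tibble with `n` rows and columns `f0 ... f{dim-1}`.
#' @examples
#' sample_cluster(cluster_spec(2, mean = c(1, -1)), n = 3, seed = 7)
#' @export
sample_cluster <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "cluster_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    abort("`n` must be a non-negative count.")
  }
  m <- withr::with_seed(as.integer(seed), sample_cluster_matrix(spec, n))
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- feature_names(spec$dim)
  out
}

# Matrix core used inside already-seeded contexts.
sample_cluster_matrix <- function(spec, n) {
  n <- as.integer(n)
  if (n == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = spec$dim))
  }
  z <- matrix(rnorm(n * spec$dim), nrow = n, ncol = spec$dim)
  sweep(z, 2L, spec$scale, `*`) + matrix(spec$mean, n, spec$dim, byrow = TRUE)
}

#' Generate the day-indexed monitored stream of a scenario
#'
#' For each day, the active phase's OOD fraction is drawn uniformly from its
#' rate interval, converted to a whole OOD count (`round(rate * batch_size)`,
#' half-to-even), the OOD images are sampled from a uniformly chosen OOD
#' cluster and the remainder from the ID cluster, and the day's records are
#' shuffled. Day `k` is generated from its own seeded substream.
#'
#' @param scenario A [drift_scenario()].
#'
#' @return A tibble with one row per image: `day`, `image_id`, `truth_label`
#'   (`"ID"`/`"OOD"`) and feature columns `f0 ...`.
#' @examples
#' sc <- ct_drift_scenario(seed = 1)
#' stream <- generate_stream(sc)
#' dplyr::count(stream, day <= 30, truth_label)
#' @export
generate_stream <- function(scenario) {
  stopifnot(inherits(scenario, "drift_scenario"))
  dim <- scenario$id_cluster$dim
  phase_of <- integer(scenario$n_days)
  for (p in seq_len(nrow(scenario$phases))) {
    phase_of[scenario$phases$start_day[p]:scenario$phases$end_day[p]] <- p
  }
  days <- purrr::map(seq_len(scenario$n_days), function(day) {
    ph <- scenario$phases[phase_of[day], ]
    withr::with_seed(derive_seed(scenario$seed, day), {
      rate <- runif(1, ph$rate_low, ph$rate_high)
      b <- scenario$batch_size
      if (scenario$rate_model == "per-day") {
        n_ood <- as.integer(round(rate * b))
      } else {
        n_ood <- sum(runif(b) < rate)
      }
      n_id <- b - n_ood
      which_ood <- if (n_ood > 0) {
        sample.int(length(scenario$ood_clusters), n_ood, replace = TRUE)
      } else integer(0)
      feats <- matrix(0, nrow = b, ncol = dim)
      if (n_id > 0) {
        feats[seq_len(n_id), ] <-
          sample_cluster_matrix(scenario$id_cluster, n_id)
      }
      if (n_ood > 0) {
        for (ci in unique(which_ood)) {
          idx <- n_id + which(which_ood == ci)
          feats[idx, ] <-
            sample_cluster_matrix(scenario$ood_clusters[[ci]], length(idx))
        }
      }
      labels <- c(rep("ID", n_id), rep("OOD", n_ood))
      ord <- sample.int(b)
      df <- as.data.frame(feats[ord, , drop = FALSE])
      names(df) <- feature_names(dim)
      cbind(
        data.frame(day = day,
                   image_id = sprintf("d%03d-i%03d", day, seq_len(b)),
                   truth_label = labels[ord],
                   stringsAsFactors = FALSE),
        df
      )
    })
  })
  tibble::as_tibble(dplyr::bind_rows(days))
}

#' Read or write a stream as CSV
#'
#' Columns: `day`, `image_id`, `truth_label`, `f0 ... f{dim-1}` (a `metric`
#' column is kept if present).
#'
#' @param stream A stream tibble.
#' @param path File path.
#' @return `write_stream_csv` returns `path` invisibly; `read_stream_csv`
#'   returns the stream tibble.
#' @export
write_stream_csv <- function(stream, path) {
  readr::write_csv(stream, path)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read or write a drift scenario config (YAML or JSON)
#'
#' @param scenario A [drift_scenario()].
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_drift_scenario` returns a [drift_scenario()];
#'   `write_drift_scenario` returns `path` invisibly.
#' @export
write_drift_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "drift_scenario"))
  cl_to_list <- function(s) {
    list(dim = s$dim, mean = s$mean, scale = s$scale, label = s$label,
         subtype = s$subtype)
  }
  cfg <- list(
    n_days = scenario$n_days, batch_size = scenario$batch_size,
    phases = as.data.frame(scenario$phases),
    id_cluster = cl_to_list(scenario$id_cluster),
    ood_clusters = lapply(scenario$ood_clusters, cl_to_list),
    seed = scenario$seed, rate_model = scenario$rate_model
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' @rdname write_drift_scenario
#' @export
read_drift_scenario <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  list_to_cl <- function(l) {
    cluster_spec(l$dim, unlist(l$mean), unlist(l$scale), l$label,
                 l$subtype %||% "")
  }
  ood <- cfg$ood_clusters
  # yaml gives a list of cluster lists; json simplification may too.
  if (!is.null(ood$dim)) ood <- list(ood)
  drift_scenario(
    n_days = cfg$n_days, batch_size = cfg$batch_size,
    phases = tibble::as_tibble(as.data.frame(cfg$phases)),
    id_cluster = list_to_cl(cfg$id_cluster),
    ood_clusters = lapply(ood, list_to_cl),
    seed = cfg$seed, rate_model = cfg$rate_model %||% "per-day"
  )
}
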