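#' Generate toy grayscale images for the desk-scale imaging task
#'
#' Produces small square images in \[0, 1\] emulating the geometry gap between
#' an in-distribution image population and a grossly different OOD one:
#' `"ID"` images contain a filled disc with jittered centre, radius and
#' intensity; `"OOD"` images contain an oriented stripe grating. The two kinds
#' differ in coarse geometric statistics, so an image-statistics baseline
#' separates them partially while learned encoders separate them strongly.
#'
#' @param kind `"ID"` or `"OOD"`.
#' @param n Number of images.
#' @param side Image side in pixels (>= 8).
#' @param seed Integer seed; output is deterministic given the seed.
#'
#' @return A list of `n` `side x side` numeric matrices with values in \[0, 1\].
#' @examples
#' imgs <- generate_toy_images("ID", 2, side = 16, seed = 1)
#' dim(imgs[[1]])
#' @export
generate_toy_images <- function(kind = c("ID", "OOD"), n, side = 28L,
                                seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(side) || side < 8) abort("`side` must be >= 8 pixels.")
  if (!is.numeric(n) || n < 0 || n != round(n)) {
    abort("`n` must be a non-negative count.")
  }
  side <- as.integer(side)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      if (kind == "ID") toy_disc(side) else toy_stripes(side)
    })
  })
}

# Both kinds share the same foreground area fraction and intensity ranges,
# so first-order intensity statistics overlap heavily and the separation
# lives mostly in shape/texture.
toy_canvas <- function(side, mask) {
  bg <- runif(1, 0.05, 0.2)
  fg <- runif(1, 0.6, 0.9)
  img <- matrix(bg, side, side)
  img[mask] <- fg
  img <- img + matrix(rnorm(side * side, sd = 0.07), side, side)
  pmin(pmax(img, 0), 1)
}

toy_area_fraction <- function() runif(1, 0.2, 0.3)

toy_disc <- function(side) {
  cx <- side / 2 + runif(1, -side / 10, side / 10)
  cy <- side / 2 + runif(1, -side / 10, side / 10)
  r <- side * sqrt(toy_area_fraction() / pi)
  xs <- matrix(seq_len(side), side, side)
  ys <- t(xs)
  toy_canvas(side, (xs - cx)^2 + (ys - cy)^2 <= r^2)
}

toy_stripes <- function(side) {
  period <- runif(1, side / 5, side / 3)
  phase <- runif(1, 0, period)
  duty <- toy_area_fraction()
  horizontal <- runif(1) < 0.5
  coord <- matrix(seq_len(side), side, side)
  if (horizontal) coord <- t(coord)
  toy_canvas(side, ((coord + phase) %% period) < duty * period)
}

# Stack a list of images into an n x pixels matrix (row-major per image).
images_to_matrix <- function(images) {
  if (length(images) == 0L) return(matrix(numeric(0), 0L, 0L))
  do.call(rbind, lapply(images, as.vector))
}
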