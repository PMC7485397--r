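#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom median sd var cov approx predict
#'   binom.test pbinom pchisq pnorm qnorm chisq.test shapiro.test t.test
#'   wilcox.test glm binomial coef quantile
#' @importFrom utils read.csv write.csv
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half away from zero (commercial rounding), the convention used for
# all percentages printed in report tables.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a count pair as a percentage
#'
#' Formats `num/den` as a percentage rounded half up, the convention used in
#' rendered report tables (e.g. 48/58 -> 83; 87/291 -> 29.9 at one digit).
#'
#' @param num numerator count.
#' @param den denominator count (> 0).
#' @param digits decimal digits to keep (default 0).
#' @return numeric percentage.
#' @export
fmt_percent <- function(num, den, digits = 0) {
  stopifnot(den > 0)
  round_half_up(100 * num / den, digits)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Smooth random field: iid normal values on a coarse grid, bilinearly
# upsampled to h x w. Used for tissue background variation and for the
# boundary-perturbation field.
smooth_noise_field <- function(h, w, grid_px = 16, sd = 1) {
  gh <- max(2L, ceiling(h / grid_px) + 1L)
  gw <- max(2L, ceiling(w / grid_px) + 1L)
  coarse <- matrix(rnorm(gh * gw, sd = sd), gh, gw)
  resize_raster(coarse, h, w)
}

# Bilinear resize of a matrix (rows x cols) or 3-channel array.
resize_raster <- function(img, target_h, target_w) {
  if (length(dim(img)) == 2L) {
    matrix(EBImage::resize(img, w = target_h, h = target_w), target_h, target_w)
  } else {
    out <- array(0, c(target_h, target_w, dim(img)[3]))
    for (k in seq_len(dim(img)[3])) {
      out[, , k] <- matrix(EBImage::resize(img[, , k], w = target_h,
                                           h = target_w), target_h, target_w)
    }
    out
  }
}

# Logical disc; center = c(row, col), radius in px.
circle_mask <- function(h, w, center, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# Euclidean dilation of a binary mask by `radius` px (distance-transform
# thresholding, exact for the Euclidean metric EBImage::distmap computes).
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask > 0)
  d <- distance_map(1 - (mask > 0))
  (mask > 0) | (d <= radius)
}

# Euclidean distance transform as a plain matrix (distance of each
# foreground pixel to the nearest background pixel).
distance_map <- function(mask) {
  m <- mask > 0
  matrix(EBImage::distmap(m), nrow(m), ncol(m))
}

# Signed Euclidean distance: positive inside the mask, negative outside.
signed_distance <- function(mask) {
  m <- mask > 0
  distance_map(m) - distance_map(!m)
}

# Bounding box of a non-empty mask: list(r0, r1, c0, c1).
bbox_mask <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  list(r0 = min(idx[, 1]), r1 = max(idx[, 1]),
       c0 = min(idx[, 2]), c1 = max(idx[, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
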