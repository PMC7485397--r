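#' Circular measurement ROI
#'
#' @param center `c(row, col)` in px.
#' @param radius radius in px.
#' @param spacing mm per px.
#' @return object of class `swerad_roi` with the area in mm^2.
#' @export
circular_roi <- function(center, radius, spacing) {
  structure(list(center = center, radius = radius,
                 area_mm2 = pi * (radius * spacing)^2, spacing = spacing),
            class = "swerad_roi")
}

# px radius of a round ROI of the given area (default 2 mm^2 in the field).
roi_radius_px <- function(roi_area_mm2, spacing) {
  sqrt(roi_area_mm2 / pi) / spacing
}

roi_pixel_values <- function(map, roi) {
  as.vector(map[circle_mask(nrow(map), ncol(map), roi$center, roi$radius)])
}

# Mean elasticity inside a circle at each candidate center, computed for
# all centers at once by convolving with the disc kernel via im2col-free
# shifting (exact, no approximation): sum over disc offsets.
disc_mean_map <- function(map, radius) {
  h <- nrow(map); w <- ncol(map)
  dr <- seq(-floor(radius), floor(radius))
  acc <- matrix(0, h, w); cnt <- 0L
  padded <- matrix(NA_real_, h + 2 * floor(radius), w + 2 * floor(radius))
  off <- floor(radius)
  padded[(off + 1):(off + h), (off + 1):(off + w)] <- map
  for (a in dr) for (b in dr) {
    if (a^2 + b^2 <= radius^2) {
      acc <- acc + padded[(off + 1 + a):(off + h + a),
                          (off + 1 + b):(off + w + b)]
      cnt <- cnt + 1L
    }
  }
  acc / cnt  # NA wherever the circle leaves the map
}

box_mask_of <- function(box, h, w) {
  m <- matrix(FALSE, h, w)
  m[box$r0:box$r1, box$c0:box$c1] <- TRUE
  m
}

# circle fully inside a region <=> center is at distance > radius from the
# region's complement
centers_fitting_inside <- function(region, radius) {
  distance_map(region) > radius
}

#' Place the maximum-stiffness measurement ROI
#'
#' Searches all circle centers within the lesion mask dilated by one ROI
#' radius ("within or adjacent to the mass") that keep the circle inside
#' the acquisition box, and returns the circle maximizing mean elasticity.
#' Ties break deterministically to the smallest row, then column.
#'
#' @param map elasticity matrix, kPa.
#' @param lesion_mask binary lesion mask.
#' @param box acquisition rectangle `list(r0, r1, c0, c1)`.
#' @param spacing mm per px.
#' @param roi_area_mm2 ROI area (default 2 mm^2).
#' @return a [circular_roi()].
#' @export
place_max_stiffness_roi <- function(map, lesion_mask, box, spacing,
                                    roi_area_mm2 = 2) {
  if (!any(lesion_mask > 0)) stop("placement error: empty lesion mask")
  h <- nrow(map); w <- ncol(map)
  r <- roi_radius_px(roi_area_mm2, spacing)
  bm <- box_mask_of(box, h, w)
  if (!all(lesion_mask[!bm] == 0))
    stop("placement error: lesion outside acquisition box")
  admissible <- dilate_mask(lesion_mask, r) & centers_fitting_inside(bm, r)
  if (!any(admissible))
    stop("placement error: lesion dilated by the ROI radius does not fit in the box")
  means <- disc_mean_map(map, r)
  means[!admissible] <- -Inf
  means[is.na(means)] <- -Inf
  best <- which(means == max(means))          # column-major: smallest col
  idx <- arrayInd(best, dim(means))           # then row within col; re-sort
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  circular_roi(c(idx[1, 1], idx[1, 2]), r, spacing)
}

#' Place the reference fatty-tissue ROI
#'
#' Returns a circle fully inside `fat_mask` and the acquisition box, at the
#' fat pixel farthest from the lesion (scan-order tie-break).
#'
#' @inheritParams place_max_stiffness_roi
#' @param fat_mask binary mask of normal fatty tissue.
#' @return a [circular_roi()].
#' @export
place_fat_roi <- function(map, fat_mask, lesion_mask, box, spacing,
                          roi_area_mm2 = 2) {
  h <- nrow(map); w <- ncol(map)
  r <- roi_radius_px(roi_area_mm2, spacing)
  region <- (fat_mask > 0) & box_mask_of(box, h, w)
  admissible <- centers_fitting_inside(region, r)
  if (!any(admissible))
    stop("placement error: no admissible center for the fat ROI")
  score <- distance_map(!(lesion_mask > 0))   # distance from the lesion
  score[!admissible] <- -Inf
  best <- which(score == max(score))
  idx <- arrayInd(best, dim(score))
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  circular_roi(c(idx[1, 1], idx[1, 2]), r, spacing)
}

#' Maximum inscribed circle of a lesion mask
#'
#' The "round ROI adjusted to the mass contour to encompass the maximum
#' area of mass", realized as the largest circle inscribed in the mask
#' (center at the distance-transform maximum).
#'
#' @param lesion_mask binary mask.
#' @param spacing mm per px.
#' @return a [circular_roi()].
#' @export
mass_roi <- function(lesion_mask, spacing) {
  if (!any(lesion_mask > 0)) stop("placement error: empty lesion mask")
  d <- distance_map(lesion_mask)
  best <- which(d == max(d))
  idx <- arrayInd(best, dim(d))
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  circular_roi(c(idx[1, 1], idx[1, 2]), max(d), spacing)
}

#' Quantitative SWE parameters from placed ROIs
#'
#' `e_max`/`e_mean` are the maximum/mean elasticity over the lesion ROI;
#' `e_ratio` is the lesion-ROI mean over the fat-ROI mean; `e_sd` is the
#' standard deviation over the mass ROI (population SD by default -- the
#' device convention is not standardized, so the sample SD is available
#' via `sd_type = "sample"`).
#'
#' @param map elasticity matrix, kPa.
#' @param lesion_roi,fat_roi,mass_roi [circular_roi()] objects.
#' @param sd_type `"population"` (n denominator, default) or `"sample"`.
#' @return object of class `swerad_quant` with fields `e_max`, `e_mean`,
#'   `e_ratio`, `e_sd` (kPa except the dimensionless ratio).
#' @export
compute_quant_params <- function(map, lesion_roi, fat_roi, mass_roi,
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  lv <- roi_pixel_values(map, lesion_roi)
  fv <- roi_pixel_values(map, fat_roi)
  mv <- roi_pixel_values(map, mass_roi)
  fat_mean <- mean(fv)
  if (fat_mean == 0) stop("undefined-ratio error: fat ROI mean is zero")
  s <- sd(mv)
  if (sd_type == "population") s <- s * sqrt((length(mv) - 1) / length(mv))
  structure(list(e_max = max(lv), e_mean = mean(lv),
                 e_ratio = mean(lv) / fat_mean,
                 e_sd = if (length(mv) > 1) s else 0),
            class = "swerad_quant")
}

#' Aggregate a measurement triplet
#'
#' Clinical convention: each parameter is measured three times; the
#' maximum of `e_max` and the median of `e_mean`, `e_ratio` and `e_sd`
#' are retained.
#'
#' @param triplet list of exactly three `swerad_quant` objects.
#' @return a single `swerad_quant`.
#' @export
aggregate_repeats <- function(triplet) {
  if (length(triplet) != 3L) stop("arity error: exactly 3 measurements required")
  g <- function(f) vapply(triplet, `[[`, numeric(1), f)
  structure(list(e_max = max(g("e_max")), e_mean = median(g("e_mean")),
                 e_ratio = median(g("e_ratio")), e_sd = median(g("e_sd"))),
            class = "swerad_quant")
}

#' Measure the quantitative SWE parameters of one case
#'
#' Full per-case measurement: place the max-stiffness lesion ROI, the fat
#' reference ROI and the mass-encompassing ROI, repeat the measurement
#' three times (repeats are simulated by re-running placement after adding
#' seeded noise jitter to the map), and aggregate with the max/median rule.
#'
#' @param case a `swerad_case`.
#' @param roi_area_mm2 measurement ROI area (default 2 mm^2).
#' @param repeat_jitter_sd SD of the seeded kPa jitter between repeats.
#' @param seed RNG seed for the repeat jitter.
#' @param sd_type SD convention passed to [compute_quant_params()].
#' @return aggregated `swerad_quant`.
#' @export
measure_case_quant <- function(case, roi_area_mm2 = 2, repeat_jitter_sd = 2,
                               seed = 1L, sd_type = "population") {
  mroi <- mass_roi(case$bmode_mask, case$spacing)
  one <- function(map) {
    lroi <- place_max_stiffness_roi(map, case$bmode_mask, case$swe_box,
                                    case$spacing, roi_area_mm2)
    froi <- place_fat_roi(map, case$fat_mask, case$bmode_mask, case$swe_box,
                          case$spacing, roi_area_mm2)
    compute_quant_params(map, lroi, froi, mroi, sd_type)
  }
  with_seed(seed, {
    reps <- lapply(1:3, function(i) {
      jitter <- if (i == 1) 0 else matrix(rnorm(length(case$elasticity),
                                                sd = repeat_jitter_sd),
                                          nrow(case$elasticity))
      one(pmax(case$elasticity + jitter, 0))
    })
    aggregate_repeats(reps)
  })
}

#' Quantitative SWE parameters for a cohort
#'
#' @param cases list of `swerad_case` objects.
#' @param ... passed to [measure_case_quant()]; per-case seeds are derived
#'   from `seed`.
#' @param seed base seed for the repeat jitter.
#' @return data.frame with case_id, label and the four parameters.
#' @export
cohort_quant_table <- function(cases, seed = 1L, ...) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      length(cases)))
  rows <- lapply(seq_along(cases), function(i) {
    q <- measure_case_quant(cases[[i]], seed = seeds[i], ...)
    data.frame(case_id = cases[[i]]$case_id, label = cases[[i]]$label,
               e_max = q$e_max, e_mean = q$e_mean, e_ratio = q$e_ratio,
               e_sd = q$e_sd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
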