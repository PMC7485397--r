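#' Cohort specification for the synthetic phantom generator
#'
#' Describes a desk-scale cohort of paired B-mode / shear-wave elastography
#' (SWE) phantom cases. Benign lesions are generated with homogeneous
#' texture and low stiffness; malignant lesions with heterogeneous texture,
#' high stiffness and a stiffer peritumoral rim (the stiffest tissue around
#' a malignant mass sits in the peritumoral region, which is also why the
#' generator dilates the malignant SWE contour to cover adjacent tissue).
#'
#' @param n_benign,n_malignant case counts (>= 0).
#' @param image_height,image_width raster size in px.
#' @param pixel_spacing mm per pixel (> 0).
#' @param benign_stiffness_mean,malignant_stiffness_mean mean lesion
#'   Young's modulus, kPa. The malignant mean must be >= the benign mean
#'   (equality gives a null cohort with no class separation).
#' @param stiffness_noise_sd additive elasticity noise, kPa.
#' @param rim_stiffness_boost extra stiffness of the malignant peritumoral
#'   rim annulus, kPa.
#' @param texture_heterogeneity named per-class multiplicative speckle
#'   log-SD, `c(benign = , malignant = )`.
#' @param lesion_diameter_range lesion diameter range, mm.
#' @param rim_width_mm width of the peritumoral rim annulus, mm.
#' @param fat_baseline_kpa stiffness of background fatty tissue, kPa.
#' @param bmode_lesion_brightness named per-class interior echogenicity of
#'   the lesion on the B-mode image, `c(benign = , malignant = )` in
#'   `[0, 1]` (malignant masses are markedly hypoechoic; set both equal
#'   for a null cohort).
#' @param birads_error_rate probability that the simulated ordinal
#'   radiologist category falls on the wrong side of the benign/malignant
#'   boundary (exercises comparison statistics only; no claim of modelling
#'   radiologists).
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @return object of class `swerad_cohort_spec`.
#' @export
cohort_spec <- function(n_benign, n_malignant,
                        image_height = 160L, image_width = 160L,
                        pixel_spacing = 0.1,
                        benign_stiffness_mean = 20,
                        malignant_stiffness_mean = 120,
                        stiffness_noise_sd = 5,
                        rim_stiffness_boost = 60,
                        texture_heterogeneity = c(benign = 0.05,
                                                  malignant = 0.35),
                        lesion_diameter_range = c(3, 6),
                        rim_width_mm = 1,
                        fat_baseline_kpa = 9,
                        bmode_lesion_brightness = c(benign = 0.42,
                                                    malignant = 0.28),
                        birads_error_rate = 0.1,
                        seed = 1L) {
  if (n_benign < 0 || n_malignant < 0) stop("case counts must be >= 0")
  if (image_height <= 0 || image_width <= 0)
    stop("invalid spec: image dimensions must be positive")
  if (pixel_spacing <= 0) stop("invalid spec: pixel_spacing must be > 0")
  if (malignant_stiffness_mean < benign_stiffness_mean)
    stop("invalid spec: malignant_stiffness_mean must be >= benign_stiffness_mean")
  if (stiffness_noise_sd < 0 || rim_stiffness_boost < 0)
    stop("invalid spec: noise and rim boost must be >= 0")
  if (!all(c("benign", "malignant") %in% names(texture_heterogeneity)))
    stop("texture_heterogeneity needs named entries 'benign' and 'malignant'")
  if (!all(c("benign", "malignant") %in% names(bmode_lesion_brightness)))
    stop("bmode_lesion_brightness needs named entries 'benign' and 'malignant'")
  if (diff(range(lesion_diameter_range)) < 0 || min(lesion_diameter_range) <= 0)
    stop("invalid lesion_diameter_range")
  structure(list(
    n_benign = as.integer(n_benign), n_malignant = as.integer(n_malignant),
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    pixel_spacing = pixel_spacing,
    benign_stiffness_mean = benign_stiffness_mean,
    malignant_stiffness_mean = malignant_stiffness_mean,
    stiffness_noise_sd = stiffness_noise_sd,
    rim_stiffness_boost = rim_stiffness_boost,
    texture_heterogeneity = texture_heterogeneity,
    lesion_diameter_range = sort(lesion_diameter_range),
    rim_width_mm = rim_width_mm,
    fat_baseline_kpa = fat_baseline_kpa,
    bmode_lesion_brightness = bmode_lesion_brightness,
    birads_error_rate = birads_error_rate,
    seed = as.integer(seed)
  ), class = "swerad_cohort_spec")
}

birads_levels <- c("3", "4a", "4b", "4c", "5")

validate_case <- function(case) {
  dims <- dim(case$bmode)
  stopifnot(length(dims) == 2L)
  if (!identical(dim(case$elasticity), dims) ||
      !identical(dim(case$bmode_mask), dims) ||
      !identical(dim(case$swe_mask), dims) ||
      !identical(dim(case$fat_mask), dims) ||
      !identical(dim(case$swe_color)[1:2], dims))
    stop("format error: rasters and masks of a case must share one shape")
  if (any(case$elasticity < 0))
    stop("data error: elasticity map contains negative values")
  if (!any(case$bmode_mask > 0) || !any(case$swe_mask > 0))
    stop("lesion masks must be non-empty")
  b <- case$swe_box
  inside <- function(mask) {
    idx <- which(mask > 0, arr.ind = TRUE)
    all(idx[, 1] >= b$r0 & idx[, 1] <= b$r1 &
        idx[, 2] >= b$c0 & idx[, 2] <= b$c1)
  }
  if (!inside(case$swe_mask))
    stop("swe_mask must lie inside the SWE acquisition box")
  if (any(case$fat_mask > 0 & case$swe_mask > 0))
    stop("fat_mask must be disjoint from swe_mask")
  if (case$spacing <= 0) stop("spacing must be > 0")
  if (!case$label %in% c("benign", "malignant")) stop("invalid label")
  invisible(case)
}

# Star-convex lesion mask from random radial harmonics around a center.
star_blob_mask <- function(h, w, center, r0, irregularity) {
  amps <- rnorm(4, sd = irregularity / (2:5))
  phis <- runif(4, 0, 2 * pi)
  rr <- matrix(seq_len(h), h, w) - center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  theta <- atan2(rr, cc)
  rad <- r0 * (1 + Reduce(`+`, lapply(1:4, function(k)
    amps[k] * cos((k + 1) * theta + phis[k]))))
  sqrt(rr^2 + cc^2) <= pmax(rad, 2)
}

generate_case <- function(spec, label, case_id) {
  h <- spec$image_height; w <- spec$image_width
  sp <- spec$pixel_spacing
  het <- spec$texture_heterogeneity[[label]]
  rim_w <- spec$rim_width_mm / sp

  # geometry: star-convex blob jittered around the image center
  r0 <- runif(1, spec$lesion_diameter_range[1], spec$lesion_diameter_range[2]) /
    2 / sp
  center <- c(h / 2, w / 2) + runif(2, -0.1, 0.1) * c(h, w)
  mask <- star_blob_mask(h, w, center, r0, 0.04 + 0.5 * het)

  # elasticity: fat background + lesion speckle (+ malignant rim annulus)
  lesion_mean <- switch(label, benign = spec$benign_stiffness_mean,
                        malignant = spec$malignant_stiffness_mean)
  emap <- spec$fat_baseline_kpa *
    exp(smooth_noise_field(h, w, 24, 0.08)) +
    rnorm(h * w, sd = spec$stiffness_noise_sd / 4)
  speckle <- exp(rnorm(h * w, sd = het) - het^2 / 2)
  lesion_vals <- lesion_mean * speckle + rnorm(h * w, sd = spec$stiffness_noise_sd)
  emap[mask] <- lesion_vals[which(mask)]
  if (label == "malignant" && spec$rim_stiffness_boost > 0) {
    rim <- dilate_mask(mask, rim_w) & !mask  # peritumoral tissue stiffest
    rim_vals <- (lesion_mean + spec$rim_stiffness_boost) * speckle +
      rnorm(h * w, sd = spec$stiffness_noise_sd)
    emap[rim] <- rim_vals[which(rim)]
  }
  emap <- pmax(emap, 0)

  # SWE contour convention: non-homogeneous masses (those with a stiff
  # peritumoral rim) are contoured to cover the mass plus adjacent tissue;
  # homogeneous masses stop at the border. In a null cohort (no rim) the
  # two classes are therefore contoured identically.
  has_rim <- label == "malignant" && spec$rim_stiffness_boost > 0
  swe_mask <- if (has_rim) dilate_mask(mask, rim_w) else mask

  # acquisition box: full frame inset by 4 px
  box <- list(r0 = 5L, r1 = h - 4L, c0 = 5L, c1 = w - 4L)
  box_mask <- matrix(FALSE, h, w)
  box_mask[box$r0:box$r1, box$c0:box$c1] <- TRUE
  fat_mask <- box_mask & !dilate_mask(swe_mask, 2)

  # B-mode: bright gland background, hypoechoic lesion (malignant darker,
  # more heterogeneous); quantized to 8 bits so PNG round trips exactly
  bmode <- 0.55 + smooth_noise_field(h, w, 24, 0.05) +
    rnorm(h * w, sd = 0.08)
  interior <- spec$bmode_lesion_brightness[[label]]
  bmode[mask] <- (interior * exp(rnorm(sum(mask), sd = het) - het^2 / 2) +
                    rnorm(sum(mask), sd = 0.05))
  bmode <- round(clamp(bmode, 0, 1) * 255) / 255

  # ordinal radiologist-like category (noisy function of the label)
  wrong <- runif(1) < spec$birads_error_rate
  pick_mal <- function() sample(c("4b", "4c", "5"), 1,
                                prob = c(0.2, 0.45, 0.35))
  pick_ben <- function() sample(c("3", "4a"), 1, prob = c(0.75, 0.25))
  birads <- if ((label == "malignant") != wrong) pick_mal() else pick_ben()

  case <- structure(list(
    case_id = case_id,
    bmode = bmode,
    swe_color = render_swe_colormap(emap, display_max = 180),
    elasticity = emap,
    bmode_mask = mask,
    swe_mask = swe_mask,
    fat_mask = fat_mask,
    swe_box = box,
    label = label,
    spacing = sp,
    birads = birads
  ), class = "swerad_case")
  validate_case(case)
}

#' Generate a synthetic phantom cohort
#'
#' Draws `n_benign + n_malignant` paired B-mode/SWE cases from a
#' [cohort_spec()]. Lesions are smooth star-convex blobs (random radial
#' harmonics) rather than ellipses so that downstream ROI code faces
#' realistic boundaries. Bit-reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param id_prefix prefix for generated case ids.
#' @return list of `swerad_case` objects (benign cases first).
#' @export
generate_cohort <- function(spec, id_prefix = "case") {
  stopifnot(inherits(spec, "swerad_cohort_spec"))
  labels <- c(rep("benign", spec$n_benign),
              rep("malignant", spec$n_malignant))
  if (length(labels) == 0L) return(list())
  with_seed(spec$seed, lapply(seq_along(labels), function(i) {
    generate_case(spec, labels[i], sprintf("%s_%03d", id_prefix, i))
  }))
}

# kPa -> ramp position in [0, 1] (clamped at display_max), shared by the
# renderer and by tests of ramp monotonicity.
swe_ramp <- function(values, display_max) {
  if (display_max <= 0) stop("display_max must be > 0")
  if (any(values < 0)) stop("data error: negative elasticity values")
  clamp(values / display_max, 0, 1)
}

#' Render an elasticity map as an SWE color overlay
#'
#' Monotone color ramp from dark blue (very soft tissue) through light
#' blue, green and orange to red (stiff); values above `display_max` clamp
#' to red, mirroring clinical SWE displays.
#'
#' @param elasticity matrix of Young's modulus values, kPa (>= 0).
#' @param display_max top of the displayed stiffness scale, kPa.
#' @return h x w x 3 array of RGB values in `[0, 1]`.
#' @export
render_swe_colormap <- function(elasticity, display_max = 180) {
  t <- swe_ramp(elasticity, display_max)
  anchors_t <- c(0, 0.25, 0.5, 0.75, 1)
  anchors <- rbind(c(0.00, 0.00, 0.35),   # dark blue
                   c(0.25, 0.65, 1.00),   # light blue
                   c(0.00, 0.80, 0.20),   # green
                   c(1.00, 0.60, 0.00),   # orange
                   c(0.90, 0.00, 0.00))   # red
  out <- array(0, c(dim(elasticity), 3L))
  for (k in 1:3) {
    out[, , k] <- matrix(approx(anchors_t, anchors[, k], xout = as.vector(t),
                                rule = 2)$y, nrow(elasticity))
  }
  round(out * 255) / 255  # 8-bit color, so PNG round trips exactly
}

#' Perturb a segmentation mask with a smooth boundary displacement
#'
#' Emulates a second rater / repeat session: the mask boundary is displaced
#' by a smooth random field whose amplitude is bounded by `magnitude`
#' pixels (the field is added to the signed Euclidean distance of the
#' mask, along which the gradient has unit norm). Deterministic from
#' `seed`; `magnitude = 0` returns the mask unchanged.
#'
#' @param mask non-empty binary matrix.
#' @param magnitude maximum boundary displacement, px (>= 0).
#' @param seed integer RNG seed.
#' @return logical matrix, guaranteed non-empty.
#' @export
perturb_mask <- function(mask, magnitude, seed = 1L) {
  if (magnitude < 0) stop("invalid argument: magnitude must be >= 0")
  if (!any(mask > 0)) stop("mask must be non-empty")
  m <- mask > 0
  if (magnitude == 0) return(m)
  sd_map <- signed_distance(m)
  out <- with_seed(seed, {
    field <- smooth_noise_field(nrow(m), ncol(m), 8)
    field <- field / max(abs(field)) * magnitude
    (sd_map + field) > 0
  })
  if (!any(out)) out[which.max(sd_map)] <- TRUE  # never emit an empty mask
  out
}
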