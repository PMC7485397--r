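# kPa ceiling of the float TIFF encoding (breast stiffness stays far
# below this; values are stored as kPa / scale in [0, 1])
elasticity_tiff_scale <- 1000

#' Write a case bundle to a cohort directory
#'
#' Lays down the per-case rasters (elasticity as 32-bit float TIFF; B-mode,
#' SWE color and binary masks as PNG) and appends/updates `manifest.csv`
#' with the fixed column set: `case_id, label, spacing, birads, box_r0,
#' box_r1, box_c0, box_c1` plus one path column per raster slot.
#'
#' @param case a `swerad_case`.
#' @param dir cohort directory (created if missing).
#' @return the case id, invisibly.
#' @export
write_case <- function(case, dir) {
  validate_case(case)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  slots <- c("bmode", "swe_color", "elasticity", "bmode_mask", "swe_mask",
             "fat_mask")
  paths <- character(length(slots)); names(paths) <- slots
  for (s in slots) {
    x <- case[[s]]
    if (s == "elasticity") {
      # 32-bit float TIFF; stored as kPa / elasticity_tiff_scale because
      # float TIFFs carry values in [0, 1]
      p <- file.path(dir, paste0(case$case_id, "_elasticity.tif"))
      tiff::writeTIFF(x / elasticity_tiff_scale, p, bits.per.sample = 32L,
                      reduce = FALSE)
    } else {
      p <- file.path(dir, paste0(case$case_id, "_", s, ".png"))
      if (grepl("mask", s)) x <- (x > 0) * 1
      png::writePNG(x, p)
    }
    paths[s] <- basename(p)
  }
  row <- data.frame(case_id = case$case_id, label = case$label,
                    spacing = case$spacing,
                    birads = case$birads %||% NA_character_,
                    box_r0 = case$swe_box$r0, box_r1 = case$swe_box$r1,
                    box_c0 = case$swe_box$c0, box_c1 = case$swe_box$c1,
                    t(paths), stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.csv")
  if (file.exists(mpath)) {
    man <- read.csv(mpath, stringsAsFactors = FALSE)
    man <- man[man$case_id != case$case_id, , drop = FALSE]
    man <- rbind(man, row)
  } else man <- row
  write.csv(man, mpath, row.names = FALSE)
  invisible(case$case_id)
}

#' Read a binary mask from PNG or NIfTI
#'
#' PNG masks are 0/255 images; NIfTI (`.nii`/`.nii.gz`) masks are accepted
#' for interoperability with segmentations drawn in external tools.
#'
#' @param path file path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("I/O error: missing file ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required to read NIfTI masks")
    v <- RNifti::readNifti(path)
    return(matrix(as.numeric(v) > 0, dim(v)[1], dim(v)[2]))
  }
  png::readPNG(path) > 0.5
}

#' Read a case bundle from a cohort directory
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @param case_id id of the case to read.
#' @return a `swerad_case`.
#' @export
read_case <- function(dir, case_id) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("I/O error: missing file ", mpath)
  man <- read.csv(mpath, stringsAsFactors = FALSE)
  row <- man[man$case_id == case_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("case ", case_id, " not found in manifest")
  need <- function(col) {
    p <- file.path(dir, row[[col]])
    if (!file.exists(p)) stop("I/O error: missing file ", p)
    p
  }
  emap <- tiff::readTIFF(need("elasticity")) * elasticity_tiff_scale
  if (any(emap < 0)) stop("data error: elasticity map contains negative values")
  bmode <- png::readPNG(need("bmode"))
  if (length(dim(bmode)) == 3L) bmode <- bmode[, , 1]
  case <- structure(list(
    case_id = row$case_id,
    bmode = bmode,
    swe_color = png::readPNG(need("swe_color")),
    elasticity = emap,
    bmode_mask = read_mask(need("bmode_mask")),
    swe_mask = read_mask(need("swe_mask")),
    fat_mask = read_mask(need("fat_mask")),
    swe_box = list(r0 = row$box_r0, r1 = row$box_r1,
                   c0 = row$box_c0, c1 = row$box_c1),
    label = row$label,
    spacing = row$spacing,
    birads = if (is.na(row$birads)) NULL else as.character(row$birads)
  ), class = "swerad_case")
  validate_case(case)
}

#' Write a whole cohort
#'
#' @param cases list of `swerad_case` objects.
#' @param dir target directory.
#' @return character vector of case ids, invisibly.
#' @export
write_cohort <- function(cases, dir) {
  invisible(vapply(cases, write_case, character(1), dir = dir))
}

#' Read a whole cohort
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @return list of `swerad_case` objects.
#' @export
read_cohort <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  lapply(man$case_id, function(id) read_case(dir, id))
}

#' Crop the lesion bounding box and resize it to the network input
#'
#' Takes the axis-aligned bounding box of the mask, expands it by `margin`
#' pixels (clipped to the image), min-max scales intensities to `[0, 1]`
#' (a constant crop maps to all zeros), and bilinearly resamples to
#' `target_size`. Grayscale input is replicated to three channels so one
#' network geometry serves both modalities. Masks themselves are never
#' resampled; only image patches are.
#'
#' @param image h x w matrix or h x w x 3 array.
#' @param mask non-empty binary matrix of the same h x w.
#' @param margin expansion of the bounding box, px.
#' @param target_size `c(height, width)` of the network input; the default
#'   is the full-resolution geometry (302 high by 430 wide).
#' @param modality,case_id metadata carried on the returned patch.
#' @return object of class `swerad_patch` with element `pixels`
#'   (target_h x target_w x 3, values in `[0, 1]`).
#' @export
extract_patch <- function(image, mask, margin = 0L,
                          target_size = c(302L, 430L),
                          modality = "bmode", case_id = "") {
  if (!any(mask > 0)) stop("no-lesion error: mask is empty")
  dims <- dim(image)[1:2]
  if (!identical(as.integer(dim(mask)), as.integer(dims)))
    stop("format error: mask and image shapes differ")
  bb <- bbox_mask(mask)
  r0 <- max(1L, bb$r0 - margin); r1 <- min(dims[1], bb$r1 + margin)
  c0 <- max(1L, bb$c0 - margin); c1 <- min(dims[2], bb$c1 + margin)
  crop <- if (length(dim(image)) == 3L) image[r0:r1, c0:c1, , drop = FALSE]
          else image[r0:r1, c0:c1, drop = FALSE]
  rng <- range(crop)
  crop <- if (diff(rng) == 0) crop * 0 else (crop - rng[1]) / diff(rng)
  out <- resize_raster(crop, target_size[1], target_size[2])
  if (length(dim(out)) == 2L) out <- array(rep(out, 3), c(dim(out), 3L))
  out <- clamp(out, 0, 1)
  structure(list(pixels = out, modality = modality, case_id = case_id),
            class = "swerad_patch")
}

#' Dice similarity coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; symmetric in its arguments.
#'
#' @param a,b binary matrices of identical shape, not both empty.
#' @return value in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch between masks")
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) stop("undefined-input error: both masks are empty")
  2 * sum(a & b) / denom
}

#' Agreement band for a Dice coefficient
#'
#' Bands: 0.75-1.00 excellent; 0.50-0.74 good; 0.25-0.49 moderate;
#' below 0.25 poor. Band edges are closed on the printed two-decimal
#' endpoints; values in the unprinted gaps fall to the lower band.
#'
#' @param d Dice value in `[0, 1]`.
#' @return one of `"excellent"`, `"good"`, `"moderate"`, `"poor"`.
#' @export
classify_dice_band <- function(d) {
  if (any(d < 0 | d > 1)) stop("invalid argument: Dice must lie in [0, 1]")
  cut_one <- function(x) {
    if (x >= 0.75) "excellent"
    else if (x >= 0.50) "good"
    else if (x >= 0.25) "moderate"
    else "poor"
  }
  vapply(d, cut_one, character(1))
}
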