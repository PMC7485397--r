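test_that("case bundles round-trip through the cohort directory format", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co[1:2], dir)
  rt <- read_case(dir, co[[1]]$case_id)
  expect_identical(rt$bmode, co[[1]]$bmode)
  expect_identical(rt$swe_color, co[[1]]$swe_color)
  expect_identical(rt$bmode_mask, co[[1]]$bmode_mask > 0)
  expect_identical(rt$swe_mask, co[[1]]$swe_mask > 0)
  expect_identical(rt$label, co[[1]]$label)
  expect_equal(rt$spacing, co[[1]]$spacing)
  # elasticity is exact to 32-bit float precision of the TIFF encoding
  expect_equal(rt$elasticity, co[[1]]$elasticity, tolerance = 1e-6)

  # error contracts: missing file named, negative elasticity rejected
  man <- read.csv(file.path(dir, "manifest.csv"))
  bad <- file.path(dir, man$bmode_mask[2])
  file.remove(bad)
  expect_error(read_case(dir, co[[2]]$case_id), basename(bad), fixed = TRUE)
  expect_error(read_case(dir, "nope"), "not found")
})

test_that("patch extraction crops, rescales and normalizes as specified", {
  img <- matrix(runif(100 * 100), 100, 100)
  full <- matrix(TRUE, 100, 100)
  # degenerate box: whole image resized
  p <- extract_patch(img, full, margin = 0, target_size = c(40L, 60L))
  expect_identical(dim(p$pixels), c(40L, 60L, 3L))
  # any box shape maps to exactly target_size
  m <- matrix(FALSE, 100, 100); m[40:49, 30:49] <- TRUE
  p2 <- extract_patch(img, m, margin = 0, target_size = c(30L, 43L))
  expect_identical(dim(p2$pixels), c(30L, 43L, 3L))
  expect_true(all(p2$pixels >= 0 & p2$pixels <= 1))
  # min-max scaling spreads the crop across [0, 1] (resampling may move
  # slightly off the exact extremes)
  expect_lt(min(p2$pixels), 0.15)
  expect_gt(max(p2$pixels), 0.85)
  # constant crop maps to zeros
  p3 <- extract_patch(matrix(0.7, 50, 50), disc(50, 50, c(25, 25), 10),
                      target_size = c(16L, 16L))
  expect_true(all(p3$pixels == 0))
  # shape idempotence: re-extracting a full-mask patch keeps the shape
  p4 <- extract_patch(p2$pixels, matrix(TRUE, 30, 43), margin = 0,
                      target_size = c(30L, 43L))
  expect_identical(dim(p4$pixels), dim(p2$pixels))
  expect_error(extract_patch(img, matrix(FALSE, 100, 100)), "no-lesion")
})

test_that("Dice coefficient matches the closed form and is symmetric", {
  a <- matrix(FALSE, 10, 10); a[1:3, 1:3] <- TRUE          # |A| = 9
  b <- matrix(FALSE, 10, 10); b[1:3, 2:4] <- TRUE          # |B| = 9, |A&B| = 6
  expect_equal(dice_coefficient(a, b), 2 * 6 / 18)
  expect_equal(dice_coefficient(a, a), 1)
  d2 <- matrix(FALSE, 10, 10); d2[8:9, 8:9] <- TRUE
  expect_equal(dice_coefficient(a, d2), 0)
  expect_error(dice_coefficient(a, matrix(FALSE, 5, 5)), "shape")
  expect_error(dice_coefficient(a * 0 > 0, b * 0 > 0), "undefined")
  # symmetry on random pairs
  set.seed(4)
  for (i in 1:5) {
    x <- matrix(runif(400) < 0.3, 20, 20)
    y <- matrix(runif(400) < 0.3, 20, 20)
    if (sum(x) + sum(y) == 0) next
    expect_identical(dice_coefficient(x, y), dice_coefficient(y, x))
  }
})

test_that("Dice against perturbed masks does not increase with magnitude", {
  m <- disc(80, 80, c(40, 40), 20)
  d <- vapply(c(0.5, 2, 5), function(mag)
    dice_coefficient(m, perturb_mask(m, mag, seed = 13)), numeric(1))
  expect_true(all(diff(d) <= 0))
})

test_that("Dice agreement bands use closed printed endpoints", {
  expect_identical(classify_dice_band(0.80), "excellent")
  expect_identical(classify_dice_band(0.75), "excellent")
  expect_identical(classify_dice_band(0.745), "good")  # gap falls lower
  expect_identical(classify_dice_band(0.50), "good")
  expect_identical(classify_dice_band(0.49), "moderate")
  expect_identical(classify_dice_band(0.25), "moderate")
  expect_identical(classify_dice_band(0.10), "poor")
  expect_error(classify_dice_band(1.2), "invalid")
})
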