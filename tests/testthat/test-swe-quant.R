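test_that("ROI radius follows the area formula", {
  # 2 mm^2 at 0.1 mm/px: r = sqrt(2/pi)/0.1 ~ 7.98 px
  expect_equal(swerad:::roi_radius_px(2, 0.1), sqrt(2 / pi) / 0.1,
               tolerance = 1e-12)
  roi <- circular_roi(c(10, 10), swerad:::roi_radius_px(2, 0.1), 0.1)
  expect_equal(roi$area_mm2, 2, tolerance = 1e-12)
})

test_that("max-stiffness ROI placement matches exhaustive search", {
  box <- list(r0 = 2L, r1 = 47L, c0 = 2L, c1 = 47L)
  lesion <- disc(48, 48, c(24, 24), 10)
  # uniform map: tie-break to first center in scan order
  uni <- matrix(50, 48, 48)
  roi_u <- place_max_stiffness_roi(uni, lesion, box, spacing = 0.25,
                                   roi_area_mm2 = 2)
  bf_u <- bf_place_roi(uni, lesion, box, 0.25, 2)
  expect_equal(roi_u$center, bf_u$center)
  # hot disc inside the lesion: ROI centres on it
  set.seed(8)
  map <- matrix(20 + runif(48 * 48), 48, 48)
  map[disc(48, 48, c(28, 20), 5)] <- 150
  roi <- place_max_stiffness_roi(map, lesion, box, spacing = 0.25,
                                 roi_area_mm2 = 2)
  bf <- bf_place_roi(map, lesion, box, 0.25, 2)
  expect_equal(roi$center, bf$center)
  expect_equal(mean(map[disc(48, 48, roi$center, roi$radius)]), bf$mean)
  # lesion escaping the box is a placement error
  expect_error(place_max_stiffness_roi(map, disc(48, 48, c(2, 24), 4),
                                       box, 0.25), "placement error")
})

test_that("fat ROI stays inside the fat tissue and breaks ties by scan order", {
  box <- list(r0 = 2L, r1 = 47L, c0 = 2L, c1 = 47L)
  lesion <- disc(48, 48, c(24, 24), 8)
  fat <- !swerad:::dilate_mask(lesion, 4) &
    swerad:::box_mask_of(box, 48, 48)
  map <- matrix(10, 48, 48)
  roi <- place_fat_roi(map, fat, lesion, box, spacing = 0.25)
  dm <- disc(48, 48, roi$center, roi$radius)
  expect_false(any(dm & lesion))
  expect_true(all(fat[dm]))
  # a strip narrower than the ROI diameter is infeasible
  strip <- matrix(FALSE, 48, 48); strip[10:12, 5:45] <- TRUE
  expect_error(place_fat_roi(map, strip, lesion, box, spacing = 0.25),
               "placement error")
})

test_that("quantitative parameters follow their definitions", {
  sp <- 0.25
  uni <- matrix(50, 40, 40)
  lroi <- circular_roi(c(20, 20), 5, sp)
  froi <- circular_roi(c(8, 8), 5, sp)
  mroi <- circular_roi(c(20, 20), 8, sp)
  q <- compute_quant_params(uni, lroi, froi, mroi)
  expect_equal(q$e_max, 50); expect_equal(q$e_mean, 50)
  expect_equal(q$e_ratio, 1); expect_equal(q$e_sd, 0)

  # ratio is lesion mean over fat mean (magnitudes as in clinical use)
  map <- uni
  map[disc(40, 40, c(20, 20), 5)] <- 210.0
  map[disc(40, 40, c(8, 8), 5)] <- 10.58
  q2 <- compute_quant_params(map, lroi, froi, mroi)
  expect_equal(q2$e_ratio, 210.0 / 10.58, tolerance = 1e-12)
  expect_equal(round(q2$e_ratio, 2), 19.85)

  # two-pixel SD honours the configured convention
  two <- matrix(0, 10, 10); two[5, 5] <- 10; two[5, 6] <- 20
  r1 <- circular_roi(c(5, 5), 0.5, sp)  # single pixel
  tiny <- circular_roi(c(5, 5.5), 0.75, sp)
  vals <- swerad:::roi_pixel_values(two, tiny)
  expect_setequal(vals, c(10, 20))
  qp <- compute_quant_params(two + 1, r1, r1, tiny, sd_type = "population")
  qs <- compute_quant_params(two + 1, r1, r1, tiny, sd_type = "sample")
  expect_equal(qp$e_sd, 5)
  expect_equal(qs$e_sd, sd(c(10, 20)), tolerance = 1e-12)

  expect_error(compute_quant_params(uni * 0, lroi, froi, mroi),
               "undefined-ratio")
})

test_that("triplicate aggregation keeps max of e_max and medians elsewhere", {
  mk <- function(emax, emean, eratio, esd)
    structure(list(e_max = emax, e_mean = emean, e_ratio = eratio,
                   e_sd = esd), class = "swerad_quant")
  tri <- list(mk(100, 50, 3, 7), mk(90, 60, 4, 9), mk(110, 55, 5, 8))
  ag <- aggregate_repeats(tri)
  expect_equal(ag$e_max, 110)
  expect_equal(ag$e_mean, 55)
  expect_equal(ag$e_ratio, 4)
  expect_equal(ag$e_sd, 8)
  same <- list(mk(1, 2, 3, 4), mk(1, 2, 3, 4), mk(1, 2, 3, 4))
  expect_equal(aggregate_repeats(same), same[[1]])
  expect_error(aggregate_repeats(tri[1:2]), "arity")
})

test_that("adding a constant shifts e_max/e_mean, fixes e_sd, pulls e_ratio to 1", {
  set.seed(3)
  map <- matrix(30 + runif(40 * 40, 0, 40), 40, 40)
  sp <- 0.25
  lroi <- circular_roi(c(20, 20), 5, sp)
  froi <- circular_roi(c(8, 8), 5, sp)
  mroi <- circular_roi(c(20, 20), 8, sp)
  q0 <- compute_quant_params(map, lroi, froi, mroi)
  qc <- compute_quant_params(map + 25, lroi, froi, mroi)
  expect_equal(qc$e_max, q0$e_max + 25)
  expect_equal(qc$e_mean, q0$e_mean + 25)
  expect_equal(qc$e_sd, q0$e_sd, tolerance = 1e-9)
  expect_lt(abs(qc$e_ratio - 1), abs(q0$e_ratio - 1))
})

test_that("per-case measurement separates stiff from soft lesions", {
  co <- tiny_cohort()
  tab <- cohort_quant_table(co, seed = 2L)
  expect_identical(names(tab),
                   c("case_id", "label", "e_max", "e_mean", "e_ratio", "e_sd"))
  expect_gt(min(tab$e_max[tab$label == "malignant"]),
            max(tab$e_max[tab$label == "benign"]))
})
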