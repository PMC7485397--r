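bus_fixture <- function()
  read_signature(system.file("extdata", "bus_signature.json",
                             package = "swerad"))
swe_fixture <- function()
  read_signature(system.file("extdata", "swe_signature.json",
                             package = "swerad"))

test_that("rad-score evaluates the reference signature fixtures exactly", {
  bus <- bus_fixture()
  expect_length(bus$selected_indices, 7)
  expect_equal(rad_score(bus, rep(0, 768)), 3.6044336)
  # all selected features at one: intercept plus the coefficient sum
  expect_equal(rad_score(bus, rep(1, 768)), 3.6044336 - 4.3621948,
               tolerance = 1e-12)
  swe <- swe_fixture()
  expect_length(swe$selected_indices, 4)
  expect_equal(rad_score(swe, rep(0, 768)), 2.496014)
  expect_equal(rad_score(swe, rep(1, 768)),
               2.496014 - (0.3666784 + 1.4319200 + 0.4749501 + 0.2671713),
               tolerance = 1e-12)
  # scoring needs every selected index
  expect_error(rad_score(bus, rep(0, 100)), "input error")
  v <- rep(0, 768); v[747] <- NA
  expect_error(rad_score(bus, v), "missing feature")
})

test_that("rad-score is affine in the features", {
  set.seed(2)
  model <- signature_model("bmode", c(2, 5, 9), c(0.5, -1.2, 2), 0.3)
  x <- matrix(rnorm(50 * 10), 50, 10)
  s <- rad_score(model, x)
  # score of the mean vector equals the mean score
  expect_equal(rad_score(model, colMeans(x)), mean(s), tolerance = 1e-12)
  # scaling acts through the coefficients
  expect_equal(rad_score(model, 2 * x[1, ]) - model$intercept,
               2 * (s[1] - model$intercept), tolerance = 1e-12)
})

test_that("LASSO fitting selects informative features and orients the score", {
  set.seed(77)
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 20), n, 20)
  x[, 7] <- x[, 7] + 3 * y          # one strongly informative feature
  m <- fit_lasso_signature(x, y, cv_folds = 5, seed = 10)
  expect_true(7 %in% m$selected_indices)
  expect_identical(m$orientation, "higher_is_malignant")
  scores <- rad_score(m, x)
  expect_gte(swerad:::auc_mann_whitney(scores, y), 0.95)
  # threshold comes from the Youden rule on the training scores
  pred <- signature_classify(m, scores)
  expect_gt(mean(pred == y), 0.9)
  # forcing the penalty to infinity shrinks everything away
  m0 <- fit_lasso_signature(x, y, seed = 10, lambda = 1e9)
  expect_length(m0$selected_indices, 0)
  expect_equal(rad_score(m0, x[1, ]), m0$intercept)
  expect_error(fit_lasso_signature(matrix(1, 20, 4), rep(c(0, 1), 10),
                                   seed = 1), "no-signal")
  expect_error(fit_lasso_signature(x, rep(0, n), seed = 1),
               "degenerate-label")
})

test_that("duplicating an informative column does not inflate the selection", {
  set.seed(55)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10)
  x[, 3] <- x[, 3] + 2.5 * y
  m1 <- fit_lasso_signature(x, y, cv_folds = 5, seed = 4)
  xd <- cbind(x, x[, 3])
  m2 <- fit_lasso_signature(xd, y, cv_folds = 5, seed = 4)
  expect_lte(length(m2$selected_indices), length(m1$selected_indices) + 1)
})

test_that("selected-feature count is non-increasing in the penalty", {
  set.seed(21)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 15), n, 15)
  x[, 1] <- x[, 1] + 2 * y; x[, 2] <- x[, 2] - 1.5 * y
  counts <- vapply(c(0.001, 0.01, 0.05, 0.2, 1), function(lam)
    length(fit_lasso_signature(x, y, seed = 3,
                               lambda = lam)$selected_indices), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("Youden threshold maximizes J with deterministic tie-breaks", {
  # perfectly separated classes: midpoint, J = 1
  yt <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(yt$threshold, 0.5)
  expect_equal(yt$j, 1)
  # no information: J = 0 at the degenerate cutpoint
  yt0 <- youden_threshold(rep(2, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(yt0$j, 0)
  expect_equal(yt0$threshold, 2)
  # label swap case against the exhaustive-cutpoint oracle
  sc <- c(1, 2, 3, 4); y <- c(0, 1, 0, 1)
  yt2 <- youden_threshold(sc, y)
  expect_equal(yt2$j, bf_youden_max_j(sc, y))
  # random instances: J always matches the oracle
  set.seed(14)
  for (i in 1:10) {
    s <- sample(1:6, 12, replace = TRUE) + runif(12, 0, 0.01)
    yy <- rbinom(12, 1, 0.5)
    if (length(unique(yy)) < 2) next
    expect_equal(youden_threshold(s, yy)$j, bf_youden_max_j(s, yy))
  }
  expect_error(youden_threshold(1:4, rep(1, 4)), "degenerate")
})

test_that("signature JSON round-trips through write/read", {
  m <- signature_model("swe", c(3, 8), c(1.5, -0.25), -0.7,
                       threshold = 0.12, lambda = 0.03,
                       center = stats::setNames(c(1, 2), c(3, 8)),
                       scale = stats::setNames(c(2, 4), c(3, 8)), seed = 9L)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(m, path)
  r <- read_signature(path)
  expect_equal(r$selected_indices, m$selected_indices)
  expect_equal(r$coefficients, m$coefficients)
  expect_equal(r$intercept, m$intercept)
  expect_equal(r$threshold, m$threshold)
  expect_equal(unname(r$center), unname(m$center))
  set.seed(1)
  x <- rnorm(10)
  expect_equal(rad_score(r, x), rad_score(m, x), tolerance = 1e-12)
})
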