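test_that("confusion metrics reproduce printed table fractions", {
  cm <- confusion_metrics(tp = 48, fn = 10, tn = 123, fp = 17)
  expect_equal(cm$sensitivity$estimate, 48 / 58)
  expect_identical(swerad:::round_half_up(100 * cm$sensitivity$estimate), 83)
  expect_equal(cm$specificity$estimate, 123 / 140)
  # Clopper-Pearson bounds match binom.test
  expect_equal(cm$sensitivity$lower,
               binom.test(48, 58)$conf.int[1], tolerance = 1e-12)
  # perfect sensitivity still has an informative lower bound
  cm2 <- confusion_metrics(tp = 58, fn = 0, tn = 1, fp = 0)
  expect_equal(cm2$sensitivity$estimate, 1)
  expect_lt(cm2$sensitivity$lower, 1)
  expect_error(confusion_metrics(0, 0, 5, 5), "undefined-metric")
})

test_that("likelihood ratios and their log-method CIs match printed cells", {
  # sens 48/58, spec 123/140
  lr <- likelihood_ratios(48, 10, 123, 17)
  expect_equal(round(lr$plr$estimate, 2), 6.82)
  expect_equal(round(lr$plr$lower, 2), 4.30)
  expect_equal(round(lr$plr$upper, 1), 10.8)
  expect_equal(round(lr$nlr$estimate, 2), 0.20)
  # sens 58/58, spec 139/140: PLR 140 with a wide CI, NLR 0
  lr2 <- likelihood_ratios(58, 0, 139, 1)
  expect_equal(lr2$plr$estimate, 140)
  expect_equal(round(lr2$plr$lower, 2), 19.86)
  expect_equal(round(lr2$plr$upper, 0), 987)
  expect_equal(lr2$nlr$estimate, 0)
  expect_true(is.na(lr2$nlr$lower))
  # sens 57/58, spec 140/140: infinite PLR, NLR 1/58
  lr3 <- likelihood_ratios(57, 1, 140, 0)
  expect_identical(lr3$plr$estimate, Inf)
  expect_equal(round(lr3$nlr$estimate, 2), 0.02)
  expect_equal(round(lr3$nlr$lower, 4), 0.0025)
  expect_equal(round(lr3$nlr$upper, 2), 0.12)
  expect_error(likelihood_ratios(0, 5, 5, 0), "undefined")
})

test_that("finite likelihood ratios satisfy their defining identities", {
  set.seed(5)
  for (i in 1:20) {
    tp <- sample(1:30, 1); fn <- sample(1:30, 1)
    tn <- sample(1:30, 1); fp <- sample(1:30, 1)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    lr <- likelihood_ratios(tp, fn, tn, fp)
    expect_equal(lr$plr$estimate * (1 - spec), sens, tolerance = 1e-12)
    expect_equal(lr$nlr$estimate * spec, 1 - sens, tolerance = 1e-12)
  }
})

test_that("likelihood-ratio interpretation bands follow the clinical guide", {
  expect_identical(interpret_lr_band(11.8, "positive"), "large")
  expect_identical(interpret_lr_band(6.82, "positive"), "moderate")
  expect_identical(interpret_lr_band(5, "positive"), "moderate")
  expect_identical(interpret_lr_band(2.07, "positive"), "small")
  expect_identical(interpret_lr_band(0.05, "negative"), "large")
  expect_identical(interpret_lr_band(0.2, "negative"), "moderate")
  expect_identical(interpret_lr_band(0.34, "negative"), "small")
  expect_identical(interpret_lr_band(Inf, "positive"), "large")
  expect_error(interpret_lr_band(-1, "positive"), "invalid")
})

test_that("AUC equals brute-force pair counting, DeLong CI behaves", {
  # degenerate endpoints
  expect_equal(roc_auc_delong(c(1, 2, 3, 10, 11, 12),
                              c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc_delong(rep(4, 8), rep(c(0, 1), 4))$auc, 0.5)
  # toy sets against the oracle
  set.seed(31)
  for (i in 1:10) {
    n <- sample(6:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(1:8, n, replace = TRUE) + runif(n, 0, 0.01)
    out <- roc_auc_delong(s, y)
    expect_equal(out$auc, bf_auc(s, y), tolerance = 1e-12)
    expect_true(out$ci[1] <= out$auc && out$auc <= out$ci[2])
  }
  expect_error(roc_auc_delong(1:4, rep(1, 4)), "degenerate")
})

test_that("DeLong variance and paired test agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(63)
  y <- rbinom(60, 1, 0.4)
  y[1:2] <- c(0, 1)
  a <- rnorm(60) + 1.2 * y
  b <- rnorm(60) + 0.8 * y
  ours <- roc_auc_delong(a, y, b)
  ra <- pROC::roc(y, a, quiet = TRUE, direction = "<")
  ci <- pROC::ci.auc(ra, method = "delong")
  expect_equal(ours$auc, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  expect_equal(ours$ci[1], as.numeric(ci[1]), tolerance = 1e-9)
  expect_equal(ours$ci[2], as.numeric(ci[3]), tolerance = 1e-9)
  rt <- pROC::roc.test(ra, pROC::roc(y, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(ours$p_value, as.numeric(rt$p.value), tolerance = 1e-9)
})

test_that("DeLong CI covers the true AUC at close to nominal rate", {
  # binormal model with known AUC: X1 ~ N(mu, 1), X0 ~ N(0, 1)
  mu <- 1
  true_auc <- pnorm(mu / sqrt(2))
  set.seed(97)
  hits <- 0
  n_sim <- 500
  for (i in seq_len(n_sim)) {
    y <- rep(c(0, 1), each = 30)
    s <- rnorm(60) + mu * y
    ci <- roc_auc_delong(s, y)$ci
    hits <- hits + (ci[1] <= true_auc && true_auc <= ci[2])
  }
  expect_gt(hits / n_sim, 0.92)
  expect_lt(hits / n_sim, 0.98)
})

test_that("McNemar test is exact for small discordance and symmetric", {
  expect_equal(mcnemar_test(c(TRUE, FALSE), c(FALSE, TRUE))$p_value, 1)
  r0 <- mcnemar_test(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(r0$p_value, 1)
  expect_identical(r0$method, "degenerate")
  # b = 10, c = 2 against the direct binomial tail oracle
  a <- c(rep(TRUE, 10), rep(FALSE, 2), rep(TRUE, 20))
  b <- c(rep(FALSE, 10), rep(TRUE, 2), rep(TRUE, 20))
  r <- mcnemar_test(a, b)
  expect_identical(c(r$b, r$c), c(10L, 2L))
  expect_equal(r$p_value, bf_mcnemar_exact(10, 2), tolerance = 1e-12)
  expect_identical(r$method, "exact binomial")
  # symmetry in (b, c)
  expect_equal(mcnemar_test(a, b)$p_value, mcnemar_test(b, a)$p_value)
  # large discordance switches to the corrected chi-square
  big_a <- rep(c(TRUE, FALSE), c(20, 15))
  big_b <- rep(c(FALSE, TRUE), c(20, 15))
  rb <- mcnemar_test(big_a, big_b)
  expect_identical(rb$method, "chi-square with continuity correction")
  tab <- matrix(c(0, 15, 20, 0), 2)
  expect_equal(rb$p_value, mcnemar.test(tab)$p.value, tolerance = 1e-12)
  expect_error(mcnemar_test(c(TRUE, FALSE), TRUE), "input error")
})

test_that("Bonferroni adjustment caps and thresholds correctly", {
  one <- bonferroni_adjust(0.03)
  expect_equal(one$p_adjusted, 0.03)
  expect_true(one$significant)
  multi <- bonferroni_adjust(c(0.02, 0.4, 0.001, 0.012), alpha = 0.05)
  expect_equal(multi$p_adjusted, c(0.08, 1, 0.004, 0.048))
  expect_identical(multi$significant, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(bonferroni_adjust(c(0.2, 1.4)), "invalid")
})

test_that("cohort summary picks the right test per variable", {
  set.seed(24)
  n <- 30
  base_age <- rnorm(n, 40, 5)
  tab <- data.frame(
    label = rep(c("benign", "malignant"), each = n),
    age = c(base_age, base_age),                      # identical groups
    size = c(rnorm(n, 10, 1), rnorm(n, 20, 1)),       # 10-SD shift
    side = sample(c("left", "right"), 2 * n, replace = TRUE))
  out <- cohort_summary(tab)
  expect_identical(out$test[out$variable == "age"], "Student t")
  expect_equal(out$p_value[out$variable == "age"], 1, tolerance = 1e-9)
  expect_lt(out$p_value[out$variable == "size"], 0.001)
  expect_identical(out$test[out$variable == "side"], "chi-square")
  # independent categorical variable: p well away from significance
  expect_gt(out$p_value[out$variable == "side"], 0.05)
  expect_error(cohort_summary(data.frame(label = rep("benign", 5), x = 1:5)),
               "degenerate")
})

test_that("diagnostic report rows reproduce their own printed percentages", {
  set.seed(40)
  y <- rep(c(0, 1), each = 29)
  s <- rnorm(58) + 2.2 * y
  rep_ <- diagnostic_report("toy", s, y,
                            youden_threshold(s, y)$threshold)
  row <- swerad:::report_row(rep_)
  sens <- rep_$sensitivity
  expect_match(row$sensitivity,
               sprintf("^%d \\(", swerad:::round_half_up(100 * sens$estimate)))
  expect_match(row$sensitivity,
               sprintf("\\[%d/%d\\]$", sens$num, sens$den))
  # percentage in the rendered row always reproduces from the counts
  expect_identical(swerad:::round_half_up(100 * sens$num / sens$den),
                   swerad:::round_half_up(100 * sens$estimate))
})
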