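#' Sensitivity and specificity with exact confidence intervals
#'
#' Point estimates as count fractions, 95% CIs by the exact
#' Clopper-Pearson method. Table rendering rounds percentages half up to
#' integers (48/58 prints as 83).
#'
#' @param tp,fn,tn,fp confusion counts; `tp + fn >= 1` and `tn + fp >= 1`.
#' @param conf confidence level (default 0.95).
#' @return list with `sensitivity` and `specificity`, each holding
#'   `estimate`, `lower`, `upper`, `num`, `den`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp, conf = 0.95) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn < 1 || tn + fp < 1)
    stop("undefined-metric error: zero denominator")
  prop <- function(num, den) {
    ci <- binom.test(num, den, conf.level = conf)$conf.int
    list(estimate = num / den, lower = ci[1], upper = ci[2],
         num = num, den = den)
  }
  list(sensitivity = prop(tp, tp + fn), specificity = prop(tn, tn + fp))
}

#' Positive and negative likelihood ratios with log-method CIs
#'
#' `PLR = sens / (1 - spec)` (infinite at perfect specificity with
#' non-zero sensitivity) and `NLR = (1 - sens) / spec` (zero at perfect
#' sensitivity). 95% CIs use the asymptotic log method on the counts
#' (`var log PLR = 1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)` and the mirror
#' for NLR); CIs are omitted (`NA`) at infinite or zero point estimates.
#'
#' @inheritParams confusion_metrics
#' @return list with `plr` and `nlr`, each `estimate`, `lower`, `upper`.
#' @export
likelihood_ratios <- function(tp, fn, tn, fp, conf = 0.95) {
  if (tp + fn < 1 || tn + fp < 1)
    stop("undefined-metric error: zero denominator")
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  if (spec == 1 && sens == 0)
    stop("undefined likelihood ratio: sens = 0 at spec = 1")
  z <- qnorm(1 - (1 - conf) / 2)
  lr_ci <- function(est, va) {
    se <- sqrt(va)
    c(exp(log(est) - z * se), exp(log(est) + z * se))
  }
  if (spec == 1) {
    plr <- list(estimate = Inf, lower = NA_real_, upper = NA_real_)
  } else {
    est <- sens / (1 - spec)
    if (tp == 0) plr <- list(estimate = est, lower = NA_real_, upper = NA_real_)
    else {
      ci <- lr_ci(est, 1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
      plr <- list(estimate = est, lower = ci[1], upper = ci[2])
    }
  }
  if (sens == 1) {
    nlr <- list(estimate = 0, lower = NA_real_, upper = NA_real_)
  } else if (spec == 0) {
    nlr <- list(estimate = Inf, lower = NA_real_, upper = NA_real_)
  } else {
    est <- (1 - sens) / spec
    if (tn == 0) nlr <- list(estimate = est, lower = NA_real_, upper = NA_real_)
    else {
      ci <- lr_ci(est, 1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn))
      nlr <- list(estimate = est, lower = ci[1], upper = ci[2])
    }
  }
  list(plr = plr, nlr = nlr)
}

#' Clinical-impact band of a likelihood ratio
#'
#' Jaeschke-style interpretation: a positive LR above 10 (or a negative
#' LR below 0.1) generates large, often conclusive changes in post-test
#' probability; 5-10 (or 0.1-0.2) moderate shifts; anything else small.
#'
#' @param lr likelihood ratio (>= 0; may be `Inf`).
#' @param direction `"positive"` or `"negative"`.
#' @return `"large"`, `"moderate"` or `"small"`.
#' @export
interpret_lr_band <- function(lr, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (any(lr < 0)) stop("invalid likelihood ratio: must be >= 0")
  cut_one <- function(x) {
    if (direction == "positive") {
      if (x > 10) "large" else if (x >= 5) "moderate" else "small"
    } else {
      if (x < 0.1) "large" else if (x <= 0.2) "moderate" else "small"
    }
  }
  vapply(lr, cut_one, character(1))
}

# AUC as the Mann-Whitney statistic (ties count 1/2).
auc_mann_whitney <- function(scores, labels) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop("degenerate error: both classes required")
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10 (per positive) and V01 (per negative).
delong_placements <- function(scores, y) {
  x <- scores[y == 1]; v <- scores[y == 0]
  psi <- outer(x, v, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' ROC AUC with DeLong variance, CI and paired comparison
#'
#' AUC is the Mann-Whitney statistic (ties counted 1/2); its variance and
#' confidence interval come from DeLong's structural components. With a
#' second score vector on the same cases, a two-sided paired z-test for
#' the AUC difference is performed.
#'
#' @param scores_a numeric scores (higher = more likely positive).
#' @param labels binary labels (`"malignant"`/1 positive), both classes
#'   present.
#' @param scores_b optional paired second score vector.
#' @param conf confidence level.
#' @return list with `auc`, `ci`, `se`; and, when `scores_b` is given,
#'   `auc_b`, `ci_b`, `delta`, `z`, `p_value`.
#' @export
roc_auc_delong <- function(scores_a, labels, scores_b = NULL, conf = 0.95) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop("degenerate error: both classes required")
  m <- sum(y == 1); n <- sum(y == 0)
  z <- qnorm(1 - (1 - conf) / 2)
  pa <- delong_placements(scores_a, y)
  var_a <- var(pa$v10) / m + var(pa$v01) / n
  out <- list(auc = pa$auc,
              ci = clamp(pa$auc + c(-1, 1) * z * sqrt(var_a), 0, 1),
              se = sqrt(var_a))
  if (is.null(scores_b)) return(out)
  if (length(scores_b) != length(scores_a))
    stop("paired comparison requires scores on the same cases")
  pb <- delong_placements(scores_b, y)
  var_b <- var(pb$v10) / m + var(pb$v01) / n
  cov_ab <- cov(pa$v10, pb$v10) / m + cov(pa$v01, pb$v01) / n
  delta <- pa$auc - pb$auc
  se_d <- sqrt(max(var_a + var_b - 2 * cov_ab, 0))
  zstat <- if (se_d == 0) {
    if (delta == 0) 0 else sign(delta) * Inf
  } else delta / se_d
  out$auc_b <- pb$auc
  out$ci_b <- clamp(pb$auc + c(-1, 1) * z * sqrt(var_b), 0, 1)
  out$delta <- delta
  out$z <- zstat
  out$p_value <- 2 * pnorm(-abs(zstat))
  out
}

#' McNemar test for two paired classifiers
#'
#' Builds the discordant counts b (A correct, B wrong) and c (A wrong,
#' B correct); exact two-sided binomial p when `b + c < 25`, otherwise
#' the continuity-corrected chi-square.
#'
#' @param correct_a,correct_b logical vectors of per-case correctness of
#'   the two classifiers (same cases, same order).
#' @return list with `p_value`, `b`, `c`, `method`.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b))
    stop("input error: paired vectors must have equal length")
  a <- as.logical(correct_a); b2 <- as.logical(correct_b)
  b <- sum(a & !b2); cc <- sum(!a & b2)
  n <- b + cc
  if (n == 0) return(list(p_value = 1, b = b, c = cc, method = "degenerate"))
  if (n < 25) {
    p <- min(1, 2 * pbinom(min(b, cc), n, 0.5))
    method <- "exact binomial"
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square with continuity correction"
  }
  list(p_value = p, b = b, c = cc, method = method)
}

#' Bonferroni correction
#'
#' @param p_values vector of p values in `[0, 1]`.
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame with `p`, `p_adjusted` (`min(1, m * p)`) and
#'   `significant` (p below the comparison-wise threshold `alpha / m`).
#' @export
bonferroni_adjust <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1))
    stop("invalid p value: must lie in [0, 1]")
  m <- length(p_values)
  data.frame(p = p_values,
             p_adjusted = pmin(1, m * p_values),
             significant = p_values < alpha / m)
}

#' Per-variable group comparison of a cohort table
#'
#' For each column other than the label: continuous variables are
#' compared with Student's t test when both groups pass a Shapiro-Wilk
#' normality check, otherwise with the Mann-Whitney U test; categorical
#' variables with the chi-square test. Summaries are mean +/- SD for
#' continuous variables and count tables for categorical ones.
#'
#' @param table data.frame with a binary `label` column
#'   (benign/malignant) and the variables to compare.
#' @param label_col name of the label column.
#' @param normality_alpha Shapiro-Wilk significance level.
#' @return data.frame with `variable`, `test`, `p_value`,
#'   `benign_summary`, `malignant_summary`.
#' @export
cohort_summary <- function(table, label_col = "label",
                           normality_alpha = 0.05) {
  y <- as_binary_label(table[[label_col]])
  if (length(unique(y)) < 2) stop("degenerate error: one group only")
  vars <- setdiff(names(table), label_col)
  rows <- lapply(vars, function(v) {
    x <- table[[v]]
    if (is.numeric(x)) {
      g0 <- x[y == 0]; g1 <- x[y == 1]
      normal <- function(g) {
        if (length(unique(g)) < 3 || length(g) < 3 || length(g) > 5000)
          return(FALSE)
        shapiro.test(g)$p.value > normality_alpha
      }
      if (normal(g0) && normal(g1)) {
        p <- t.test(g1, g0, var.equal = TRUE)$p.value
        test <- "Student t"
      } else {
        p <- suppressWarnings(wilcox.test(g1, g0)$p.value)
        test <- "Mann-Whitney U"
      }
      fmt <- function(g) sprintf("%.2f +/- %.2f", mean(g), sd(g))
      data.frame(variable = v, test = test, p_value = p,
                 benign_summary = fmt(g0), malignant_summary = fmt(g1))
    } else {
      tab <- table(factor(x), y)
      p <- suppressWarnings(chisq.test(tab)$p.value)
      fmt <- function(col) paste(rownames(tab), tab[, col],
                                 sep = ":", collapse = "; ")
      data.frame(variable = v, test = "chi-square", p_value = p,
                 benign_summary = fmt("0"), malignant_summary = fmt("1"))
    }
  })
  do.call(rbind, rows)
}

#' Full diagnostic report for one thresholded classifier
#'
#' Applies the decision rule, tallies the confusion counts against the
#' truth and assembles the Tables-style row: sensitivity/specificity with
#' exact CIs and counts, DeLong AUC with CI, likelihood ratios with
#' log-method CIs and interpretation bands.
#'
#' @param name classifier name.
#' @param scores per-case scores.
#' @param labels per-case truth.
#' @param threshold decision threshold.
#' @param positive_high TRUE if scores above threshold mean malignant.
#' @return object of class `swerad_report` (a list).
#' @export
diagnostic_report <- function(name, scores, labels, threshold,
                              positive_high = TRUE) {
  y <- as_binary_label(labels)
  pred <- if (positive_high) scores > threshold else scores < threshold
  tp <- sum(pred & y == 1); fn <- sum(!pred & y == 1)
  tn <- sum(!pred & y == 0); fp <- sum(pred & y == 0)
  cm <- confusion_metrics(tp, fn, tn, fp)
  # a classifier that calls nothing positive has undefined likelihood
  # ratios; report NA for that row instead of failing the whole report
  na_lr <- list(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
  lr <- tryCatch(likelihood_ratios(tp, fn, tn, fp),
                 error = function(e) list(plr = na_lr, nlr = na_lr))
  band <- function(est, dir)
    if (is.na(est)) NA_character_ else interpret_lr_band(est, dir)
  auc_scores <- if (positive_high) scores else -scores
  roc <- roc_auc_delong(auc_scores, y)
  structure(list(name = name, threshold = threshold,
                 positive_high = positive_high,
                 counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 sensitivity = cm$sensitivity, specificity = cm$specificity,
                 auc = roc$auc, auc_ci = roc$ci,
                 plr = lr$plr, nlr = lr$nlr,
                 plr_band = band(lr$plr$estimate, "positive"),
                 nlr_band = band(lr$nlr$estimate, "negative"),
                 correct = pred == (y == 1)),
            class = "swerad_report")
}

# Table-rendering helpers: percentages as rounded integers, LRs to two
# decimals except values >= 100 shown as integers, infinite PLR as the
# infinity glyph.
fmt_lr <- function(x) {
  if (is.na(x)) "-"
  else if (is.infinite(x)) "∞"
  else if (x >= 100) sprintf("%d", round_half_up(x))
  else sprintf("%.2f", x)
}

report_row <- function(rep) {
  pct <- function(p) sprintf("%d (%d-%d) [%d/%d]",
                             round_half_up(100 * p$estimate),
                             round_half_up(100 * p$lower),
                             round_half_up(100 * p$upper), p$num, p$den)
  lr_txt <- function(lr) {
    if (is.na(lr$lower)) fmt_lr(lr$estimate)
    else sprintf("%s (%s-%s)", fmt_lr(lr$estimate), fmt_lr(lr$lower),
                 fmt_lr(lr$upper))
  }
  data.frame(parameter = rep$name,
             threshold = sprintf("%.2f", rep$threshold),
             sensitivity = pct(rep$sensitivity),
             specificity = pct(rep$specificity),
             auc = sprintf("%.2f (%.2f-%.2f)", rep$auc, rep$auc_ci[1],
                           rep$auc_ci[2]),
             plr = lr_txt(rep$plr), nlr = lr_txt(rep$nlr),
             stringsAsFactors = FALSE)
}
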