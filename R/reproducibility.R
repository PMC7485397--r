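#' Intraclass correlation coefficient from the two-way ANOVA decomposition
#'
#' Single-measure ICC for a cases x raters matrix. The default `"ICC2"`
#' is the two-way random-effects, absolute-agreement form ICC(2,1), the
#' natural choice when the question is measurement reproducibility across
#' interchangeable raters; `"ICC3"` gives the two-way mixed, consistency
#' form ICC(3,1). Negative estimates are possible and returned as-is.
#'
#' @param ratings numeric matrix, rows = cases (>= 2), columns = raters
#'   (>= 2), no missing cells.
#' @param type `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency).
#' @return scalar ICC estimate.
#' @export
icc <- function(ratings, type = c("ICC2", "ICC3")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 cases and >= 2 raters")
  if (anyNA(ratings)) stop("missing cells are not allowed")
  grand <- mean(ratings)
  if (all(ratings == ratings[1])) stop("undefined-ICC error: zero total variance")
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)        # between cases
  ssc <- n * sum((col_m - grand)^2)        # between raters
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "ICC2") {
    denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  } else {
    denom <- msr + (k - 1) * mse
  }
  if (denom == 0) stop("undefined-ICC error: zero total variance")
  (msr - mse) / denom
}

#' Agreement band for an ICC value
#'
#' Bands: 0.81-1.00 almost perfect; 0.61-0.80 substantial; 0.41-0.60
#' moderate; 0.21-0.40 fair; 0-0.20 (and any negative estimate) weak or
#' no agreement. Edges are closed on the printed endpoints; gap values
#' fall to the lower band.
#'
#' @param v ICC value (<= 1).
#' @return band label.
#' @export
classify_icc_band <- function(v) {
  if (any(v > 1)) stop("invalid argument: ICC cannot exceed 1")
  cut_one <- function(x) {
    if (x >= 0.81) "almost perfect"
    else if (x >= 0.61) "substantial"
    else if (x >= 0.41) "moderate"
    else if (x >= 0.21) "fair"
    else "weak/none"
  }
  vapply(v, cut_one, character(1))
}

#' ICC reproducibility screen over a deep-feature matrix
#'
#' First selection step of the signature procedure: a feature is retained
#' only if both its intra-rater ICC (rater 1, sessions 1 vs 2) and
#' inter-rater ICC (rater 1 vs rater 2, first sessions) are strictly
#' greater than `threshold` (default 0.6, the conventional cutoff for
#' satisfactory feature reproducibility). Features whose ICC is undefined
#' (zero variance, e.g. dead ReLU units) get `NA` and are not retained.
#'
#' @param features_r1s1,features_r1s2,features_r2 cases x features
#'   matrices sharing shape and case order.
#' @param threshold retention cutoff (strict inequality).
#' @param type ICC form, see [icc()].
#' @return data.frame with `feature_index`, `icc_intra`, `icc_inter`,
#'   `retained` (ascending feature index).
#' @export
filter_reproducible_features <- function(features_r1s1, features_r1s2,
                                         features_r2, threshold = 0.6,
                                         type = "ICC2") {
  d <- dim(features_r1s1)
  if (!identical(d, dim(features_r1s2)) || !identical(d, dim(features_r2)))
    stop("input error: the three feature matrices must share one shape")
  safe_icc <- function(m) tryCatch(icc(m, type), error = function(e) NA_real_)
  p <- d[2]
  intra <- vapply(seq_len(p), function(j)
    safe_icc(cbind(features_r1s1[, j], features_r1s2[, j])), numeric(1))
  inter <- vapply(seq_len(p), function(j)
    safe_icc(cbind(features_r1s1[, j], features_r2[, j])), numeric(1))
  retained <- !is.na(intra) & !is.na(inter) &
    intra > threshold & inter > threshold
  data.frame(feature_index = seq_len(p), icc_intra = intra,
             icc_inter = inter, retained = retained)
}
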