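#' Construct a rad-score signature model
#'
#' Low-level constructor; most users obtain models from
#' [fit_lasso_signature()] or [read_signature()].
#'
#' @param modality `"bmode"` or `"swe"`.
#' @param selected_indices feature indices (into the full feature vector)
#'   with non-zero LASSO coefficients.
#' @param coefficients their coefficients (same length, all non-zero).
#' @param intercept model intercept.
#' @param threshold classification threshold on the rad-score scale.
#' @param lambda LASSO penalty at which the model was taken.
#' @param orientation `"higher_is_malignant"` or `"lower_is_malignant"`.
#' @param center,scale optional named standardization vectors (names =
#'   selected indices) applied to features before scoring.
#' @param seed seed used for the cross-validation folds.
#' @return object of class `swerad_signature`.
#' @export
signature_model <- function(modality, selected_indices, coefficients,
                            intercept, threshold = NA_real_,
                            lambda = NA_real_,
                            orientation = "higher_is_malignant",
                            center = NULL, scale = NULL, seed = NA_integer_) {
  if (length(selected_indices) != length(coefficients))
    stop("selected_indices and coefficients must have equal length")
  if (any(coefficients == 0)) stop("all stored coefficients must be non-zero")
  structure(list(modality = modality,
                 selected_indices = as.integer(selected_indices),
                 coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept),
                 threshold = threshold, lambda = lambda,
                 orientation = match.arg(orientation,
                                         c("higher_is_malignant",
                                           "lower_is_malignant")),
                 center = center, scale = scale, seed = seed),
            class = "swerad_signature")
}

#' Fit a LASSO rad-score signature
#'
#' Second and third steps of the signature procedure: L1-penalized
#' logistic regression on (ICC-filtered) deep features, penalty chosen by
#' stratified cross-validation on the binomial deviance, non-zero
#' coefficients forming the signature, and a Youden-index threshold on
#' the training rad-scores. Features are standardized (mean 0, SD 1)
#' before fitting and the standardization is stored in the model, so
#' coefficients are on the standardized scale.
#'
#' @param features cases x features numeric matrix (already ICC-filtered).
#' @param labels per-case labels; `"malignant"` (or 1) is the positive
#'   class.
#' @param cv_folds number of CV folds (each class must have at least this
#'   many cases).
#' @param seed RNG seed for fold assignment.
#' @param modality stored on the model.
#' @param column_index original feature indices of the columns of
#'   `features` (default `1:ncol`); selected indices are reported in this
#'   indexing so models fitted on an ICC-retained subset still address the
#'   full feature vector.
#' @param lambda optional fixed penalty overriding cross-validation
#'   (e.g. a very large value forces the empty, intercept-only model).
#' @param lambda_rule `"min"` (deviance-minimizing, default) or `"1se"`.
#' @param standardize standardize features before fitting (default TRUE).
#' @return a [signature_model()] with Youden threshold and orientation set.
#' @export
fit_lasso_signature <- function(features, labels, cv_folds = 10, seed = 1L,
                                modality = "bmode", column_index = NULL,
                                lambda = NULL, lambda_rule = c("min", "1se"),
                                standardize = TRUE) {
  lambda_rule <- match.arg(lambda_rule)
  features <- as.matrix(features)
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop("degenerate-label error: one class only")
  if (is.null(column_index)) column_index <- seq_len(ncol(features))
  stopifnot(length(column_index) == ncol(features))
  sds <- apply(features, 2, sd)
  if (all(sds == 0)) stop("no-signal error: constant feature matrix")
  if (is.null(lambda) && min(table(y)) < cv_folds)
    stop("need at least cv_folds cases per class")

  ctr <- scl <- NULL
  x <- features
  if (standardize) {
    ctr <- colMeans(features)
    scl <- ifelse(sds == 0, 1, sds)
    x <- sweep(sweep(features, 2, ctr), 2, scl, "/")
  }

  if (is.null(lambda)) {
    foldid <- integer(length(y))
    with_seed(seed, for (cl in unique(y)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    })
    # desk-scale cohorts legitimately have small classes; keep glmnet's
    # small-class caution out of the way while letting other warnings through
    cv <- withCallingHandlers(
      glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                        foldid = foldid, standardize = FALSE,
                        type.measure = "deviance"),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    lambda <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          standardize = FALSE)
  }
  cf <- as.numeric(coef(fit, s = lambda, exact = FALSE))
  sel <- which(cf[-1] != 0)

  model <- signature_model(
    modality = modality,
    selected_indices = column_index[sel],
    coefficients = cf[-1][sel],
    intercept = cf[1],
    lambda = lambda,
    center = if (standardize) stats::setNames(ctr[sel], column_index[sel]),
    scale = if (standardize) stats::setNames(scl[sel], column_index[sel]),
    seed = as.integer(seed))

  # orient so that a higher rad-score means malignancy has AUC >= 0.5
  full <- matrix(0, nrow(features), max(column_index))
  full[, column_index] <- features
  scores <- rad_score(model, full)
  if (auc_mann_whitney(scores, y) < 0.5)
    model$orientation <- "lower_is_malignant"
  yt <- youden_threshold(
    if (model$orientation == "higher_is_malignant") scores else -scores, y)
  model$threshold <- if (model$orientation == "higher_is_malignant")
    yt$threshold else -yt$threshold
  model
}

as_binary_label <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("benign", "malignant"))
    if (length(bad)) stop("labels must be 'benign'/'malignant' or 0/1")
    as.integer(labels == "malignant")
  } else {
    if (!all(labels %in% c(0, 1))) stop("labels must be 'benign'/'malignant' or 0/1")
    as.integer(labels)
  }
}

#' Evaluate the rad-score of a signature
#'
#' `intercept + sum(coefficient * feature)` over the selected indices
#' (after the model's stored standardization, if any). Accepts one
#' feature vector or a cases x features matrix.
#'
#' @param model a [signature_model()].
#' @param features numeric vector or matrix covering all selected indices.
#' @return numeric score(s).
#' @export
rad_score <- function(model, features) {
  stopifnot(inherits(model, "swerad_signature"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  sel <- model$selected_indices
  if (length(sel) == 0)
    return(rep(model$intercept, nrow(features)))
  if (ncol(features) < max(sel))
    stop("input error: feature vector does not supply all selected indices")
  x <- features[, sel, drop = FALSE]
  if (anyNA(x)) stop("input error: missing feature value")
  if (!is.null(model$center))
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  drop(model$intercept + x %*% model$coefficients)
}

#' Classify rad-scores with a signature's threshold and orientation
#'
#' @param model a [signature_model()] with a threshold.
#' @param scores rad-scores from [rad_score()].
#' @return integer vector, 1 = malignant.
#' @export
signature_classify <- function(model, scores) {
  if (model$orientation == "higher_is_malignant")
    as.integer(scores > model$threshold)
  else as.integer(scores < model$threshold)
}

#' Youden-index threshold
#'
#' Maximizes J = sensitivity + specificity - 1 over candidate cutpoints
#' (midpoints between adjacent sorted unique scores), with the decision
#' rule "score > threshold is positive". Ties break toward higher
#' specificity, then the lower threshold.
#'
#' @param scores numeric scores, higher meaning more likely positive.
#' @param labels binary labels (`"malignant"`/1 positive).
#' @return list with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
youden_threshold <- function(scores, labels) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop("degenerate error: both classes required")
  u <- sort(unique(scores))
  cand <- if (length(u) >= 2) (u[-1] + u[-length(u)]) / 2 else u
  evals <- vapply(cand, function(t) {
    pred <- scores > t
    c(sens = sum(pred & y == 1) / sum(y == 1),
      spec = sum(!pred & y == 0) / sum(y == 0))
  }, numeric(2))
  j <- evals["sens", ] + evals["spec", ] - 1
  best <- which(j == max(j))
  best <- best[evals["spec", best] == max(evals["spec", best])]
  best <- best[which.min(cand[best])]
  list(threshold = unname(cand[best]),
       sensitivity = unname(evals["sens", best]),
       specificity = unname(evals["spec", best]), j = unname(j[best]))
}

#' Serialize a signature model as JSON
#'
#' @param model a [signature_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "swerad_signature"))
  obj <- unclass(model)
  obj$standardized <- !is.null(model$center)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a signature model from JSON
#'
#' @param path JSON path written by [write_signature()] (or a hand-written
#'   fixture in the same layout).
#' @return a [signature_model()].
#' @export
read_signature <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- signature_model(
    modality = o$modality,
    selected_indices = o$selected_indices,
    coefficients = o$coefficients,
    intercept = o$intercept,
    threshold = o$threshold %||% NA_real_,
    lambda = o$lambda %||% NA_real_,
    orientation = o$orientation %||% "higher_is_malignant",
    seed = o$seed %||% NA_integer_)
  if (isTRUE(o$standardized) && !is.null(o$center)) {
    m$center <- stats::setNames(as.numeric(o$center), m$selected_indices)
    m$scale <- stats::setNames(as.numeric(o$scale), m$selected_indices)
  }
  m
}
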