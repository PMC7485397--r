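# Shared fixtures (generated in code, cached per test run) and
# independent brute-force oracles used across the suite.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

disc <- function(h, w, center, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

tiny_cohort <- function() {
  cached("tiny_cohort", function() {
    generate_cohort(cohort_spec(4, 4, image_height = 128L,
                                image_width = 128L,
                                lesion_diameter_range = c(3, 5),
                                seed = 11L))
  })
}

# bright-vs-dark disc patches, linearly separable by intensity
separable_patches <- function(n_per_class, h, w, seed = 1) {
  set.seed(seed)
  mk <- function(bright) {
    x <- array(runif(h * w * 3, 0, 0.2), c(h, w, 3))
    r0 <- round(h * 0.3):round(h * 0.7)
    c0 <- round(w * 0.3):round(w * 0.7)
    if (bright) x[r0, c0, ] <- x[r0, c0, ] + 0.7
    pmin(x, 1)
  }
  list(patches = c(lapply(seq_len(n_per_class), function(i) mk(TRUE)),
                   lapply(seq_len(n_per_class), function(i) mk(FALSE))),
       labels = rep(c("malignant", "benign"), each = n_per_class))
}

# ---- independent oracles -------------------------------------------------

# AUC by exhaustive pair counting
bf_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# ICC(2,1) via stats::aov mean squares
bf_icc2_aov <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  d <- data.frame(y = as.vector(ratings),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# two-sided exact binomial McNemar p by direct tail enumeration
bf_mcnemar_exact <- function(b, cc) {
  n <- b + cc
  lo <- min(b, cc)
  tail1 <- sum(stats::dbinom(0:lo, n, 0.5))
  min(1, 2 * tail1)
}

# Youden J by exhaustive evaluation of every midpoint cutpoint
bf_youden_max_j <- function(scores, y) {
  u <- sort(unique(scores))
  cand <- if (length(u) >= 2) (u[-1] + u[-length(u)]) / 2 else u
  best <- -Inf
  for (t in cand) {
    sens <- sum(scores > t & y == 1) / sum(y == 1)
    spec <- sum(scores <= t & y == 0) / sum(y == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}

# exhaustive max-stiffness ROI placement over every admissible center:
# center within one ROI radius of the lesion (computed by direct pairwise
# distances) and the discrete circle entirely inside the box
bf_place_roi <- function(map, mask, box, spacing, roi_area) {
  r <- sqrt(roi_area / pi) / spacing
  h <- nrow(map); w <- ncol(map)
  lesion_px <- which(mask > 0, arr.ind = TRUE)
  box_ok <- matrix(FALSE, h, w)
  box_ok[box$r0:box$r1, box$c0:box$c1] <- TRUE
  best <- NULL; best_mean <- -Inf
  for (i in seq_len(h)) for (j in seq_len(w)) {
    near <- min(sqrt((lesion_px[, 1] - i)^2 + (lesion_px[, 2] - j)^2))
    if (near > r && !mask[i, j]) next
    dm <- disc(h, w, c(i, j), r)
    if (any(dm & !box_ok)) next
    m <- mean(map[dm])
    if (m > best_mean + 1e-9) { best_mean <- m; best <- c(i, j) }
  }
  list(center = best, mean = best_mean)
}
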