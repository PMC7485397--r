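#' Network configuration for the deep-feature extractor
#'
#' Geometry of the small CNN used for deep-radiomic feature extraction:
#' two blocks of 3x3 same-padded convolution (depths 32 and 64, ReLU) each
#' followed by 2x2 max pooling, then fully connected layers of 512
#' (with dropout 0.5), 256 and 2 nodes. The concatenated activations of
#' the 512- and 256-node layers are the deep-radiomic features, so the
#' feature dimension is `fc_sizes[1] + fc_sizes[2]` = 768 at the default
#' widths regardless of input size. The full-resolution input is 302 high
#' by 430 wide by 3 channels; smaller inputs keep the identical layer
#' structure and feature dimension at a desk-scale cost.
#'
#' @param input_size `c(height, width, channels)`; height and width must
#'   survive two 2x2 poolings (>= 4).
#' @param conv_depths depths of the two convolution layers.
#' @param conv_kernel convolution kernel size (square).
#' @param pool_kernel pooling kernel/stride.
#' @param fc_sizes widths of the three fully connected layers; the last
#'   entry is the number of classes (2).
#' @param dropout_rate dropout after the first fully connected layer,
#'   in `[0, 1)`.
#' @return object of class `swerad_net_config`.
#' @export
network_config <- function(input_size = c(302L, 430L, 3L),
                           conv_depths = c(32L, 64L),
                           conv_kernel = 3L, pool_kernel = 2L,
                           fc_sizes = c(512L, 256L, 2L),
                           dropout_rate = 0.5) {
  if (length(input_size) != 3L) stop("input_size must be (h, w, channels)")
  if (input_size[1] < 4 || input_size[2] < 4)
    stop("architecture error: input smaller than two pooling stages allow")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (conv_kernel != 3L) stop("only 3x3 convolution kernels are supported")
  if (pool_kernel != 2L) stop("only 2x2 pooling is supported")
  if (length(fc_sizes) != 3L || fc_sizes[3] != 2L)
    stop("fc_sizes must end in 2 output classes")
  structure(list(input_size = as.integer(input_size),
                 conv_depths = as.integer(conv_depths),
                 conv_kernel = as.integer(conv_kernel),
                 pool_kernel = as.integer(pool_kernel),
                 fc_sizes = as.integer(fc_sizes),
                 dropout_rate = dropout_rate),
            class = "swerad_net_config")
}

#' Training configuration
#'
#' @param epochs training epochs (default 80).
#' @param learning_rate SGD learning rate (default 0.01).
#' @param batch_size minibatch size (default 8; unstated upstream detail
#'   fixed here and recorded on the trained model).
#' @param split_ratio training fraction of the internal 8:2
#'   train/validation split.
#' @param augment apply on-the-fly horizontal/vertical flips and random
#'   rescaling (zoom in `[0.9, 1.1]`) to the training stream.
#' @param seed RNG seed governing initialization, the split, shuffling,
#'   augmentation and dropout.
#' @return object of class `swerad_train_config`.
#' @export
training_config <- function(epochs = 80L, learning_rate = 0.01,
                            batch_size = 8L, split_ratio = 0.8,
                            augment = TRUE, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (split_ratio <= 0 || split_ratio >= 1)
    stop("split_ratio must lie in (0, 1)")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 split_ratio = split_ratio, augment = augment,
                 seed = as.integer(seed)),
            class = "swerad_train_config")
}

# spatial dims after the two conv/pool blocks (floor at odd sizes)
conv_out_dims <- function(cfg) {
  h <- cfg$input_size[1]; w <- cfg$input_size[2]
  h1 <- h %/% 2; w1 <- w %/% 2
  c(h1 %/% 2, w1 %/% 2)
}

#' Describe the network layer by layer
#'
#' Returns the layer sequence with output shapes and parameter counts
#' (e.g. the first convolution at 3 input channels holds
#' 3*3*3*32 + 32 = 896 parameters).
#'
#' @param cfg a [network_config()].
#' @return data.frame with `layer`, `output_shape`, `n_params`.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "swerad_net_config"))
  h <- cfg$input_size[1]; w <- cfg$input_size[2]; ch <- cfg$input_size[3]
  k <- cfg$conv_kernel
  d1 <- cfg$conv_depths[1]; d2 <- cfg$conv_depths[2]
  fd <- conv_out_dims(cfg)
  if (any(fd < 1))
    stop("architecture error: input smaller than two pooling stages allow")
  flat <- fd[1] * fd[2] * d2
  fc <- cfg$fc_sizes
  shp <- function(...) paste(c(...), collapse = "x")
  data.frame(
    layer = c("conv1 (3x3, ReLU)", "maxpool1 (2x2)", "conv2 (3x3, ReLU)",
              "maxpool2 (2x2)", "flatten", "fc1 (ReLU)",
              sprintf("dropout (%.1f)", cfg$dropout_rate), "fc2 (ReLU)",
              "fc3 (softmax)"),
    output_shape = c(shp(h, w, d1), shp(h %/% 2, w %/% 2, d1),
                     shp(h %/% 2, w %/% 2, d2), shp(fd[1], fd[2], d2),
                     shp(flat), shp(fc[1]), shp(fc[1]), shp(fc[2]),
                     shp(fc[3])),
    n_params = c(k * k * ch * d1 + d1, 0, k * k * d1 * d2 + d2, 0, 0,
                 flat * fc[1] + fc[1], 0, fc[1] * fc[2] + fc[2],
                 fc[2] * fc[3] + fc[3]),
    stringsAsFactors = FALSE)
}

# ---- low-level layers (im2col convolution, BLAS matrix products) --------

# Column-major linear indices mapping each output position to its 3x3xC
# receptive field in the zero-padded input; cached per geometry.
im2col_index <- function(h, w, ch, k = 3L) {
  hp <- h + k - 1L; wp <- w + k - 1L
  pos_i <- rep(seq_len(h), times = w)
  pos_j <- rep(seq_len(w), each = h)
  cols <- vector("list", k * k * ch)
  t <- 1L
  for (c0 in seq_len(ch)) for (v in seq_len(k)) for (u in seq_len(k)) {
    cols[[t]] <- (c0 - 1L) * hp * wp + (pos_j + v - 2L) * hp + (pos_i + u - 1L)
    t <- t + 1L
  }
  matrix(unlist(cols), nrow = h * w)
}

pad_input <- function(x, h, w, ch, k = 3L) {
  hp <- h + k - 1L; wp <- w + k - 1L
  out <- array(0, c(hp, wp, ch))
  off <- (k - 1L) %/% 2L
  out[(off + 1):(off + h), (off + 1):(off + w), ] <- x
  out
}

conv_forward <- function(x, weight, bias, h, w, ch, idx) {
  xp <- pad_input(x, h, w, ch)
  xcol <- matrix(xp[as.vector(idx)], nrow = h * w)
  pre <- xcol %*% weight
  pre <- sweep(pre, 2, bias, "+")
  list(out = pre, xcol = xcol)               # (h*w) x depth, pre-ReLU
}

conv_backward <- function(dpre, cache, weight, h, w, ch, idx,
                          need_dx = TRUE) {
  dw <- crossprod(cache$xcol, dpre)
  db <- colSums(dpre)
  dx <- NULL
  if (need_dx) {
    dxcol <- tcrossprod(dpre, weight)
    k2c <- ncol(idx)
    hp <- h + 2L; wp <- w + 2L
    dxp <- numeric(hp * wp * ch)
    for (t in seq_len(k2c)) {
      v <- idx[, t]
      dxp[v] <- dxp[v] + dxcol[, t]
    }
    dxp <- array(dxp, c(hp, wp, ch))
    dx <- dxp[2:(h + 1), 2:(w + 1), , drop = FALSE]
  }
  list(dw = dw, db = db, dx = dx)
}

pool_forward <- function(x, h, w, depth) {
  # x: (h*w) x depth matrix; returns pooled (h2*w2) x depth plus argmax
  a <- array(x, c(h, w, depth))
  h2 <- h %/% 2L; w2 <- w %/% 2L
  i1 <- seq.int(1L, 2L * h2, 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, 2L * w2, 2L); j2 <- j1 + 1L
  s <- list(a[i1, j1, , drop = FALSE], a[i2, j1, , drop = FALSE],
            a[i1, j2, , drop = FALSE], a[i2, j2, , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  which_max <- array(1L, dim(m))
  taken <- s[[1]] == m
  for (t in 2:4) {
    hit <- (s[[t]] == m) & !taken
    which_max[hit] <- t
    taken <- taken | hit
  }
  list(out = matrix(m, h2 * w2, depth), which_max = which_max,
       h2 = h2, w2 = w2)
}

pool_backward <- function(dout, cache, h, w, depth) {
  h2 <- cache$h2; w2 <- cache$w2
  dm <- array(dout, c(h2, w2, depth))
  dx <- array(0, c(h, w, depth))
  i1 <- seq.int(1L, 2L * h2, 2L); j1 <- seq.int(1L, 2L * w2, 2L)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (t in 1:4) {
    sel <- cache$which_max == t
    g <- dm * sel
    dx[i1 + offs[[t]][1], j1 + offs[[t]][2], ] <-
      dx[i1 + offs[[t]][1], j1 + offs[[t]][2], ] + g
  }
  matrix(dx, h * w, depth)
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

he_init <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
}

init_weights <- function(cfg) {
  ch <- cfg$input_size[3]
  d1 <- cfg$conv_depths[1]; d2 <- cfg$conv_depths[2]
  fd <- conv_out_dims(cfg)
  flat <- fd[1] * fd[2] * d2
  fc <- cfg$fc_sizes
  k2 <- cfg$conv_kernel^2
  list(w1 = he_init(k2 * ch, d1), b1 = numeric(d1),
       w2 = he_init(k2 * d1, d2), b2 = numeric(d2),
       wf1 = he_init(flat, fc[1]), bf1 = numeric(fc[1]),
       wf2 = he_init(fc[1], fc[2]), bf2 = numeric(fc[2]),
       wf3 = he_init(fc[2], fc[3]), bf3 = numeric(fc[3]))
}

# Forward pass for one sample. x: h x w x ch array. Returns activations
# needed for backprop (training) or just the FC activations (inference).
net_forward <- function(x, wts, cfg, geom, dropout_mask = NULL) {
  h <- cfg$input_size[1]; w <- cfg$input_size[2]; ch <- cfg$input_size[3]
  d1 <- cfg$conv_depths[1]; d2 <- cfg$conv_depths[2]
  c1 <- conv_forward(x, wts$w1, wts$b1, h, w, ch, geom$idx1)
  a1 <- relu(c1$out)
  p1 <- pool_forward(a1, h, w, d1)
  h1 <- geom$h1; w1 <- geom$w1
  c2 <- conv_forward(array(p1$out, c(h1, w1, d1)), wts$w2, wts$b2,
                     h1, w1, d1, geom$idx2)
  a2 <- relu(c2$out)
  p2 <- pool_forward(a2, h1, w1, d2)
  flat <- as.vector(p2$out)
  z1 <- drop(flat %*% wts$wf1) + wts$bf1
  f1 <- relu(z1)
  f1d <- if (is.null(dropout_mask)) f1 else f1 * dropout_mask
  z2 <- drop(f1d %*% wts$wf2) + wts$bf2
  f2 <- relu(z2)
  logits <- drop(f2 %*% wts$wf3) + wts$bf3
  list(c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2, flat = flat,
       z1 = z1, f1 = f1, f1d = f1d, z2 = z2, f2 = f2, logits = logits)
}

# Backward pass for one sample; dlogits is the gradient of the loss wrt
# the output logits. Accumulates into the gradient list `g`.
net_backward <- function(fw, dlogits, wts, cfg, geom, g,
                         dropout_mask = NULL) {
  h <- cfg$input_size[1]; w <- cfg$input_size[2]; ch <- cfg$input_size[3]
  d1 <- cfg$conv_depths[1]; d2 <- cfg$conv_depths[2]
  g$wf3 <- g$wf3 + outer(fw$f2, dlogits)
  g$bf3 <- g$bf3 + dlogits
  df2 <- drop(wts$wf3 %*% dlogits) * (fw$z2 > 0)
  g$wf2 <- g$wf2 + outer(fw$f1d, df2)
  g$bf2 <- g$bf2 + df2
  df1 <- drop(wts$wf2 %*% df2)
  if (!is.null(dropout_mask)) df1 <- df1 * dropout_mask
  df1 <- df1 * (fw$z1 > 0)
  g$wf1 <- g$wf1 + outer(fw$flat, df1)
  g$bf1 <- g$bf1 + df1
  dflat <- drop(wts$wf1 %*% df1)
  h1 <- geom$h1; w1 <- geom$w1
  dp2 <- matrix(dflat, geom$h2 * geom$w2, d2)
  da2 <- pool_backward(dp2, fw$p2, h1, w1, d2)
  dpre2 <- da2 * (fw$c2$out > 0)
  bk2 <- conv_backward(dpre2, fw$c2, wts$w2, h1, w1, d1, geom$idx2,
                       need_dx = TRUE)
  g$w2 <- g$w2 + bk2$dw
  g$b2 <- g$b2 + bk2$db
  dp1 <- matrix(bk2$dx, h1 * w1, d1)
  da1 <- pool_backward(dp1, fw$p1, h, w, d1)
  dpre1 <- da1 * (fw$c1$out > 0)
  bk1 <- conv_backward(dpre1, fw$c1, wts$w1, h, w, ch, geom$idx1,
                       need_dx = FALSE)
  g$w1 <- g$w1 + bk1$dw
  g$b1 <- g$b1 + bk1$db
  g
}

zero_grads <- function(wts) lapply(wts, function(w) w * 0)

net_geometry <- function(cfg) {
  h <- cfg$input_size[1]; w <- cfg$input_size[2]; ch <- cfg$input_size[3]
  h1 <- h %/% 2L; w1 <- w %/% 2L
  fd <- conv_out_dims(cfg)
  list(h1 = h1, w1 = w1, h2 = fd[1], w2 = fd[2],
       idx1 = im2col_index(h, w, ch),
       idx2 = im2col_index(h1, w1, cfg$conv_depths[1]))
}

# Random flip/zoom augmentation of one h x w x ch patch array.
augment_patch <- function(x) {
  if (runif(1) < 0.5) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  if (runif(1) < 0.5) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  z <- runif(1, 0.9, 1.1)
  if (abs(z - 1) > 1e-3) x <- zoom_patch(x, z)
  x
}

zoom_patch <- function(x, z) {
  h <- dim(x)[1]; w <- dim(x)[2]
  zh <- max(4L, round(h * z)); zw <- max(4L, round(w * z))
  big <- resize_raster(x, zh, zw)
  out <- array(0, dim(x))
  if (z >= 1) {
    r0 <- (zh - h) %/% 2; c0 <- (zw - w) %/% 2
    out <- big[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), , drop = FALSE]
  } else {
    r0 <- (h - zh) %/% 2; c0 <- (w - zw) %/% 2
    out[(r0 + 1):(r0 + zh), (c0 + 1):(c0 + zw), ] <- big
  }
  out
}

patch_pixels <- function(p) {
  if (inherits(p, "swerad_patch")) p$pixels else p
}

#' Train the deep-feature CNN
#'
#' Stratified 8:2 split into training and internal validation streams,
#' on-the-fly augmentation (flips and rescaling) applied to the training
#' stream only, minibatch SGD on the categorical cross-entropy, and
#' best-checkpoint selection by internal-validation accuracy. Fully
#' deterministic from `train_cfg$seed`.
#'
#' @param patches list of patches from [extract_patch()] (or raw
#'   h x w x 3 arrays) matching `net_cfg$input_size`.
#' @param labels per-case labels (`"malignant"`/1 positive); both classes
#'   must be present with >= 2 cases each.
#' @param net_cfg a [network_config()].
#' @param train_cfg a [training_config()].
#' @return object of class `swerad_cnn`: weights at the best checkpoint,
#'   per-epoch log, configs and an `extractor_version` string recording
#'   the feature definition (post-ReLU fc1 and fc2 activations).
#' @export
train_network <- function(patches, labels, net_cfg, train_cfg) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("degenerate-label error: need >= 2 cases per class")
  xs <- lapply(patches, patch_pixels)
  stopifnot(all(vapply(xs, function(x)
    identical(as.integer(dim(x)), net_cfg$input_size), logical(1))))
  geom <- net_geometry(net_cfg)
  keep <- 1 - net_cfg$dropout_rate
  nf1 <- net_cfg$fc_sizes[1]

  with_seed(train_cfg$seed, {
    wts <- init_weights(net_cfg)
    # stratified 8:2 split
    tr_idx <- unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      n_tr <- max(1L, min(length(idx) - 1L,
                          round(train_cfg$split_ratio * length(idx))))
      sample(idx, n_tr)
    }))
    va_idx <- setdiff(seq_along(y), tr_idx)
    best <- list(acc = -Inf, wts = wts, epoch = 0L)
    log_rows <- vector("list", train_cfg$epochs)

    evaluate <- function(idx) {
      loss <- 0; correct <- 0L
      for (i in idx) {
        fw <- net_forward(xs[[i]], wts, net_cfg, geom)
        p <- softmax_rows(matrix(fw$logits, 1))
        loss <- loss - log(max(p[1, y[i] + 1], 1e-12))
        correct <- correct + as.integer(which.max(p) == y[i] + 1)
      }
      c(loss = loss / length(idx), acc = correct / length(idx))
    }

    for (epoch in seq_len(train_cfg$epochs)) {
      order_idx <- sample(tr_idx)
      batches <- split(order_idx,
                       ceiling(seq_along(order_idx) / train_cfg$batch_size))
      ep_loss <- 0; ep_correct <- 0L
      for (bt in batches) {
        g <- zero_grads(wts)
        for (i in bt) {
          x <- xs[[i]]
          if (train_cfg$augment) x <- augment_patch(x)
          dmask <- if (net_cfg$dropout_rate > 0)
            (runif(nf1) >= net_cfg$dropout_rate) / keep else NULL
          fw <- net_forward(x, wts, net_cfg, geom, dropout_mask = dmask)
          p <- drop(softmax_rows(matrix(fw$logits, 1)))
          ep_loss <- ep_loss - log(max(p[y[i] + 1], 1e-12))
          ep_correct <- ep_correct + as.integer(which.max(p) == y[i] + 1)
          dlogits <- p
          dlogits[y[i] + 1] <- dlogits[y[i] + 1] - 1
          g <- net_backward(fw, dlogits / length(bt), wts, net_cfg, geom,
                            g, dropout_mask = dmask)
        }
        for (nm in names(wts))
          wts[[nm]] <- wts[[nm]] - train_cfg$learning_rate * g[[nm]]
      }
      va <- if (length(va_idx)) evaluate(va_idx) else c(loss = NA, acc = NA)
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / length(tr_idx),
        train_acc = ep_correct / length(tr_idx),
        val_loss = va[["loss"]], val_acc = va[["acc"]])
      if (length(va_idx) && va[["acc"]] > best$acc) {
        best <- list(acc = va[["acc"]], wts = wts, epoch = epoch)
      }
    }
    if (!length(va_idx) || is.infinite(best$acc))
      best <- list(acc = NA_real_, wts = wts, epoch = train_cfg$epochs)
    structure(list(weights = best$wts, final_weights = wts,
                   net_cfg = net_cfg, train_cfg = train_cfg,
                   best_epoch = best$epoch, best_val_acc = best$acc,
                   train_idx = sort(tr_idx), val_idx = sort(va_idx),
                   log = do.call(rbind, log_rows),
                   extractor_version = "swerad-cnn-1/fc1+fc2-postrelu"),
              class = "swerad_cnn")
  })
}

#' Extract deep-radiomic features
#'
#' Concatenated post-ReLU activations of the first two fully connected
#' layers, evaluated in inference mode (no dropout, no augmentation):
#' 512 + 256 = 768 values at the default widths.
#'
#' @param model a trained [train_network()] model.
#' @param patches one patch (from [extract_patch()] or a raw array) or a
#'   list of patches.
#' @return a numeric vector for a single patch, or a cases x features
#'   matrix (rownames = case ids when available) for a list.
#' @export
extract_features <- function(model, patches) {
  stopifnot(inherits(model, "swerad_cnn"))
  single <- !is.list(patches) || inherits(patches, "swerad_patch")
  plist <- if (single) list(patches) else patches
  geom <- net_geometry(model$net_cfg)
  feats <- lapply(plist, function(p) {
    x <- patch_pixels(p)
    if (!identical(as.integer(dim(x)), model$net_cfg$input_size))
      stop("input error: patch shape does not match the trained input size")
    fw <- net_forward(x, model$weights, model$net_cfg, geom)
    c(fw$f1, fw$f2)
  })
  if (single) return(feats[[1]])
  out <- do.call(rbind, feats)
  ids <- vapply(plist, function(p)
    if (inherits(p, "swerad_patch")) p$case_id else "", character(1))
  if (any(nzchar(ids))) rownames(out) <- ids
  colnames(out) <- sprintf("f%03d", seq_len(ncol(out)) - 1L)
  out
}

#' Feature dimension of a network configuration
#'
#' @param cfg a [network_config()].
#' @return `fc_sizes[1] + fc_sizes[2]` (768 at the default widths).
#' @export
feature_dimension <- function(cfg) sum(cfg$fc_sizes[1:2])

#' Save / load a trained CNN checkpoint
#'
#' The checkpoint is an RDS file accompanied by a JSON sidecar recording
#' the network/training configuration, seed and extractor version.
#'
#' @param model a `swerad_cnn`.
#' @param path checkpoint path (`.rds`).
#' @return `path`, invisibly.
#' @export
write_cnn <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(net_cfg = unclass(model$net_cfg),
                  train_cfg = unclass(model$train_cfg),
                  best_epoch = model$best_epoch,
                  best_val_acc = model$best_val_acc,
                  extractor_version = model$extractor_version)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cnn
#' @export
read_cnn <- function(path) readRDS(path)
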