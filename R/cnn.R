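#' CNN hyperparameters
#'
#' The six tunable hyperparameters of the convolutional classifier:
#' learning rate, training epochs, the filter counts of the two convolution
#' layers, the dropout rate, and the width of the first dense layer.
#'
#' @param lr Adam learning rate (> 0).
#' @param ep number of training epochs (>= 1).
#' @param f_conv1,f_conv2 filter counts of the two 3x3 convolution layers.
#' @param d_drop1 dropout rate in `[0, 1)` applied between the dense layers.
#' @param out_dense1 width of the first dense layer.
#' @return an object of class `hyperparameters`.
#' @export
hyperparameters <- function(lr = 1e-3, ep = 100L, f_conv1 = 32L,
                            f_conv2 = 32L, d_drop1 = 0.2, out_dense1 = 64L) {
  if (!is.numeric(lr) || lr <= 0) stop_invalid("`lr` must be > 0")
  if (!is_count(ep)) stop_invalid("`ep` must be an integer >= 1")
  if (!is_count(f_conv1) || !is_count(f_conv2) || !is_count(out_dense1)) {
    stop_invalid("`f_conv1`, `f_conv2`, `out_dense1` must be integers >= 1")
  }
  if (!is.numeric(d_drop1) || d_drop1 < 0 || d_drop1 >= 1) {
    stop_invalid("`d_drop1` must be in [0, 1)")
  }
  structure(
    list(lr = lr, ep = as.integer(ep), f_conv1 = as.integer(f_conv1),
         f_conv2 = as.integer(f_conv2), d_drop1 = d_drop1,
         out_dense1 = as.integer(out_dense1)),
    class = "hyperparameters"
  )
}

#' @export
print.hyperparameters <- function(x, ...) {
  cat(sprintf("lr=%g ep=%d f_conv1=%d f_conv2=%d d_drop1=%g out_dense1=%d\n",
              x$lr, x$ep, x$f_conv1, x$f_conv2, x$d_drop1, x$out_dense1))
  invisible(x)
}

# im2col index map for a valid 3x3 convolution over an (h, w, C) tensor
# stored column-major. Row = output position (h fastest), column = kernel
# element (kernel row fastest, then kernel column, then channel).
im2col_index <- function(h, w, C, kh = 3L, kw = 3L) {
  oh <- h - kh + 1L
  ow <- w - kw + 1L
  i <- rep(seq_len(oh), times = ow)
  j <- rep(seq_len(ow), each = oh)
  idx <- matrix(0L, oh * ow, kh * kw * C)
  q <- 0L
  for (cc in seq_len(C)) {
    for (dj in seq_len(kw)) {
      for (di in seq_len(kh)) {
        q <- q + 1L
        idx[, q] <- (cc - 1L) * h * w + (j + dj - 2L) * h + (i + di - 1L)
      }
    }
  }
  idx
}

# 2x2 max-pooling index map over an (oh, ow) grid (floor division).
pool_index <- function(oh, ow) {
  po <- oh %/% 2L
  pw <- ow %/% 2L
  pi <- rep(seq_len(po), times = pw)
  pj <- rep(seq_len(pw), each = po)
  idx <- matrix(0L, po * pw, 4L)
  k <- 0L
  for (dj in 0:1) {
    for (di in 0:1) {
      k <- k + 1L
      idx[, k] <- (2L * pj - 2L + dj) * oh + (2L * pi - 1L + di)
    }
  }
  idx
}

# Extract patches for a batch: `xm` is (h*w*C, B) column-major; returns
# (P*B, Q) with rows ordered position-fastest, then sample.
extract_patches <- function(xm, idx_vec, P, Q, B) {
  xv <- xm[idx_vec, , drop = FALSE]            # (P*Q, B)
  dim(xv) <- c(P, Q, B)
  xv <- aperm(xv, c(1L, 3L, 2L))               # (P, B, Q)
  dim(xv) <- c(P * B, Q)
  xv
}

# Max pool an activation array (P, B, f) -> list(values (P', B, f), argmax).
pool_forward <- function(ya, pidx) {
  m <- ya[pidx[, 1L], , , drop = FALSE]
  am <- array(1L, dim = dim(m))
  for (k in 2:4) {
    cand <- ya[pidx[, k], , , drop = FALSE]
    sel <- cand > m
    m[sel] <- cand[sel]
    am[sel] <- k
  }
  list(values = m, argmax = am)
}

# Scatter pooled gradients back: dm (P', B, f) -> (P, B, f).
pool_backward <- function(dm, am, pidx, P) {
  d <- dim(dm)
  pp <- d[1L]
  pvec <- rep(seq_len(pp), times = d[2L] * d[3L])
  rows <- pidx[cbind(pvec, as.vector(am))]
  off <- rep(seq_len(d[2L] * d[3L]) - 1L, each = pp) * P
  dx <- numeric(P * d[2L] * d[3L])
  dx[rows + off] <- as.vector(dm)
  dim(dx) <- c(P, d[2L], d[3L])
  dx
}

# Geometry and index maps of the fixed layer stack for a given input shape.
cnn_geometry <- function(h = 12L, w = 32L, C = 1L, f1, f2) {
  if (h < 3L || w < 3L) stop_build("input too small for a 3x3 convolution")
  o1 <- c(h - 2L, w - 2L)
  p1 <- o1 %/% 2L
  if (any(p1 < 3L)) stop_build("spatial size collapses before second convolution")
  o2 <- p1 - 2L
  p2 <- o2 %/% 2L
  if (any(p2 < 1L)) stop_build("spatial size collapses after second pooling")
  list(
    h = h, w = w, C = C,
    o1 = o1, p1 = p1, o2 = o2, p2 = p2,
    P1 = prod(o1), P1p = prod(p1), P2 = prod(o2), P2p = prod(p2),
    n_flat = as.integer(prod(p2) * f2),
    idx1 = as.vector(im2col_index(h, w, C)),
    pidx1 = pool_index(o1[1L], o1[2L]),
    idx2 = as.vector(im2col_index(p1[1L], p1[2L], f1)),
    pidx2 = pool_index(o2[1L], o2[2L]),
    # full-convolution map for the gradient w.r.t. the second conv input:
    # pad o2 by 2 on each side, then valid 3x3 over f2 channels lands on p1
    idxb = as.vector(im2col_index(o2[1L] + 4L, o2[2L] + 4L, f2)),
    pad_idx = {
      hp <- o2[1L] + 4L
      i <- rep(seq_len(o2[1L]), times = o2[2L])
      j <- rep(seq_len(o2[2L]), each = o2[1L])
      base <- (j + 1L) * hp + (i + 2L)
      as.vector(outer(base, (seq_len(f2) - 1L) * hp * (o2[2L] + 4L), "+"))
    },
    pad_len = (o2[1L] + 4L) * (o2[2L] + 4L) * f2
  )
}

#' Number of trainable parameters of the CNN
#'
#' Closed-form count for the fixed layer stack: two valid 3x3 convolutions
#' with ReLU and 2x2 max-pooling, a flatten, a ReLU dense layer, dropout and
#' a softmax output. For the 12 x 32 activity images the flattened size is
#' `6 * f_conv2`.
#'
#' @param hyper a [hyperparameters()].
#' @param n_channels image depth (markers).
#' @param n_classes 2 or 3.
#' @return integer parameter count.
#' @export
n_parameters <- function(hyper, n_channels, n_classes) {
  g <- cnn_geometry(C = n_channels, f1 = hyper$f_conv1, f2 = hyper$f_conv2)
  9L * n_channels * hyper$f_conv1 + hyper$f_conv1 +
    9L * hyper$f_conv1 * hyper$f_conv2 + hyper$f_conv2 +
    g$n_flat * hyper$out_dense1 + hyper$out_dense1 +
    hyper$out_dense1 * n_classes + n_classes
}

cnn_init_params <- function(hyper, C, n_classes, n_flat) {
  he <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  list(
    W1 = he(9L * C, hyper$f_conv1, 9L * C), b1 = numeric(hyper$f_conv1),
    W2 = he(9L * hyper$f_conv1, hyper$f_conv2, 9L * hyper$f_conv1),
    b2 = numeric(hyper$f_conv2),
    W3 = he(n_flat, hyper$out_dense1, n_flat), b3 = numeric(hyper$out_dense1),
    W4 = he(hyper$out_dense1, n_classes, hyper$out_dense1),
    b4 = numeric(n_classes)
  )
}

# Forward pass on a batch matrix xm (h*w*C, B). Returns probabilities and,
# when `training`, the cache needed for backpropagation.
cnn_forward <- function(params, g, xm, B, dropout = 0, training = FALSE) {
  f1 <- ncol(params$W1)
  f2 <- ncol(params$W2)
  p1m <- extract_patches(xm, g$idx1, g$P1, 9L * g$C, B)
  y1 <- sweep(p1m %*% params$W1, 2L, params$b1, "+")
  a1 <- y1 * (y1 > 0)
  a1a <- array(a1, c(g$P1, B, f1))
  pool1 <- pool_forward(a1a, g$pidx1)
  x2m <- aperm(pool1$values, c(1L, 3L, 2L))    # (P1p, f1, B)
  dim(x2m) <- c(g$P1p * f1, B)
  p2m <- extract_patches(x2m, g$idx2, g$P2, 9L * f1, B)
  y2 <- sweep(p2m %*% params$W2, 2L, params$b2, "+")
  a2 <- y2 * (y2 > 0)
  a2a <- array(a2, c(g$P2, B, f2))
  pool2 <- pool_forward(a2a, g$pidx2)
  fm <- aperm(pool2$values, c(1L, 3L, 2L))     # (P2p, f2, B)
  dim(fm) <- c(g$n_flat, B)
  fmat <- t(fm)                                 # (B, n_flat)
  h <- sweep(fmat %*% params$W3, 2L, params$b3, "+")
  hr <- h * (h > 0)
  if (training && dropout > 0) {
    mask <- (matrix(stats::runif(length(hr)), nrow(hr)) >= dropout) / (1 - dropout)
  } else {
    mask <- NULL
  }
  z <- if (is.null(mask)) hr else hr * mask
  logits <- sweep(z %*% params$W4, 2L, params$b4, "+")
  lmax <- apply(logits, 1L, max)
  el <- exp(logits - lmax)
  probs <- el / rowSums(el)
  out <- list(probs = probs)
  if (training) {
    out$cache <- list(p1m = p1m, y1 = y1, pool1 = pool1, p2m = p2m, y2 = y2,
                      pool2 = pool2, fmat = fmat, h = h, mask = mask, z = z)
  }
  out
}

# Backward pass; returns gradients for all parameters.
cnn_backward <- function(params, g, cache, probs, y_onehot, B) {
  f1 <- ncol(params$W1)
  f2 <- ncol(params$W2)
  dlog <- (probs - y_onehot) / B
  gW4 <- crossprod(cache$z, dlog)
  gb4 <- colSums(dlog)
  dz <- dlog %*% t(params$W4)
  dhr <- if (is.null(cache$mask)) dz else dz * cache$mask
  dh <- dhr * (cache$h > 0)
  gW3 <- crossprod(cache$fmat, dh)
  gb3 <- colSums(dh)
  df <- dh %*% t(params$W3)                    # (B, n_flat)
  dfm <- t(df)
  dim(dfm) <- c(g$P2p, f2, B)
  dpool2 <- aperm(dfm, c(1L, 3L, 2L))          # (P2p, B, f2)
  da2 <- pool_backward(dpool2, cache$pool2$argmax, g$pidx2, g$P2)
  dy2 <- da2 * (array(cache$y2, c(g$P2, B, f2)) > 0)
  dy2m <- dy2
  dim(dy2m) <- c(g$P2 * B, f2)
  gW2 <- crossprod(cache$p2m, dy2m)
  gb2 <- colSums(dy2m)
  # gradient w.r.t. second conv input via full convolution of dy2
  dy2c <- aperm(dy2, c(1L, 3L, 2L))            # (P2, f2, B)
  dim(dy2c) <- c(g$P2 * f2, B)
  dpad <- matrix(0, g$pad_len, B)
  dpad[g$pad_idx, ] <- dy2c
  pbm <- extract_patches(dpad, g$idxb, g$P1p, 9L * f2, B)
  w2a <- array(params$W2, c(3L, 3L, f1, f2))
  w2r <- aperm(w2a[3:1, 3:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
  dim(w2r) <- c(9L * f2, f1)
  dx2 <- pbm %*% w2r                           # (P1p*B, f1)
  dpool1 <- array(dx2, c(g$P1p, B, f1))
  da1 <- pool_backward(dpool1, cache$pool1$argmax, g$pidx1, g$P1)
  dy1 <- da1 * (array(cache$y1, c(g$P1, B, f1)) > 0)
  dy1m <- dy1
  dim(dy1m) <- c(g$P1 * B, f1)
  gW1 <- crossprod(cache$p1m, dy1m)
  gb1 <- colSums(dy1m)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(state = state, params = params)
}

as_image_array <- function(x) {
  if (is.list(x) && !is.array(x)) {
    d <- dim(x[[1]])
    x <- array(unlist(x), dim = c(d, length(x)))
  }
  if (!is.array(x) || length(dim(x)) == 3L) {
    # a single image: promote to n = 1
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  }
  if (length(dim(x)) != 4L) {
    stop_invalid("images must be a 12 x w x C x n array (or list of images)")
  }
  x
}

#' Fit the convolutional activity-image classifier
#'
#' The central fitting function of the package. The network is the fixed
#' stack: 3x3 valid convolution (`f_conv1` filters, ReLU), 2x2 max-pooling,
#' 3x3 valid convolution (`f_conv2`, ReLU), 2x2 max-pooling, flatten, dense
#' (`out_dense1`, ReLU), dropout (`d_drop1`), dense softmax over the
#' classes. Training minimizes multi-class cross-entropy with Adam at
#' learning rate `lr` for `ep` epochs on shuffled mini-batches. Everything
#' runs in base R (im2col + BLAS matrix products) and is deterministic for
#' a fixed seed on single-threaded BLAS.
#'
#' @param x images: a `12 x 32 x C x n` array (or a list of
#'   `activity_image`s).
#' @param y factor of class labels, length n.
#' @param hyper a [hyperparameters()].
#' @param batch_size mini-batch size (default 32).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return an object of class `limb_cnn` with components `params`, `hyper`,
#'   `levels`, `history` (per-epoch training loss), `geometry`.
#' @seealso [predict.limb_cnn()], [evaluate()], [train_cnn()].
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_stroke = 4, n_control = 4,
#'                                      activities = "SC", seed = 3))
#' enc <- encode_cohort(coh, markers = "FN")
#' ds <- label_dataset(enc, "group2")
#' fit <- cnn_fit(ds$images, ds$labels, hyperparameters(ep = 5), seed = 1)
#' fit
#' }
#' @export
cnn_fit <- function(x, y, hyper = hyperparameters(), batch_size = 32L,
                    seed = 1L) {
  x <- as_image_array(x)
  y <- droplevels(as.factor(y))
  n <- dim(x)[4L]
  if (length(y) != n || n < 2L) stop_invalid("need labels for every image")
  if (nlevels(y) < 2L) stop_invalid("need at least two classes")
  stopifnot(inherits(hyper, "hyperparameters"))
  K <- nlevels(y)
  C <- dim(x)[3L]
  g <- cnn_geometry(dim(x)[1L], dim(x)[2L], C, hyper$f_conv1, hyper$f_conv2)
  xm_all <- x
  dim(xm_all) <- c(prod(dim(x)[1:3]), n)
  onehot <- diag(K)[as.integer(y), , drop = FALSE]

  with_seed(seed, {
    params <- cnn_init_params(hyper, C, K, g$n_flat)
    state <- list(t = 0L,
                  m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    losses <- numeric(hyper$ep)
    for (epoch in seq_len(hyper$ep)) {
      perm <- sample.int(n)
      bl <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        ii <- perm[start:min(start + batch_size - 1L, n)]
        B <- length(ii)
        fw <- cnn_forward(params, g, xm_all[, ii, drop = FALSE], B,
                          dropout = hyper$d_drop1, training = TRUE)
        pt <- fw$probs[cbind(seq_len(B), as.integer(y[ii]))]
        bl <- bl - sum(log(pmax(pt, 1e-12)))
        nb <- nb + B
        grads <- cnn_backward(params, g, fw$cache, fw$probs,
                              onehot[ii, , drop = FALSE], B)
        upd <- adam_step(state, params, grads, hyper$lr)
        state <- upd$state
        params <- upd$params
      }
      losses[epoch] <- bl / nb
    }
    structure(
      list(params = params, hyper = hyper, levels = levels(y),
           n_channels = C, n_classes = K, geometry = g,
           history = data.frame(epoch = seq_len(hyper$ep), loss = losses),
           n_train = n, call = match.call()),
      class = "limb_cnn"
    )
  })
}

#' Predict from a fitted activity-image CNN
#'
#' @param object a `limb_cnn` from [cnn_fit()].
#' @param newdata images (`12 x 32 x C x n` array, a single image, or list).
#' @param type `"prob"` for the softmax probability matrix (rows sum to 1),
#'   `"class"` for the argmax label.
#' @param ... unused.
#' @return probability matrix or factor of predicted classes.
#' @export
predict.limb_cnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as_image_array(newdata)
  if (dim(x)[3L] != object$n_channels) {
    stop_invalid("channel count differs from the fitted model")
  }
  n <- dim(x)[4L]
  dim(x) <- c(prod(dim(x)[1:3]), n)
  probs <- cnn_forward(object$params, object$geometry, x, n)$probs
  colnames(probs) <- object$levels
  if (type == "prob") return(probs)
  factor(object$levels[max.col(probs, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.limb_cnn <- function(x, ...) {
  h <- x$hyper
  g <- x$geometry
  cat("Activity-image CNN (", x$n_classes, " classes, ",
      x$n_channels, " marker channel", if (x$n_channels > 1) "s", ")\n", sep = "")
  cat(sprintf("  conv 3x3/%d -> pool -> conv 3x3/%d -> pool -> dense %d -> dropout %.3g -> softmax\n",
              h$f_conv1, h$f_conv2, h$out_dense1, h$d_drop1))
  cat(sprintf("  %d parameters | Adam lr=%g, %d epochs | final loss %.4f\n",
              n_parameters(h, x$n_channels, x$n_classes), h$lr, h$ep,
              utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' @export
summary.limb_cnn <- function(object, ...) {
  g <- object$geometry
  h <- object$hyper
  cat("Layer stack (input ", g$h, "x", g$w, "x", g$C, "):\n", sep = "")
  cat(sprintf("  conv1  3x3 valid, %3d filters, ReLU -> %dx%d\n",
              h$f_conv1, g$o1[1], g$o1[2]))
  cat(sprintf("  pool1  2x2 max                      -> %dx%d\n", g$p1[1], g$p1[2]))
  cat(sprintf("  conv2  3x3 valid, %3d filters, ReLU -> %dx%d\n",
              h$f_conv2, g$o2[1], g$o2[2]))
  cat(sprintf("  pool2  2x2 max                      -> %dx%d\n", g$p2[1], g$p2[2]))
  cat(sprintf("  flatten -> %d\n", g$n_flat))
  cat(sprintf("  dense  %d, ReLU; dropout %.3g\n", h$out_dense1, h$d_drop1))
  cat(sprintf("  dense  %d, softmax\n", object$n_classes))
  print(object)
  invisible(object)
}

#' @export
plot.limb_cnn <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "training cross-entropy",
                 main = "CNN training loss", ...)
  invisible(x)
}

#' Evaluate a fitted classifier on labelled images
#'
#' @param object a fitted model (`limb_cnn` or `limb_baseline`).
#' @param images images to score.
#' @param labels factor of true labels.
#' @param ... method-specific arguments.
#' @return an `eval_metrics` (see [classification_metrics()]).
#' @export
evaluate <- function(object, images, labels, ...) UseMethod("evaluate")

#' @rdname evaluate
#' @export
evaluate.limb_cnn <- function(object, images, labels, ...) {
  labels <- factor(as.character(labels), levels = object$levels)
  if (!length(labels)) stop_invalid("empty evaluation set")
  classification_metrics(labels, predict(object, images))
}

#' Train the CNN on a labelled dataset with an 80/20 split
#'
#' Convenience wrapper: builds a stratified (or participant-grouped) split,
#' fits [cnn_fit()] on the training portion and evaluates on the held-out
#' validation portion.
#'
#' @param dataset a `labeled_dataset` from [label_dataset()].
#' @param hyper a [hyperparameters()].
#' @param frac training fraction (default 0.8).
#' @param group_by `NULL` for recording-level stratification or
#'   `"participant"` to keep each participant on one side of the split.
#' @param split optionally a precomputed `data_split` (shared across models
#'   for paired comparisons).
#' @param seed integer seed (split, initialization, shuffling, dropout).
#' @param batch_size mini-batch size.
#' @return list of class `cnn_run`: `model`, `metrics` (validation),
#'   `split`.
#' @export
train_cnn <- function(dataset, hyper = hyperparameters(), frac = 0.8,
                      group_by = NULL, split = NULL, seed = 1L,
                      batch_size = 32L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (is.null(split)) {
    groups <- dataset_groups(dataset, group_by)
    split <- make_split(dataset$labels, groups = groups, frac = frac,
                        seed = seed)
  }
  xtr <- dataset$images[, , , split$train, drop = FALSE]
  xva <- dataset$images[, , , split$val, drop = FALSE]
  model <- cnn_fit(xtr, dataset$labels[split$train], hyper,
                   batch_size = batch_size, seed = seed)
  metrics <- evaluate(model, xva, dataset$labels[split$val])
  structure(list(model = model, metrics = metrics, split = split),
            class = "cnn_run")
}

#' @export
print.cnn_run <- function(x, ...) {
  print(x$model)
  cat(sprintf("Validation (n=%d): ", length(x$split$val)))
  print(x$metrics)
  invisible(x)
}

dataset_groups <- function(dataset, group_by) {
  if (is.null(group_by)) return(NULL)
  if (identical(group_by, "participant")) {
    return(dataset$meta$participant_id)
  }
  stop_invalid("`group_by` must be NULL or \"participant\"")
}
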