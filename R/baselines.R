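#' Flatten activity images to feature vectors
#'
#' Row-major flattening used by the flat baseline classifiers: time-major
#' within each feature row, the 12 feature rows stacked, channels last.
#'
#' @param images a `12 x w x C x n` array (or a single image / list).
#' @return an `n x (12 * w * C)` numeric matrix.
#' @export
flatten_images <- function(images) {
  x <- as_image_array(images)
  d <- dim(x)
  ap <- aperm(x, c(2L, 1L, 3L, 4L))
  dim(ap) <- c(d[1L] * d[2L] * d[3L], d[4L])
  t(ap)
}

# ---- random forest (Gini CART, bootstrap + random feature subsets) --------

rf_grow_tree <- function(x, y, K, max_depth, mtry, min_split = 2L) {
  p <- ncol(x)
  grow <- function(idx, depth) {
    counts <- tabulate(y[idx], K)
    n <- length(idx)
    if (depth >= max_depth || n < min_split || max(counts) == n) {
      return(list(leaf = TRUE, prob = counts / n))
    }
    feats <- sample.int(p, mtry)
    best <- NULL
    for (f in feats) {
      xf <- x[idx, f]
      o <- order(xf)
      xs <- xf[o]
      valid <- which(xs[-n] < xs[-1L])
      if (!length(valid)) next
      ys <- y[idx][o]
      cnt <- vapply(seq_len(K), function(k) cumsum(ys == k),
                    numeric(n))
      if (K == 1L) dim(cnt) <- c(n, 1L)
      tot <- cnt[n, ]
      i <- valid
      nl <- i
      nr <- n - i
      sl <- rowSums(cnt[i, , drop = FALSE]^2)
      cr <- sweep(-cnt[i, , drop = FALSE], 2L, tot, "+")
      sr <- rowSums(cr^2)
      score <- (nl - sl / nl) + (nr - sr / nr)
      b <- which.min(score)
      if (is.null(best) || score[b] < best$score) {
        best <- list(score = score[b], feat = f,
                     thr = (xs[i[b]] + xs[i[b] + 1L]) / 2)
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, prob = counts / n))
    go_left <- x[idx, best$feat] <= best$thr
    list(leaf = FALSE, feat = best$feat, thr = best$thr,
         left = grow(idx[go_left], depth + 1L),
         right = grow(idx[!go_left], depth + 1L))
  }
  grow(seq_len(nrow(x)), 0L)
}

rf_tree_predict <- function(node, x, rows, out) {
  if (node$leaf) {
    out[rows, ] <- matrix(node$prob, length(rows), length(node$prob),
                          byrow = TRUE)
    return(out)
  }
  go_left <- x[rows, node$feat] <= node$thr
  if (any(go_left)) out <- rf_tree_predict(node$left, x, rows[go_left], out)
  if (any(!go_left)) out <- rf_tree_predict(node$right, x, rows[!go_left], out)
  out
}

rf_fit <- function(x, y, n_trees = 100L, max_depth = 10L,
                   mtry = max(1L, floor(sqrt(ncol(x)))), seed = 1L) {
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  yi <- as.integer(y)
  n <- nrow(x)
  with_seed(seed, {
    trees <- lapply(seq_len(n_trees), function(i) {
      boot <- sample.int(n, n, replace = TRUE)
      rf_grow_tree(x[boot, , drop = FALSE], yi[boot], K, max_depth, mtry)
    })
    list(trees = trees, levels = levels(y), K = K)
  })
}

rf_predict <- function(fit, x) {
  n <- nrow(x)
  acc <- matrix(0, n, fit$K)
  out <- matrix(0, n, fit$K)
  for (tr in fit$trees) {
    acc <- acc + rf_tree_predict(tr, x, seq_len(n), out)
  }
  probs <- acc / length(fit$trees)
  colnames(probs) <- fit$levels
  probs
}

# ---- linear SVM (squared hinge, one-vs-rest, L-BFGS) ----------------------

svm_binary <- function(x, t, cost = 1, maxit = 300L) {
  p <- ncol(x)
  obj <- function(par) {
    w <- par[seq_len(p)]
    b <- par[p + 1L]
    m <- 1 - t * (drop(x %*% w) + b)
    h <- pmax(m, 0)
    0.5 * sum(w^2) + cost * sum(h^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]
    b <- par[p + 1L]
    m <- 1 - t * (drop(x %*% w) + b)
    h <- pmax(m, 0)
    coef <- -2 * cost * t * h
    c(w + drop(crossprod(x, coef)), sum(coef))
  }
  fit <- stats::optim(numeric(p + 1L), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1L])
}

svm_fit <- function(x, y, cost = 1) {
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  if (K == 2L) {
    m <- svm_binary(x, ifelse(y == levels(y)[2L], 1, -1), cost)
    list(models = list(m), levels = levels(y), K = K, binary = TRUE)
  } else {
    models <- lapply(levels(y), function(l) {
      svm_binary(x, ifelse(y == l, 1, -1), cost)
    })
    list(models = models, levels = levels(y), K = K, binary = FALSE)
  }
}

svm_decision <- function(fit, x) {
  if (fit$binary) {
    s <- drop(x %*% fit$models[[1]]$w) + fit$models[[1]]$b
    scores <- cbind(-s, s)
  } else {
    scores <- vapply(fit$models, function(m) {
      drop(x %*% m$w) + m$b
    }, numeric(nrow(x)))
  }
  colnames(scores) <- fit$levels
  scores
}

# ---- logistic regression (ridge multinomial via glmnet) -------------------

lr_fit <- function(x, y) {
  y <- droplevels(as.factor(y))
  fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
  lam <- 1 / nrow(x)
  fit <- glmnet::glmnet(x, y, family = fam, alpha = 0, lambda = lam,
                        standardize = FALSE)
  list(fit = fit, lambda = lam, levels = levels(y), K = nlevels(y))
}

lr_predict <- function(fit, x) {
  pr <- stats::predict(fit$fit, newx = x, type = "response", s = fit$lambda)
  if (fit$K == 2L) {
    probs <- cbind(1 - pr[, 1L], pr[, 1L])
  } else {
    probs <- pr[, , 1L]
  }
  colnames(probs) <- fit$levels
  probs
}

#' Train a flat baseline classifier on activity images
#'
#' The three comparison classifiers, all consuming the same flattened
#' normalized activity images as the CNN: `"RF"` a random forest with 100
#' trees and maximum depth 10; `"LSV"` a linear support-vector machine
#' (squared hinge, one-vs-rest, cost 1); `"LR"` multinomial logistic
#' regression (ridge, lambda = 1/n). The split protocol and metrics are
#' identical to [train_cnn()], so a shared `split` gives paired
#' comparisons.
#'
#' @param kind one of `"RF"`, `"LSV"`, `"LR"`.
#' @param dataset a `labeled_dataset`.
#' @param frac,group_by,split,seed as in [train_cnn()].
#' @param ... passed to the underlying fitter (e.g. `n_trees`, `max_depth`
#'   for RF).
#' @return list of class `limb_baseline`: `kind`, `model`, `metrics`
#'   (validation), `split`, `levels`.
#' @export
train_baseline <- function(kind, dataset, frac = 0.8, group_by = NULL,
                           split = NULL, seed = 1L, ...) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("RF", "LSV", "LR")) {
    stop_invalid("`kind` must be one of \"RF\", \"LSV\", \"LR\"")
  }
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (is.null(split)) {
    split <- make_split(dataset$labels, dataset_groups(dataset, group_by),
                        frac = frac, seed = seed)
  }
  xf <- flatten_images(dataset$images)
  xtr <- xf[split$train, , drop = FALSE]
  xva <- xf[split$val, , drop = FALSE]
  ytr <- droplevels(dataset$labels[split$train])
  yva <- factor(as.character(dataset$labels[split$val]), levels = levels(ytr))
  model <- switch(kind,
    RF = rf_fit(xtr, ytr, seed = seed, ...),
    LSV = svm_fit(xtr, ytr, ...),
    LR = lr_fit(xtr, ytr)
  )
  scores <- switch(kind,
    RF = rf_predict(model, xva),
    LSV = svm_decision(model, xva),
    LR = lr_predict(model, xva)
  )
  metrics <- classification_metrics(yva, scores)
  structure(list(kind = kind, model = model, metrics = metrics,
                 split = split, levels = levels(ytr)),
            class = "limb_baseline")
}

#' @rdname evaluate
#' @export
evaluate.limb_baseline <- function(object, images, labels, ...) {
  labels <- factor(as.character(labels), levels = object$levels)
  if (!length(labels)) stop_invalid("empty evaluation set")
  xf <- flatten_images(images)
  scores <- switch(object$kind,
    RF = rf_predict(object$model, xf),
    LSV = svm_decision(object$model, xf),
    LR = lr_predict(object$model, xf)
  )
  classification_metrics(labels, scores)
}

#' @export
print.limb_baseline <- function(x, ...) {
  cat(sprintf("Baseline %s | validation: ", x$kind))
  print(x$metrics)
  invisible(x)
}
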