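#' Search space for the six CNN hyperparameters
#'
#' Default bounds form the tightest hyper-rectangle containing every
#' optimum reported by the reference experiments: learning rate log-uniform
#' on `[1e-5, 1e-2]`, epochs on `[100, 300]`, both filter counts on
#' `[10, 100]`, dropout on `[0, 0.25]`, dense width on `[10, 100]`.
#'
#' @param lr,ep,f_conv1,f_conv2,d_drop1,out_dense1 length-2 numeric bounds
#'   (lower, upper). `ep`, `f_conv1`, `f_conv2`, `out_dense1` are integer
#'   dimensions; `lr` is sampled on a log scale.
#' @return an object of class `search_space`.
#' @export
search_space <- function(lr = c(1e-5, 1e-2), ep = c(100L, 300L),
                         f_conv1 = c(10L, 100L), f_conv2 = c(10L, 100L),
                         d_drop1 = c(0, 0.25), out_dense1 = c(10L, 100L)) {
  dims <- list(
    lr = list(type = "log", lower = lr[1], upper = lr[2]),
    ep = list(type = "int", lower = ep[1], upper = ep[2]),
    f_conv1 = list(type = "int", lower = f_conv1[1], upper = f_conv1[2]),
    f_conv2 = list(type = "int", lower = f_conv2[1], upper = f_conv2[2]),
    d_drop1 = list(type = "num", lower = d_drop1[1], upper = d_drop1[2]),
    out_dense1 = list(type = "int", lower = out_dense1[1], upper = out_dense1[2])
  )
  for (nm in names(dims)) {
    d <- dims[[nm]]
    if (!is.numeric(c(d$lower, d$upper)) || d$lower >= d$upper) {
      stop_invalid(paste0("dimension ", nm, ": lower must be < upper"))
    }
    if (d$type == "log" && d$lower <= 0) {
      stop_invalid("log-uniform dimension needs positive bounds")
    }
  }
  structure(dims, class = "search_space")
}

# unit-cube encoding ---------------------------------------------------------

space_encode <- function(space, h) {
  vapply(names(space), function(nm) {
    d <- space[[nm]]
    x <- h[[nm]]
    if (d$type == "log") {
      (log(x) - log(d$lower)) / (log(d$upper) - log(d$lower))
    } else {
      (x - d$lower) / (d$upper - d$lower)
    }
  }, numeric(1))
}

space_decode <- function(space, u) {
  u <- unname(u)
  vals <- lapply(seq_along(space), function(k) {
    d <- space[[k]]
    x <- switch(d$type,
      log = exp(log(d$lower) + u[k] * (log(d$upper) - log(d$lower))),
      int = round(d$lower + u[k] * (d$upper - d$lower)),
      num = d$lower + u[k] * (d$upper - d$lower)
    )
    if (d$type == "int") as.integer(x) else x
  })
  names(vals) <- names(space)
  hyperparameters(lr = vals$lr, ep = vals$ep, f_conv1 = vals$f_conv1,
                  f_conv2 = vals$f_conv2, d_drop1 = vals$d_drop1,
                  out_dense1 = vals$out_dense1)
}

# GP machinery (squared-exponential kernel, unit signal variance on
# standardized objective values, scalar lengthscale + noise fitted by
# marginal likelihood) -------------------------------------------------------

gp_kernel <- function(x1, x2, ell) {
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  exp(-0.5 * pmax(d2, 0) / ell^2)
}

gp_fit <- function(x, y) {
  mu <- mean(y)
  sdv <- stats::sd(y)
  if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
  ys <- (y - mu) / sdv
  nll <- function(par) {
    ell <- exp(par[1])
    sn2 <- exp(par[2])
    kk <- gp_kernel(x, x, ell) + diag(sn2 + 1e-8, nrow(x))
    ch <- tryCatch(chol(kk), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    0.5 * sum(ys * alpha) + sum(log(diag(ch)))
  }
  opt <- stats::optim(c(log(0.5), log(0.1)), nll, method = "L-BFGS-B",
                      lower = log(c(0.05, 1e-6)), upper = log(c(3, 1)))
  ell <- exp(opt$par[1])
  sn2 <- exp(opt$par[2])
  kk <- gp_kernel(x, x, ell) + diag(sn2 + 1e-8, nrow(x))
  ch <- chol(kk)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  list(x = x, mu = mu, sdv = sdv, ell = ell, chol = ch, alpha = alpha)
}

gp_predict <- function(gp, xnew) {
  ks <- gp_kernel(xnew, gp$x, gp$ell)
  mean_s <- ks %*% gp$alpha
  v <- forwardsolve(t(gp$chol), t(ks))
  var_s <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = gp$mu + gp$sdv * drop(mean_s),
       sd = gp$sdv * sqrt(var_s))
}

expected_improvement <- function(mean, sd, best) {
  z <- (best - mean) / sd
  (best - mean) * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Gaussian-process Bayesian optimization of the CNN hyperparameters
#'
#' Minimizes `1 - validation AUC` over the six-dimensional hyperparameter
#' space. The first `n_initial` configurations are drawn uniformly at
#' random (log-uniformly for the learning rate); each later configuration
#' maximizes the expected improvement of a Gaussian-process surrogate
#' (squared-exponential kernel, lengthscale and noise refit by marginal
#' likelihood each call) over a random candidate set. Every objective
#' evaluation retrains the CNN from scratch with a call-indexed seed, so
#' runs are reproducible.
#'
#' @param dataset a `labeled_dataset`.
#' @param space a [search_space()].
#' @param n_calls total number of objective evaluations (>= 5, default 40).
#' @param n_initial random configurations before the GP starts (default 10).
#' @param group_by,frac split protocol (the split is frozen across calls).
#' @param seed integer seed.
#' @param batch_size CNN mini-batch size.
#' @param n_candidates candidate points scored per EI step.
#' @return an object of class `hyperopt_result`: `best_hyper`,
#'   `best_objective` (= min over the history), `best_auc`, and `history`
#'   (one row per call with the six hyperparameters, `objective`, `auc`).
#' @export
optimize_hyperparameters <- function(dataset, space = search_space(),
                                     n_calls = 40L, n_initial = 10L,
                                     group_by = NULL, frac = 0.8, seed = 1L,
                                     batch_size = 32L, n_candidates = 500L) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(space, "search_space"))
  if (!is_count(n_calls, 5L)) stop_invalid("`n_calls` must be an integer >= 5")
  n_initial <- min(n_initial, n_calls)
  d <- length(space)
  split <- make_split(dataset$labels, dataset_groups(dataset, group_by),
                      frac = frac, seed = seed)
  call_seeds <- derive_seeds(seed, n_calls)

  objective <- function(h, k) {
    run <- train_cnn(dataset, h, split = split, seed = call_seeds[k],
                     batch_size = batch_size)
    run$metrics$auc
  }

  u_hist <- matrix(0, n_calls, d)
  hypers <- vector("list", n_calls)
  obj <- numeric(n_calls)
  auc <- numeric(n_calls)

  u_init <- with_seed(seed, matrix(stats::runif(n_initial * d), n_initial, d))
  for (k in seq_len(n_calls)) {
    if (k <= n_initial) {
      u <- u_init[k, ]
    } else {
      gp <- gp_fit(u_hist[seq_len(k - 1L), , drop = FALSE], obj[seq_len(k - 1L)])
      u <- with_seed(call_seeds[k] %% .Machine$integer.max, {
        cand <- matrix(stats::runif(n_candidates * d), n_candidates, d)
        ubest <- u_hist[which.min(obj[seq_len(k - 1L)]), ]
        local_c <- matrix(pmin(1, pmax(0,
          rep(ubest, each = 50) + stats::rnorm(50 * d, sd = 0.05))), 50, d)
        cand <- rbind(cand, local_c)
        pr <- gp_predict(gp, cand)
        ei <- expected_improvement(pr$mean, pr$sd, min(obj[seq_len(k - 1L)]))
        cand[which.max(ei), ]
      })
    }
    u_hist[k, ] <- u
    hypers[[k]] <- space_decode(space, u)
    auc[k] <- objective(hypers[[k]], k)
    obj[k] <- 1 - auc[k]
  }

  best <- which.min(obj)
  history <- cbind(
    data.frame(call = seq_len(n_calls)),
    do.call(rbind, lapply(hypers, function(h) as.data.frame(unclass(h)))),
    data.frame(objective = obj, auc = auc)
  )
  structure(
    list(best_hyper = hypers[[best]], best_objective = obj[best],
         best_auc = auc[best], best_call = best, history = history,
         space = space, split = split),
    class = "hyperopt_result"
  )
}

#' @export
print.hyperopt_result <- function(x, ...) {
  cat(sprintf("GP hyperparameter search: %d calls, best 1-AUC = %.4f (call %d)\n",
              nrow(x$history), x$best_objective, x$best_call))
  cat("best: ")
  print(x$best_hyper)
  invisible(x)
}

#' @export
plot.hyperopt_result <- function(x, ...) {
  graphics::plot(x$history$call, cummin(x$history$objective), type = "s",
                 xlab = "call", ylab = "best 1 - AUC so far",
                 main = "GP hyperparameter search convergence", ...)
  graphics::points(x$history$call, x$history$objective, pch = 20)
  invisible(x)
}
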