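test_that("layer geometry and parameter count match the closed form", {
  h <- hyperparameters(f_conv1 = 10, f_conv2 = 10, out_dense1 = 10)
  g <- actimage:::cnn_geometry(12L, 32L, 1L, h$f_conv1, h$f_conv2)
  # (32,12) -> conv (30,10) -> pool (15,5) -> conv (13,3) -> pool (6,1)
  expect_identical(g$o1, c(10L, 30L))
  expect_identical(g$p1, c(5L, 15L))
  expect_identical(g$o2, c(3L, 13L))
  expect_identical(g$p2, c(1L, 6L))
  expect_identical(g$n_flat, 60L)

  # hand-computed total: 3*3*C*f1+f1 + 3*3*f1*f2+f2 + 60*10+10 + 10*3+3
  expect_identical(n_parameters(h, n_channels = 1, n_classes = 3),
                   (9 * 1 * 10 + 10) + (9 * 10 * 10 + 10) +
                     (60 * 10 + 10) + (10 * 3 + 3))

  # too-small input collapses before the stack completes
  expect_error(actimage:::cnn_geometry(6L, 6L, 1L, 4L, 4L),
               class = "actimage_build_error")
})

test_that("softmax output is a probability distribution over classes", {
  ds <- tiny_group2()
  fit <- cnn_fit(ds$images[, , , 1:10], factor(rep(c("a", "b", "c"), len = 10)),
                 quiet_hyper(ep = 2), seed = 1)
  probs <- predict(fit, ds$images[, , , 11:20])
  expect_identical(dim(probs), c(10L, 3L))
  expect_equal(rowSums(probs), rep(1, 10), tolerance = 1e-6)
  cls <- predict(fit, ds$images[, , , 11:20], type = "class")
  expect_s3_class(cls, "factor")
  expect_identical(levels(cls), c("a", "b", "c"))
})

test_that("backpropagation matches numerical gradients", {
  set.seed(99)
  h <- hyperparameters(f_conv1 = 3, f_conv2 = 4, d_drop1 = 0, out_dense1 = 5)
  C <- 2L; K <- 3L; B <- 3L
  g <- actimage:::cnn_geometry(12L, 32L, C, h$f_conv1, h$f_conv2)
  params <- actimage:::cnn_init_params(h, C, K, g$n_flat)
  x <- matrix(runif(12 * 32 * C * B), ncol = B)
  y <- c(1L, 3L, 2L)
  onehot <- diag(K)[y, ]
  fw <- actimage:::cnn_forward(params, g, x, B, training = TRUE)
  gr <- actimage:::cnn_backward(params, g, fw$cache, fw$probs, onehot, B)
  loss <- function(p) {
    pr <- actimage:::cnn_forward(p, g, x, B)$probs
    -mean(log(pr[cbind(seq_len(B), y)]))
  }
  eps <- 1e-6
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(5, length(params[[nm]])))) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss(up) - loss(dn)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training is reproducible and has enough capacity to overfit", {
  ds <- tiny_group2()
  idx <- c(1:10, seq(dim(ds$images)[4] - 9, dim(ds$images)[4]))
  x <- ds$images[, , , idx]
  y <- ds$labels[idx]

  f1 <- cnn_fit(x, y, quiet_hyper(ep = 10), seed = 42)
  f2 <- cnn_fit(x, y, quiet_hyper(ep = 10), seed = 42)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)

  # capacity check: a 20-example dataset is memorized within 300 epochs
  fit <- cnn_fit(x, y, hyperparameters(ep = 300, f_conv1 = 8, f_conv2 = 8,
                                       out_dense1 = 16, d_drop1 = 0),
                 seed = 7)
  acc <- mean(predict(fit, x, type = "class") == y)
  expect_gte(acc, 0.99)
})

test_that("shuffled labels destroy the class signal", {
  ds <- tiny_group2()
  shuffled <- ds
  shuffled$labels <- actimage:::with_seed(5, sample(ds$labels))
  run <- train_cnn(shuffled, quiet_hyper(ep = 30), seed = 5)
  majority <- max(table(ds$labels)) / length(ds$labels)
  # accuracy near the majority rate: within 3 binomial SEs
  n_val <- length(run$split$val)
  expect_lte(run$metrics$accuracy,
             majority + 3 * sqrt(majority * (1 - majority) / n_val))
})

test_that("train_cnn errors when a class cannot appear in both partitions", {
  ds <- tiny_group2()
  one <- ds
  keep <- which(one$labels == "G1")
  one$labels <- droplevels(one$labels[keep])
  one$images <- one$images[, , , keep, drop = FALSE]
  one$meta <- one$meta[keep, ]
  expect_error(train_cnn(one, quiet_hyper(ep = 1)),
               class = "actimage_split_error")
})
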