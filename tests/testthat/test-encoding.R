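test_that("displacement, difference rates and normalization match hand arithmetic", {
  expect_equal(displacement_series(c(0, 1, 3, 2)), c(1, 2, 1))
  expect_identical(displacement_series(rep(5, 10)), numeric(9))
  expect_error(displacement_series(1), class = "actimage_invalid_argument")

  expect_equal(difference_rate(c(1, 2, 4), 0.5), c(2, 4))
  expect_identical(difference_rate(rep(3, 5), 0.1), numeric(4))
  expect_error(difference_rate(c(1, 2), 0), class = "actimage_invalid_argument")

  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_identical(minmax_normalize(c(5, 5, 5)), c(0, 0, 0))
})

test_that("chained differences equal a one-shot higher-order oracle", {
  set.seed(11)
  for (rep in 1:25) {
    d <- rnorm(sample(10:64, 1))
    tp <- runif(1, 0.005, 0.1)
    v <- difference_rate(d, tp)
    a <- difference_rate(v, tp)
    j <- difference_rate(a, tp)
    # independent brute-force triple difference
    expect_equal(j, diff(diff(diff(d))) / tp^3, tolerance = 1e-9)
    expect_equal(abs(diff(d)), displacement_series(d), tolerance = 1e-12)
  }

  set.seed(12)
  x <- rnorm(50)
  a <- runif(1, 0.5, 3); b <- rnorm(1)
  expect_equal(minmax_normalize(a * x + b), minmax_normalize(x),
               tolerance = 1e-12)
})

test_that("feature blocks have the 12 x 32 geometry and degenerate rules", {
  rec <- unify_side(generate_recording("SC", "right", class_effect(),
                                       seed = 3, rest_padding = c(0, 0)))
  block <- encode_marker(rec, "FN")
  expect_identical(dim(block), c(12L, 32L))
  expect_true(all(block >= 0 & block <= 1))
  expect_identical(rownames(block)[1:4], c("d_x", "v_x", "a_x", "j_x"))

  # a stationary marker encodes to 12 all-zero rows
  still <- recording(list(ST = matrix(2, 100, 3,
                                      dimnames = list(NULL, c("x", "y", "z")))),
                     0.01)
  expect_identical(encode_marker(still, "ST"),
                   matrix(0, 12, 32, dimnames = list(rownames(block), NULL)))
})

test_that("activity images stack marker channels in order", {
  rec <- unify_side(generate_recording("LC", "right", paretic_effect(),
                                       seed = 5, rest_padding = c(0, 0)))
  one <- assemble_image(rec, "FN")
  expect_identical(dim(one), c(12L, 32L, 1L))
  four <- assemble_image(rec, upper_limb_markers())
  expect_identical(dim(four), c(12L, 32L, 4L))
  expect_equal(four[, , 1], one[, , 1], ignore_attr = TRUE)

  perm <- c("MPH", "FN", "ACR", "LEP")
  img_p <- assemble_image(rec, perm)
  expect_equal(img_p[, , match(upper_limb_markers(), perm)],
               four[, , ], ignore_attr = TRUE)

  expect_error(assemble_image(rec, c("FN", "XX")),
               class = "actimage_invalid_argument")
  expect_error(assemble_image(rec, character(0)),
               class = "actimage_invalid_argument")
})

test_that("mirror-pair recordings encode to identical images", {
  for (s in c(2, 14, 31)) {
    rr <- generate_recording("DG", "right", paretic_effect(), seed = s)
    rl <- generate_recording("DG", "left", paretic_effect(), seed = s)
    expect_equal(encode_recording(rr), encode_recording(rl),
                 ignore_attr = TRUE)
  }
})

test_that("time reversal approximately reverses the displacement rows", {
  rec <- unify_side(generate_recording("SC", "right", class_effect(),
                                       seed = 9, rest_padding = c(0, 0)))
  revd <- rec
  revd$markers <- lapply(rec$markers, function(p) p[nrow(p):1, , drop = FALSE])
  b1 <- encode_marker(rec, "FN")
  b2 <- encode_marker(revd, "FN")
  # displacement rows (1, 5, 9); drop the padded left edge on both sides
  for (r in c(1, 5, 9)) {
    expect_equal(b1[r, 2:32], rev(b2[r, 2:32]), tolerance = 1e-8)
  }
})

test_that("the per-recording encoding pipeline is deterministic", {
  rec <- generate_recording("SC", "right", nonparetic_effect(), seed = 13)
  expect_identical(encode_recording(rec), encode_recording(rec))
})
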