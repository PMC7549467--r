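test_that("movement bounds recover the generator's true window", {
  # tremor-free recordings with known 0.5-1.0 s rest padding at 100 Hz
  for (s in 1:25) {
    rec <- generate_recording("SC", "right",
      class_effect(1.4, 0.7, 2, tremor_amplitude = 0,
                   proximal_compensation = 0.2), seed = s)
    b <- detect_movement_bounds(rec)
    expect_lte(abs(b$start - rec$truth$start), 5)
    expect_lte(abs(b$end - rec$truth$end), 5)
  }
})

test_that("flat recordings fail detection; unpadded ones keep the full range", {
  p <- matrix(1, 300, 3, dimnames = list(NULL, c("x", "y", "z")))
  flat <- recording(list(FNR = p), 0.01)
  expect_error(detect_movement_bounds(flat),
               class = "actimage_detection_failure")

  rec <- generate_recording("SC", "right", class_effect(), seed = 2,
                            rest_padding = c(0, 0))
  b <- detect_movement_bounds(rec)
  n <- nrow(rec$markers$FNR)
  expect_lte(b$start, 6)
  expect_gte(b$end, n - 5)
})

test_that("clip truncates inclusively and re-detection is stable", {
  rec <- generate_recording("SC", "right", class_effect(), seed = 4)
  n <- nrow(rec$markers$FNR)
  ident <- clip(rec, clip_bounds(1, n))
  expect_identical(ident$markers, rec$markers)

  small <- clip(rec, clip_bounds(11, 21))
  expect_equal(nrow(small$markers$FNR), 11)

  expect_error(clip(rec, clip_bounds(10, n + 5)),
               class = "actimage_invalid_argument")
  expect_error(clip_bounds(5, 5), class = "actimage_invalid_argument")

  # detector applied to its own output keeps nearly the full range
  once <- clip(rec, detect_movement_bounds(rec))
  again <- detect_movement_bounds(once)
  n1 <- nrow(once$markers$FNR)
  expect_lte(again$start, 6)
  expect_gte(again$end, n1 - 5)
})

test_that("unify_side mirrors left recordings and strips side suffixes", {
  rr <- generate_recording("LC", "right", class_effect(), seed = 6)
  ur <- unify_side(rr)
  expect_identical(names(ur$markers), upper_limb_markers())
  expect_identical(ur$markers$FN, rr$markers$FNR)

  rl <- generate_recording("LC", "left", class_effect(), seed = 6)
  ul <- unify_side(rl)
  expect_equal(ul$markers, ur$markers)

  # second application is the identity
  expect_identical(unify_side(ul)$markers, ul$markers)

  mixed <- recording(list(FNL = rr$markers$FNR, LEPR = rr$markers$LEPR), 0.01)
  expect_error(unify_side(mixed), class = "actimage_invalid_argument")
})

test_that("linear resampling matches a brute-force interpolation oracle", {
  ramp <- seq(0, 99)
  out <- resample_linear(ramp, 32)
  expect_equal(out, seq(0, 99, length.out = 32))

  x32 <- rnorm(32)
  expect_equal(resample_linear(x32, 32), x32)

  set.seed(123)
  for (rep in 1:20) {
    x <- rnorm(sample(5:200, 1))
    n_out <- sample(2:64, 1)
    got <- resample_linear(x, n_out)
    # independent two-point interpolation oracle
    q <- seq(0, length(x) - 1, length.out = n_out)
    lo <- pmin(floor(q) + 1, length(x))
    hi <- pmin(lo + 1, length(x))
    w <- q - (lo - 1)
    expected <- x[lo] * (1 - w) + x[hi] * w
    expect_equal(got, expected, tolerance = 1e-12)
    expect_gte(min(got), min(x))
    expect_lte(max(got), max(x))
  }

  expect_error(resample_linear(1), class = "actimage_invalid_argument")
})
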