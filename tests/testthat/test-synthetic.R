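test_that("minimum-jerk profile satisfies boundary conditions and peak speed", {
  expect_identical(min_jerk_profile(0, 1, 32), numeric(32))

  x <- min_jerk_profile(120, 1.4, 200)
  expect_equal(x[1], 0)
  expect_equal(x[200], 120)
  expect_true(all(diff(x) >= 0))

  # peak speed oracle: brute-force maximum of the analytic velocity
  # 30*(tau^2 - 2 tau^3 + tau^4) * A / D on a dense grid
  tau <- seq(0, 1, length.out = 20001)
  v_peak_oracle <- max(30 * (tau^2 - 2 * tau^3 + tau^4)) * 120 / 1.4
  expect_equal(v_peak_oracle, 1.875 * 120 / 1.4, tolerance = 1e-8)
  n <- 4001
  xs <- min_jerk_profile(120, 1.4, n)
  v_fd <- max(abs(diff(xs))) / (1.4 / (n - 1))
  expect_equal(v_fd, v_peak_oracle, tolerance = 1e-4)

  expect_error(min_jerk_profile(1, 0, 10), class = "actimage_invalid_argument")
  expect_error(min_jerk_profile(1, 1, 1), class = "actimage_invalid_argument")
})

test_that("class_effect validates its fields and the null effect exists", {
  e <- class_effect()
  expect_s3_class(e, "class_effect")
  expect_true(actimage:::is_null_effect(e))
  expect_error(class_effect(duration_factor = 0), class = "actimage_invalid_argument")
  expect_error(class_effect(peak_velocity_factor = 0), class = "actimage_invalid_argument")
  expect_error(class_effect(n_submovements = 0), class = "actimage_invalid_argument")
  expect_error(class_effect(tremor_amplitude = -1), class = "actimage_invalid_argument")
  expect_error(class_effect(markers = "XYZ"), class = "actimage_invalid_argument")
})

test_that("generate_recording is deterministic and mirror-symmetric", {
  r1 <- generate_recording("SC", "right", paretic_effect(), seed = 3)
  r2 <- generate_recording("SC", "right", paretic_effect(), seed = 3)
  expect_identical(r1$markers, r2$markers)

  # left/right mirror pair: lateral axis sign-flipped, others identical
  rr <- generate_recording("DG", "right", nonparetic_effect(), seed = 9)
  rl <- generate_recording("DG", "left", nonparetic_effect(), seed = 9)
  for (m in upper_limb_markers()) {
    pr <- rr$markers[[paste0(m, "R")]]
    pl <- rl$markers[[paste0(m, "L")]]
    expect_identical(pl[, "x"], -pr[, "x"])
    expect_identical(pl[, c("y", "z")], pr[, c("y", "z")])
  }

  expect_error(generate_recording("XX", "right"), class = "actimage_invalid_argument")
})

test_that("sub-movement composition raises the finite-difference jerk cost", {
  smooth <- generate_recording("SC", "right",
    class_effect(n_submovements = 1), seed = 5)
  segmented <- generate_recording("SC", "right",
    class_effect(n_submovements = 3), seed = 5)
  y1 <- smooth$markers$FNR[, "y"]
  y3 <- segmented$markers$FNR[, "y"]
  j1 <- mean_squared_jerk(y1, smooth$sample_interval)
  j3 <- mean_squared_jerk(y3, segmented$sample_interval)
  expect_lt(j1, j3)
})

test_that("effect factors act monotonically on duration and peak speed", {
  # movement time grows with duration_factor (measured after clipping)
  durs <- sapply(c(1, 1.3, 1.6), function(df) {
    r <- generate_recording("SC", "right", class_effect(duration_factor = df),
                            seed = 17)
    b <- detect_movement_bounds(r)
    (b$end - b$start) * r$sample_interval
  })
  expect_true(all(diff(durs) > 0))

  # peak hand speed falls with peak_velocity_factor (noise-free recordings)
  peaks <- sapply(c(1, 0.8, 0.6), function(pv) {
    r <- generate_recording("SC", "right",
                            class_effect(peak_velocity_factor = pv), seed = 17)
    max(sqrt(rowSums(diff(r$markers$FNR)^2))) / r$sample_interval
  })
  expect_true(all(diff(peaks) < 0))
})

test_that("generate_cohort obeys the cohort arithmetic and role tagging", {
  coh <- generate_cohort(cohort_config(n_stroke = 2, n_control = 1, seed = 2))
  expect_equal(nrow(coh$meta), (2 * 2 + 1 * 2) * 3)
  expect_equal(sum(coh$meta$role == "paresis"), 2 * 3)
  expect_setequal(unique(coh$meta$group), c("G1", "G2"))

  # each stroke participant has exactly one paretic limb
  g1 <- coh$meta[coh$meta$group == "G1", ]
  per <- tapply(g1$role, g1$participant_id, function(r) sort(unique(r)))
  for (p in names(per)) expect_identical(per[[p]], c("non-paresis", "paresis"))

  small <- generate_cohort(cohort_config(n_stroke = 0, n_control = 1,
                                         activities = "DG", seed = 4))
  expect_equal(nrow(small$meta), 2)
  expect_true(all(small$meta$group == "G2"))

  # determinism: identical config + seed gives identical cohorts
  coh2 <- generate_cohort(cohort_config(n_stroke = 2, n_control = 1, seed = 2))
  expect_identical(lapply(coh$recordings, `[[`, "markers"),
                   lapply(coh2$recordings, `[[`, "markers"))
  expect_identical(coh$meta, coh2$meta)
})
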