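# Build a labelling fixture from cohort metadata without paying for
# trajectory encoding: the labelling rules depend only on the metadata.
fake_encoded <- function(meta) {
  structure(list(images = array(0, c(12, 32, 1, nrow(meta))),
                 markers = "FN", meta = meta),
            class = "encoded_cohort")
}

cohort_meta <- function(n_stroke, n_control, n_act) {
  acts <- activity_codes()[seq_len(n_act)]
  rows <- list()
  for (p in seq_len(n_stroke)) {
    for (role in c("paresis", "non-paresis")) {
      for (a in acts) {
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = sprintf("S%02d", p), group = "G1",
          limb = "R", role = role, activity = a)
      }
    }
  }
  for (p in seq_len(n_control)) {
    for (role in c("left", "right")) {
      for (a in acts) {
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = sprintf("C%02d", p), group = "G2",
          limb = "R", role = role, activity = a)
      }
    }
  }
  do.call(rbind, rows)
}

test_that("labelings obey the class-count arithmetic for any cohort size", {
  set.seed(20)
  for (rep in 1:8) {
    ns <- sample(0:6, 1)
    nc <- sample(1:6, 1)
    na <- sample(1:3, 1)
    enc <- fake_encoded(cohort_meta(ns, nc, na))
    l3 <- label_dataset(enc, "limb3")
    expect_equal(unname(table(l3$labels)["HUL"]), nc * 2 * na,
                 ignore_attr = TRUE)
    expect_equal(unname(table(l3$labels)["NPUL"]), ns * na, ignore_attr = TRUE)
    expect_equal(unname(table(l3$labels)["PUL"]), ns * na, ignore_attr = TRUE)
    l2 <- label_dataset(enc, "group2")
    expect_equal(sum(l2$labels == "G1"), 2 * sum(l3$labels == "PUL"))
    expect_equal(sum(l2$labels == "G2"), sum(l3$labels == "HUL"))
  }

  empty <- label_dataset(fake_encoded(cohort_meta(1, 1, 1)[0, ]), "limb3")
  expect_length(empty$labels, 0)

  bad <- cohort_meta(1, 1, 1)
  bad$role[2] <- NA
  expect_error(label_dataset(fake_encoded(bad), "limb3"),
               class = "actimage_invalid_argument")
})

test_that("channel subsetting equals re-encoding with fewer markers", {
  coh <- generate_cohort(cohort_config(n_stroke = 1, n_control = 1,
                                       activities = "SC", seed = 5))
  full <- label_dataset(encode_cohort(coh), "group2")
  two <- subset_channels(full, c("LEP", "MPH"))
  direct <- label_dataset(encode_cohort(coh, markers = c("LEP", "MPH")),
                          "group2")
  expect_equal(two$images, direct$images)
  expect_error(subset_channels(full, "XXX"),
               class = "actimage_invalid_argument")
})

test_that("ablation reports have one row per marker set and model on a shared split", {
  ds <- tiny_group2()
  rep1 <- run_ablation(ds, "group2", marker_sets = list("FN", c("LEP", "MPH")),
                       hyper = quiet_hyper(ep = 5), seed = 3)
  expect_s3_class(rep1, "ablation_report")
  expect_equal(nrow(rep1), 2 * 4)
  expect_setequal(unique(rep1$model), c("CNN", "RF", "LSV", "LR"))
  expect_equal(unique(rep1$n_train) + unique(rep1$n_val), length(ds$labels))

  # regeneration with the same seed is identical
  rep2 <- run_ablation(ds, "group2", marker_sets = list("FN", c("LEP", "MPH")),
                       hyper = quiet_hyper(ep = 5), seed = 3)
  expect_identical(rep1, rep2)

  expect_error(run_ablation(ds, "group2", marker_sets = list("BAD")),
               class = "actimage_invalid_argument")
})
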