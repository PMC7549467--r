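# Shared fixtures, built in code and memoized for the test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Small strong-effect cohort: 4 stroke + 3 control participants, 2 activities.
tiny_cohort <- function() {
  memo("tiny_cohort", generate_cohort(
    cohort_config(n_stroke = 4, n_control = 3, activities = c("SC", "DG"),
                  seed = 7)
  ))
}

tiny_group2 <- function() {
  memo("tiny_group2",
       label_dataset(encode_cohort(tiny_cohort()), "group2"))
}

# Full study-shaped default cohort (324 recordings), encoded with all four
# markers; shared by the acceptance criteria.
default_encoded <- function() {
  memo("default_encoded", encode_cohort(generate_cohort(cohort_config(seed = 11))))
}

# Mean squared jerk of a position series by plain finite differences:
# an oracle independent of the package's feature code.
mean_squared_jerk <- function(p, tt) {
  mean((diff(p, differences = 3) / tt^3)^2)
}

quiet_hyper <- function(ep = 20) {
  hyperparameters(ep = ep, f_conv1 = 8, f_conv2 = 8, out_dense1 = 16,
                  d_drop1 = 0.1)
}
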