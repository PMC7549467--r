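#' Per-axis displacement series
#'
#' Displacement is the distance between subsequent marker positions along
#' one axis, \eqn{d_i = |p_i - p_{i-1}|}; always nonnegative, which also
#' makes it invariant to the lateral mirroring used for side unification.
#'
#' @param p numeric position series (length >= 2).
#' @return numeric vector of length `length(p) - 1`.
#' @export
displacement_series <- function(p) {
  if (!is.numeric(p) || length(p) < 2L) {
    stop_invalid("position series must have length >= 2")
  }
  abs(diff(p))
}

#' First difference rate (chained derivative features)
#'
#' One finite-difference step \eqn{(x_i - x_{i-1}) / T}. Applied once to the
#' displacement series it yields the velocity feature, applied again the
#' acceleration, and a third time the jerk — the features are derivatives of
#' the absolute displacement series, not of the signed position.
#'
#' @param x numeric series (length >= 2).
#' @param t_prime time step in seconds (> 0); for encoded images this is the
#'   effective resampled interval of the clipped movement.
#' @return numeric vector of length `length(x) - 1`.
#' @export
difference_rate <- function(x, t_prime) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop_invalid("series must have length >= 2")
  }
  if (!is.numeric(t_prime) || length(t_prime) != 1L || !is.finite(t_prime) ||
      t_prime <= 0) {
    stop_invalid("`t_prime` must be a single positive number")
  }
  diff(x) / t_prime
}

#' Min-max normalization to the unit interval
#'
#' \eqn{f' = (f - \min f) / (\max f - \min f)}. A constant series maps to
#' all zeros (a constant feature carries no information and this avoids a
#' division by zero).
#'
#' @param x numeric vector (nonempty).
#' @return numeric vector of the same length with values in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (!is.numeric(x) || !length(x)) stop_invalid("series must be nonempty")
  r <- range(x)
  if (r[1] == r[2]) return(numeric(length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# Left-pad a series to `len` by repeating its first value, preserving the
# temporal alignment of the late samples.
pad_left <- function(x, len) {
  if (length(x) >= len) return(x[seq_len(len)])
  c(rep(x[1], len - length(x)), x)
}

#' Encode one marker of a clipped, side-unified recording as a 12 x 32
#' feature block
#'
#' Per axis (x, y, z): the position series is linearly resampled to
#' `n_samples` (default 32) points; displacement (|first difference|),
#' velocity, acceleration and jerk are then chained first differences
#' divided by the effective resampled interval T' = (clipped duration) /
#' (n_samples - 1). Each derivative loses one sample, so the d/v/a/j series
#' (31/30/29/28 values for width 32) are left-padded by edge replication
#' back to the full width, and every row is min-max normalized on its own
#' range.
#'
#' @param rec a clipped, side-unified [recording()].
#' @param marker marker name (e.g. `"FN"`).
#' @param n_samples image width (default 32).
#' @return a 12 x `n_samples` numeric matrix; rows are (d, v, a, j) for x,
#'   then y, then z, values in `[0, 1]`.
#' @export
encode_marker <- function(rec, marker, n_samples = 32L) {
  stopifnot(inherits(rec, "recording"))
  if (!marker %in% names(rec$markers)) {
    stop_invalid(paste0("marker ", marker, " not present in recording"))
  }
  p <- rec$markers[[marker]]
  n_raw <- nrow(p)
  t_prime <- (n_raw - 1L) * rec$sample_interval / (n_samples - 1L)
  block <- matrix(0, nrow = 12L, ncol = n_samples)
  rn <- character(12L)
  r <- 0L
  for (ax in c("x", "y", "z")) {
    pos <- resample_linear(p[, ax], n_samples)
    d <- displacement_series(pos)
    v <- difference_rate(d, t_prime)
    a <- difference_rate(v, t_prime)
    j <- difference_rate(a, t_prime)
    for (f in list(d = d, v = v, a = a, j = j)) {
      r <- r + 1L
      block[r, ] <- minmax_normalize(pad_left(f, n_samples))
    }
    rn[(r - 3L):r] <- paste0(c("d", "v", "a", "j"), "_", ax)
  }
  rownames(block) <- rn
  block
}

#' Assemble a multi-channel activity image
#'
#' Stacks one [encode_marker()] feature block per marker as image channels:
#' width 32 (time), height 12 (4 features x 3 axes), depth = number of
#' markers (1 = grey-scale analogue, 4 = RGBA analogue).
#'
#' @param rec a clipped, side-unified [recording()].
#' @param markers ordered character vector, subset of
#'   `c("FN", "LEP", "MPH", "ACR")`.
#' @param n_samples image width (default 32).
#' @return a 12 x `n_samples` x `length(markers)` array of class
#'   `activity_image` with attribute `channel_order`.
#' @export
assemble_image <- function(rec, markers = upper_limb_markers(),
                           n_samples = 32L) {
  if (!length(markers) || length(markers) > 4L) {
    stop_invalid("need between 1 and 4 markers")
  }
  missing <- setdiff(markers, names(rec$markers))
  if (length(missing)) {
    stop_invalid(paste0("unknown marker(s): ", paste(missing, collapse = ", ")))
  }
  img <- array(0, dim = c(12L, n_samples, length(markers)),
               dimnames = list(NULL, NULL, markers))
  for (k in seq_along(markers)) {
    img[, , k] <- encode_marker(rec, markers[k], n_samples)
  }
  structure(img, channel_order = markers, class = c("activity_image", "array"))
}

#' Preprocess and encode one raw recording
#'
#' Runs the full per-recording pipeline: movement-window detection on the
#' reference marker, clipping, side unification and activity-image
#' assembly.
#'
#' @param rec a raw [recording()] (marker names may carry side suffixes).
#' @param markers channels to encode, in order.
#' @param n_samples image width (default 32).
#' @param ... passed to [detect_movement_bounds()].
#' @return an `activity_image`.
#' @export
encode_recording <- function(rec, markers = upper_limb_markers(),
                             n_samples = 32L, ...) {
  bounds <- detect_movement_bounds(rec, ...)
  rec <- unify_side(clip(rec, bounds))
  assemble_image(rec, markers, n_samples)
}

#' Encode every recording of a cohort
#'
#' @param cohort a `mocap_cohort`.
#' @param markers channels to encode.
#' @param n_samples image width.
#' @param ... passed to [detect_movement_bounds()].
#' @return a list with `images` (12 x `n_samples` x C x n array) and `meta`
#'   (the cohort metadata), of class `encoded_cohort`.
#' @export
encode_cohort <- function(cohort, markers = upper_limb_markers(),
                          n_samples = 32L, ...) {
  stopifnot(inherits(cohort, "mocap_cohort"))
  n <- length(cohort$recordings)
  images <- array(0, dim = c(12L, n_samples, length(markers), n))
  for (i in seq_len(n)) {
    images[, , , i] <- encode_recording(cohort$recordings[[i]], markers,
                                        n_samples, ...)
  }
  structure(list(images = images, markers = markers, meta = cohort$meta),
            class = "encoded_cohort")
}
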