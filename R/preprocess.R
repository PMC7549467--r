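#' Detect the movement window of a recording
#'
#' Kinematic onset/offset detection on the reference marker (default FN, the
#' hand): the 3D speed is smoothed with a centred moving average, the onset
#' is the first sample where smoothed speed exceeds `speed_fraction` of its
#' peak and stays above it for `min_hold` seconds, refined by backtracking
#' to where the speed last fell below `backtrack_fraction` of the peak; the
#' offset is found symmetrically from the tail. One temporal window is used
#' for all markers and axes so that the three planes stay aligned.
#'
#' @param rec a [recording()].
#' @param reference_marker marker name (side suffix optional).
#' @param speed_fraction threshold as a fraction of peak smoothed speed
#'   (default 0.05).
#' @param min_hold time (s) the speed must stay above threshold (default 0.1).
#' @param smooth_window moving-average window in samples (default 5).
#' @param backtrack_fraction backtracking target as a fraction of peak speed
#'   (default 0.01).
#' @return a list of class `clip_bounds` with 1-based inclusive sample
#'   indices `start` and `end`.
#' @export
detect_movement_bounds <- function(rec, reference_marker = "FN",
                                   speed_fraction = 0.05, min_hold = 0.1,
                                   smooth_window = 5L,
                                   backtrack_fraction = 0.01) {
  stopifnot(inherits(rec, "recording"))
  nm <- names(rec$markers)
  hit <- nm[nm == reference_marker | nm %in% paste0(reference_marker, c("L", "R"))]
  if (!length(hit)) {
    stop_invalid(paste0("reference marker ", reference_marker, " not present"))
  }
  p <- rec$markers[[hit[1]]]
  n <- nrow(p)
  tt <- rec$sample_interval
  if (n * tt <= 2 * min_hold) {
    stop_invalid("recording shorter than 2 * min_hold")
  }
  speed <- sqrt(rowSums(diff(p)^2)) / tt
  w <- min(as.integer(smooth_window), length(speed))
  sm <- as.numeric(stats::filter(speed, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- speed[is.na(sm)]
  peak <- max(sm)
  thr <- speed_fraction * peak
  if (peak <= 0 || !any(sm > thr)) {
    stop_detection("no movement detected: speed never exceeds threshold")
  }
  hold_n <- max(1L, round(min_hold / tt))
  sustained <- function(s) {
    above <- s > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= hold_n)
    if (!length(ok)) return(NA_integer_)
    starts[ok[1]]
  }
  i0 <- sustained(sm)
  i1r <- sustained(rev(sm))
  if (is.na(i0) || is.na(i1r)) {
    stop_detection("no sustained movement found")
  }
  i1 <- length(sm) - i1r + 1L
  bt <- backtrack_fraction * peak
  j <- i0
  while (j > 1L && sm[j - 1L] > bt) j <- j - 1L
  k <- i1
  while (k < length(sm) && sm[k + 1L] > bt) k <- k + 1L
  # speed[i] sits between position samples i and i+1
  clip_bounds(j, min(n, k + 1L), n)
}

#' @rdname detect_movement_bounds
#' @param start,end 1-based inclusive sample indices.
#' @param n_total total number of samples the bounds refer to.
#' @export
clip_bounds <- function(start, end, n_total = Inf) {
  if (!is_count(start) || !is_count(end) || start >= end || end > n_total) {
    stop_invalid("require 1 <= start < end <= number of samples")
  }
  structure(list(start = as.integer(start), end = as.integer(end)),
            class = "clip_bounds")
}

#' Clip a recording to a movement window
#'
#' Truncates every marker series to the inclusive sample range
#' `[bounds$start, bounds$end]`; metadata and sampling interval are
#' preserved.
#'
#' @param rec a [recording()].
#' @param bounds a `clip_bounds` (from [detect_movement_bounds()]).
#' @return the clipped [recording()].
#' @export
clip <- function(rec, bounds) {
  stopifnot(inherits(rec, "recording"), inherits(bounds, "clip_bounds"))
  n <- n_frames(rec)
  if (bounds$end > n) stop_invalid("bounds out of range")
  out <- rec
  out$markers <- lapply(rec$markers, function(p) {
    p[bounds$start:bounds$end, , drop = FALSE]
  })
  if (!is.null(out$truth)) out$truth <- NULL
  out
}

#' Unify the movement side of a recording
#'
#' Reflects left-limb recordings onto the right side by negating the
#' lateral (x) axis, and strips the trailing side letter from the marker
#' names, so that downstream encoding sees one canonical side. Right-limb
#' recordings only have their names stripped. A recording whose marker
#' names carry no side suffix is returned unchanged (the operation is
#' idempotent).
#'
#' @param rec a [recording()].
#' @return the side-unified [recording()].
#' @export
unify_side <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  nm <- names(rec$markers)
  last <- substr(nm, nchar(nm), nchar(nm))
  # a canonical base name (e.g. ACR) carries no side suffix even though it
  # ends in R; this makes the operation idempotent on unified recordings
  suffixed <- !(nm %in% upper_limb_markers()) & last %in% c("L", "R")
  if (!any(suffixed)) {
    return(rec)
  }
  if (!all(suffixed) || length(unique(last)) != 1L) {
    stop_invalid("mixed-side marker set: cannot unify")
  }
  out <- rec
  if (last[1] == "L") {
    out$markers <- lapply(rec$markers, function(p) {
      p[, "x"] <- -p[, "x"]
      p
    })
  }
  names(out$markers) <- substr(nm, 1, nchar(nm) - 1L)
  out
}

#' Linear resampling of a scalar series to a fixed length
#'
#' Resamples by linear interpolation at `n_out` uniformly spaced fractional
#' positions over the original index range, preserving both endpoints.
#' Output values are convex combinations of neighbouring inputs, so the
#' range of the series cannot grow.
#'
#' @param x numeric vector (length >= 2).
#' @param n_out output length (default 32, the activity-image width).
#' @return numeric vector of length `n_out`.
#' @export
resample_linear <- function(x, n_out = 32L) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop_invalid("input series must have length >= 2")
  }
  if (!is_count(n_out, min = 2L)) stop_invalid("`n_out` must be an integer >= 2")
  stats::approx(x = seq_along(x) - 1L, y = x,
                xout = seq(0, length(x) - 1L, length.out = n_out))$y
}
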