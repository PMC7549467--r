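#' Minimum-jerk point-to-point position profile
#'
#' The minimum-jerk polynomial is the standard model of smooth healthy
#' reaching: for a movement of amplitude \eqn{A} and duration \eqn{D} the
#' position is \eqn{x(t) = A (10\tau^3 - 15\tau^4 + 6\tau^5)} with
#' \eqn{\tau = t/D}. Its peak speed is \eqn{1.875 A / D}, reached at
#' mid-movement.
#'
#' @param amplitude total displacement (mm); may be zero or negative.
#' @param duration movement duration in seconds; must be positive.
#' @param n number of samples (>= 2) uniformly spanning `[0, duration]`.
#' @return numeric vector of length `n`; `x[1] == 0`, `x[n] == amplitude`,
#'   monotone nondecreasing for positive amplitudes.
#' @examples
#' x <- min_jerk_profile(100, 1, 101)
#' max(diff(x)) / 0.01  # peak speed, about 187.5 mm/s
#' @export
min_jerk_profile <- function(amplitude, duration, n) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || !is.finite(amplitude)) {
    stop_invalid("`amplitude` must be a single finite number")
  }
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop_invalid("`duration` must be a single positive number")
  }
  if (!is_count(n, min = 2L)) {
    stop_invalid("`n` must be an integer >= 2")
  }
  tau <- seq(0, 1, length.out = n)
  amplitude * minjerk_shape(tau)
}

# Unit minimum-jerk shape s(tau) on [0,1], clamped to 0/1 outside.
minjerk_shape <- function(tau) {
  s <- ifelse(tau <= 0, 0,
    ifelse(tau >= 1, 1, 10 * tau^3 - 15 * tau^4 + 6 * tau^5))
  s
}

# Smoothed-trapezoid unit shape: velocity ramps up over a fraction `corner`
# of the movement with a smoothstep, cruises, and ramps down symmetrically.
# C^2 position profile with a flat speed peak of 1/(1-corner) (vs 1.875 for
# minimum jerk); used to lower peak velocity without changing amplitude or
# duration.
flat_shape <- function(tau, corner = 0.2) {
  c0 <- corner
  k <- 1 / (1 - c0)
  s <- numeric(length(tau))
  lo <- tau <= 0
  hi <- tau >= 1
  s[hi] <- 1
  mid <- !lo & !hi
  tm <- tau[mid]
  out <- numeric(length(tm))
  # integral of k * smoothstep(u), u = t/c: k*c*(u^3 - u^4/2)
  a <- tm < c0
  u <- tm[a] / c0
  out[a] <- k * c0 * (u^3 - u^4 / 2)
  b <- tm >= c0 & tm <= 1 - c0
  out[b] <- k * c0 / 2 + k * (tm[b] - c0)
  d <- tm > 1 - c0
  u <- (1 - tm[d]) / c0
  out[d] <- 1 - (k * c0 * (u^3 - u^4 / 2))
  s[mid] <- out
  s
}

# Blend of minimum-jerk and smoothed-trapezoid shapes. `velocity_factor` = 1
# reproduces minimum jerk (peak speed 1.875 A/D); lower values flatten the
# speed profile toward 1.25 A/D while keeping the endpoints and C^2
# smoothness. Peak speed is strictly increasing in `velocity_factor`.
blend_shape <- function(tau, velocity_factor = 1) {
  velocity_factor * minjerk_shape(tau) + (1 - velocity_factor) * flat_shape(tau)
}
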