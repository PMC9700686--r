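# Truncated-normal sampling and mean calibration.
#
# The synthetic generator samples event durations and amplitudes from normal
# distributions truncated to the admissible filter windows, with the location
# parameter solved so that the truncated mean equals a requested target.

tnorm_mean <- function(loc, sd, lower, upper) {
  a <- (lower - loc) / sd
  b <- (upper - loc) / sd
  pa <- pnorm(a); pb <- pnorm(b)
  z <- pb - pa
  # in the far tails fall back to the nearer bound
  out <- loc + sd * (dnorm(a) - dnorm(b)) / z
  bad <- !is.finite(out) | z < 1e-300
  if (any(bad)) out[bad] <- pmin(pmax(loc[bad], lower), upper)
  out
}

#' Sample from a truncated normal distribution
#'
#' Inverse-CDF sampler; adequate for the mild truncations used by the
#' session generator (targets well inside the filter windows).
#'
#' @param n number of draws.
#' @param loc,sd location and scale of the parent normal (vectorized over
#'   `loc`).
#' @param lower,upper truncation bounds (may be `-Inf` / `Inf`).
#' @return numeric vector of draws in `[lower, upper]`.
#' @export
rtnorm <- function(n, loc, sd, lower, upper) {
  pa <- pnorm(lower, loc, sd)
  pb <- pnorm(upper, loc, sd)
  u <- runif(n, pa, pb)
  out <- qnorm(u, loc, sd)
  pmin(pmax(out, lower), upper)
}

#' Calibrate the location of a truncated normal to hit a target mean
#'
#' Solves for `location` such that the mean of a normal(`location`, `sd`)
#' truncated to `[lower, upper]` equals `target_mean`. Solved by fixed-point
#' iteration `loc <- loc + (target - truncated_mean(loc))`, which is a
#' contraction because the truncated mean increases in `loc` with slope in
#' (0, 1].
#'
#' @param target_mean desired truncated mean; must lie strictly inside
#'   `(lower, upper)`.
#' @param sd scale of the parent normal, > 0.
#' @param lower,upper truncation bounds.
#' @param tol absolute convergence tolerance (default gives far better than
#'   the contracted 0.1% relative accuracy).
#' @param max_iter iteration cap; exceeding it raises a calibration error.
#' @return the solved location (scalar).
#' @export
calibrate_truncated_mean <- function(target_mean, sd, lower, upper,
                                     tol = 1e-8 * max(1, abs(target_mean)),
                                     max_iter = 200L) {
  assert_scalar_num(sd, "sd")
  if (sd <= 0) {
    stop_vrgaze("`sd` must be > 0", class = "vrgaze_validation_error")
  }
  if (!(lower < target_mean && target_mean < upper)) {
    stop_vrgaze("target_mean %g must lie strictly inside (%g, %g)",
                target_mean, lower, upper, class = "vrgaze_validation_error")
  }
  loc <- target_mean
  for (i in seq_len(max_iter %/% 2L)) {
    m <- tnorm_mean(loc, sd, lower, upper)
    err <- target_mean - m
    if (abs(err) <= tol) return(loc)
    loc <- loc + err
  }
  # near a bound the truncated mean is almost flat in the location and the
  # fixed point crawls; fall back to bisection on a bracketing interval
  lo <- loc - 50 * sd; hi <- loc + 50 * sd
  for (i in seq_len(max_iter %/% 2L)) {
    mid <- (lo + hi) / 2
    m <- tnorm_mean(mid, sd, lower, upper)
    if (abs(m - target_mean) <= tol) return(mid)
    if (m < target_mean) lo <- mid else hi <- mid
  }
  stop_vrgaze("truncated-mean calibration did not converge in %d iterations",
              max_iter, class = "vrgaze_calibration_error")
}
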