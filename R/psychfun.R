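#' Equivalent-noise spread
#'
#' The equivalent-noise decomposition of psychometric spread,
#' \deqn{\sigma = \sqrt{(\sigma_{int}^2 + \sigma_{ext}^2) / N},}
#' where \eqn{\sigma_{int}} is the observer's internal noise,
#' \eqn{\sigma_{ext}} the external (stimulus) noise, and \eqn{N} the number
#' of samples integrated into the judgement. \eqn{N} need not be an integer:
#' fractional values express integration efficiency.
#'
#' @param sigma_int internal noise, degrees (> 0).
#' @param sigma_ext external noise, degrees (>= 0).
#' @param n number of integrated samples (>= 1, real-valued).
#' @return the spread in degrees. Arguments recycle as usual.
#' @export
#' @examples
#' en_spread(5, 0, 1)   # = sigma_int
#' en_spread(6, 8, 4)   # sqrt(100 / 4) = 5
en_spread <- function(sigma_int, sigma_ext, n) {
  if (any(sigma_int <= 0)) stop("'sigma_int' must be > 0")
  if (any(sigma_ext < 0)) stop("'sigma_ext' must be >= 0")
  if (any(n < 1)) stop("'n' (integrated samples) must be >= 1")
  sqrt((sigma_int^2 + sigma_ext^2) / n)
}

#' Cumulative-Normal psychometric function
#'
#' Probability of a "rightwards" judgement at a given stimulus angle, for a
#' yes/no (left/right) task:
#' \eqn{\lambda/2 + (1-\lambda)\,\Phi((x - m)/\sigma)}.
#'
#' @param angle stimulus angle(s), degrees.
#' @param midpoint point of subjective equality \eqn{m}, degrees.
#' @param spread spread (inverse slope) \eqn{\sigma}, degrees (> 0).
#' @param lapse lapse rate \eqn{\lambda} in [0, 0.5); splits equally between
#'   the two responses.
#' @return probability of responding "right"; vectorised over `angle`,
#'   `midpoint` and `spread`.
#' @export
pf_cnorm <- function(angle, midpoint = 0, spread = 1, lapse = 0) {
  if (any(spread <= 0)) stop("'spread' must be > 0")
  if (any(lapse < 0 | lapse >= 0.5)) stop("'lapse' must be in [0, 0.5)")
  lapse / 2 + (1 - lapse) * stats::pnorm((angle - midpoint) / spread)
}

# Core wrapped cumulative Normal, no lapse. P(perceived direction on the
# rightward half-circle (0, 180]) when the perceived direction is
# wrapped-Normal(delta, spread) with delta = wrap(angle - midpoint).
# Sum over wraps k: Phi((180 + 360k - delta)/s) - Phi((360k - delta)/s).
# Terms decay like the Normal tail; n_wraps is chosen so the neglected tail
# is < 1e-12 even at the largest spread in the call.
.wrapped_right_prob <- function(delta, spread) {
  smax <- max(spread)
  k_max <- max(3L, ceiling((8 * smax + 360) / 360))
  p <- 0
  for (k in -k_max:k_max) {
    p <- p + (stats::pnorm((180 + 360 * k - delta) / spread) -
                stats::pnorm((360 * k - delta) / spread))
  }
  pmin(pmax(p, 0), 1)
}

#' Wrapped cumulative-Normal psychometric function
#'
#' Probability of a "rightwards" judgement when the perceived mean direction
#' is wrapped-Normal distributed on the circle: the probability that a
#' wrapped-Normal(angle - midpoint, spread) direction falls on the rightward
#' half-circle (0, 180]. Periodic in `angle` with period 360; equals 0.5 at
#' `angle = midpoint`; approaches the plain cumulative Normal for small
#' spreads and central angles.
#'
#' @inheritParams pf_cnorm
#' @return probability of responding "right"; vectorised over `angle`,
#'   `midpoint` and `spread`.
#' @export
pf_wrapped_cnorm <- function(angle, midpoint = 0, spread = 1, lapse = 0) {
  if (any(spread <= 0)) stop("'spread' must be > 0")
  if (any(lapse < 0 | lapse >= 0.5)) stop("'lapse' must be in [0, 0.5)")
  delta <- wrap_angle(angle - midpoint)
  lapse / 2 + (1 - lapse) * .wrapped_right_prob(delta, spread)
}

#' Weibull psychometric function (2AFC)
#'
#' Probability of a correct response at distortion amplitude `x`:
#' \eqn{\gamma + (1-\gamma-\lambda)(1 - e^{-(x/\alpha)^\beta})}.
#' At `x = alpha` with `guess = 0.5` and `lapse = 0` this evaluates to
#' \eqn{0.5 + 0.5(1 - e^{-1}) \approx 0.816}, i.e. the threshold corresponds
#' to roughly 82% correct.
#'
#' @param x stimulus amplitude(s), >= 0 (fraction of object radius).
#' @param alpha threshold (> 0), same units as `x`.
#' @param beta slope (> 0), dimensionless.
#' @param guess guess rate \eqn{\gamma} (0.5 for 2AFC).
#' @param lapse lapse rate \eqn{\lambda} in [0, 0.5).
#' @return probability correct; vectorised over `x`, `alpha`, `beta`.
#' @export
pf_weibull <- function(x, alpha, beta, guess = 0.5, lapse = 0) {
  if (any(x < 0)) stop("'x' must be >= 0")
  if (any(alpha <= 0) || any(beta <= 0)) stop("'alpha' and 'beta' must be > 0")
  guess + (1 - guess - lapse) * (1 - exp(-(x / alpha)^beta))
}
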