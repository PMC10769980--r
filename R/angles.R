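#' Wrap angles into (-180, +180]
#'
#' Maps arbitrary angles in degrees onto the principal interval used
#' throughout the package: 0 is frontal (the observer's vantage point),
#' negative angles are leftwards, positive rightwards. The boundary value
#' -180 is mapped to +180, so the mapping is idempotent on its own output.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, in (-180, +180].
#' @export
#' @examples
#' wrap_angle(c(-180, 180, 359, -361))
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w <= -180] <- w[w <= -180] + 360  # guard: %% can return exact 0 -> -180
  w
}

#' Circular mean of angles in degrees
#'
#' Resultant-vector mean, optionally weighted. Returns a value in
#' (-180, +180]. Undefined (NaN) if the resultant length is numerically zero.
#'
#' @param x angles in degrees.
#' @param w optional non-negative weights (recycled to `length(x)`).
#' @return scalar circular mean in degrees.
#' @export
circ_mean <- function(x, w = NULL) {
  r <- x * pi / 180
  if (is.null(w)) {
    s <- sum(sin(r)); c <- sum(cos(r))
  } else {
    s <- sum(w * sin(r)); c <- sum(w * cos(r))
  }
  if (s == 0 && c == 0) return(NaN)
  wrap_angle(atan2(s, c) * 180 / pi)
}

#' Circular standard deviation of angles in degrees
#'
#' The standard circular SD, sqrt(-2 log R) where R is the mean resultant
#' length, converted to degrees. For tightly concentrated samples this
#' approaches the linear SD.
#'
#' @param x angles in degrees.
#' @return scalar circular SD in degrees.
#' @export
circ_sd <- function(x) {
  r <- x * pi / 180
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  sqrt(-2 * log(R)) * 180 / pi
}

#' Draw wrapped-Normal angles
#'
#' i.i.d. draws from a wrapped Normal with the given mean and SD, wrapped
#' into (-180, +180]. With `sd = 0` all draws equal the (wrapped) mean.
#'
#' @param n number of draws.
#' @param mean mean direction, degrees.
#' @param sd standard deviation of the underlying Normal, degrees (>= 0).
#' @return numeric vector of `n` angles in (-180, +180].
#' @export
rwrapped_normal <- function(n, mean = 0, sd = 0) {
  stopifnot(sd >= 0)
  if (sd == 0) return(rep(wrap_angle(mean), n))
  wrap_angle(stats::rnorm(n, mean, sd))
}
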