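# Generative observers for the lighting-direction task. Three modes:
#  * "sample":     integrate a fixed integer number of objects, drawn
#                  without replacement each trial; each attended azimuth is
#                  perturbed by internal noise before circular averaging, so
#                  the induced psychometric spread follows the
#                  equivalent-noise law sigma = sqrt((si^2+se^2)/N).
#  * "weights":    fixed per-object-position attention weights (layout
#                  order); weighted circular mean of noisy azimuths.
#  * "efficiency": response-level observer with fractional integration
#                  N = set_size^exponent; responds from the wrapped
#                  cumulative Normal with the equivalent-noise spread.

#' Construct a simulated direction-judgement observer
#'
#' Exactly one of `n_integrated`, `weights`, `exponent` must be given; see
#' the mode descriptions in the package's methods vignette. `bias` is the
#' midpoint of the induced psychometric function (degrees); `lapse` is the
#' probability of a stimulus-independent uniform guess.
#'
#' @param sigma_int internal noise, degrees (> 0).
#' @param n_integrated integer number of integrated objects (>= 1).
#' @param weights non-negative attention weights over object positions in
#'   layout order (centre, inner ring, outer ring); normalised to sum 1.
#' @param exponent integration exponent x, in [0, 1.25]; N = set_size^x.
#' @param bias midpoint bias, degrees.
#' @param lapse lapse probability in [0, 1] (1 = pure guessing).
#' @return an object of class `en_observer`.
#' @export
observer <- function(sigma_int, n_integrated = NULL, weights = NULL,
                     exponent = NULL, bias = 0, lapse = 0) {
  if (sigma_int <= 0) stop("'sigma_int' must be > 0")
  if (lapse < 0 || lapse > 1) stop("'lapse' must be in [0, 1]")
  modes <- c(!is.null(n_integrated), !is.null(weights), !is.null(exponent))
  if (sum(modes) != 1) {
    stop("specify exactly one of 'n_integrated', 'weights', 'exponent'")
  }
  if (!is.null(weights)) {
    if (any(weights < 0) || sum(weights) <= 0) {
      stop("'weights' must be non-negative with positive sum")
    }
    weights <- weights / sum(weights)
  }
  if (!is.null(n_integrated) && n_integrated < 1) {
    stop("'n_integrated' must be >= 1")
  }
  if (!is.null(exponent) && (exponent < 0 || exponent > 1.25)) {
    stop("'exponent' must be in [0, 1.25]")
  }
  structure(list(sigma_int = sigma_int, n_integrated = n_integrated,
                 weights = weights, exponent = exponent,
                 bias = bias, lapse = lapse,
                 mode = c("sample", "weights", "efficiency")[modes]),
            class = "en_observer")
}

#' @export
print.en_observer <- function(x, ...) {
  cat(sprintf("<en_observer> mode '%s', sigma_int %.2f deg, bias %.2f deg, lapse %.3f\n",
              x$mode, x$sigma_int, x$bias, x$lapse))
  invisible(x)
}

#' Simulate left/right direction judgements
#'
#' Vectorised over trials. For the object-based modes, per-trial per-object
#' azimuths are drawn (wrapped Normal around `mean_angle` with SD
#' `ext_noise_sd`) unless supplied in `azimuths`; the observer attends to a
#' subset (or weighting) of objects, perturbs each attended azimuth with
#' internal noise, circularly averages, and responds "right" iff the wrapped
#' estimate minus the midpoint bias lies in (0, 180]. With probability
#' `lapse` the response is a uniform guess instead.
#'
#' @param obs an [observer()].
#' @param mean_angle vector of per-trial mean illumination angles, degrees.
#' @param ext_noise_sd per-trial external noise SD, degrees (recycled).
#' @param set_size number of objects per scene (scalar).
#' @param azimuths optional trials x set_size matrix of pre-drawn azimuths.
#' @return list with `response` (character "left"/"right") and `azimuths`
#'   (trials x set_size matrix; `NULL` in efficiency mode, which is
#'   response-level only).
#' @export
sim_direction_trials <- function(obs, mean_angle, ext_noise_sd = 0,
                                 set_size, azimuths = NULL) {
  stopifnot(inherits(obs, "en_observer"))
  nt <- length(mean_angle)
  ext <- rep_len(ext_noise_sd, nt)
  if (obs$mode == "efficiency") {
    n_eff <- pmax(1, set_size^obs$exponent)
    p0 <- pf_wrapped_cnorm(mean_angle, obs$bias,
                           en_spread(obs$sigma_int, ext, n_eff))
    p <- obs$lapse / 2 + (1 - obs$lapse) * p0
    return(list(response = ifelse(stats::runif(nt) < p, "right", "left"),
                azimuths = NULL))
  }
  if (is.null(azimuths)) {
    azimuths <- matrix(wrap_angle(stats::rnorm(nt * set_size,
                                               mean = rep(mean_angle, set_size),
                                               sd = rep(ext, set_size))),
                       nrow = nt, ncol = set_size)
    zero <- ext == 0
    if (any(zero)) azimuths[zero, ] <- wrap_angle(mean_angle[zero])
  } else {
    azimuths <- matrix(azimuths, nrow = nt)
    if (ncol(azimuths) != set_size) stop("'azimuths' must have set_size columns")
  }
  if (obs$mode == "sample") {
    n <- obs$n_integrated
    if (n > set_size) {
      stop("n_integrated (", n, ") exceeds set_size (", set_size, ")")
    }
    if (n == set_size) {
      att <- azimuths
    } else {
      raw <- vapply(seq_len(nt),
                    function(i) sample.int(set_size, n), integer(n))
      idx <- if (n == 1L) matrix(raw, ncol = 1L) else t(raw)
      att <- matrix(azimuths[cbind(rep(seq_len(nt), n), as.vector(idx))],
                    nrow = nt, ncol = n)
    }
    noisy <- att + stats::rnorm(length(att), 0, obs$sigma_int)
    rad <- noisy * pi / 180
    est <- atan2(rowMeans(sin(rad)), rowMeans(cos(rad))) * 180 / pi
  } else {
    w <- obs$weights
    if (length(w) != set_size) {
      stop("'weights' length (", length(w), ") must equal set_size (",
           set_size, ")")
    }
    noisy <- azimuths + stats::rnorm(length(azimuths), 0, obs$sigma_int)
    rad <- noisy * pi / 180
    est <- atan2(sin(rad) %*% w, cos(rad) %*% w) * 180 / pi
  }
  resp <- ifelse(wrap_angle(est - obs$bias) > 0, "right", "left")
  if (obs$lapse > 0) {
    lap <- stats::runif(nt) < obs$lapse
    resp[lap] <- ifelse(stats::runif(sum(lap)) < 0.5, "right", "left")
  }
  list(response = as.vector(resp), azimuths = azimuths)
}

#' Simulate one direction judgement for a scene specification
#'
#' Convenience wrapper over [sim_direction_trials()] for a single
#' [scene_spec()] (uses the scene's realised per-object azimuths).
#'
#' @param scene a `scene_spec`.
#' @param obs an [observer()].
#' @return "left" or "right".
#' @export
simulate_direction_response <- function(scene, obs) {
  validate_scene_spec(scene)
  sim_direction_trials(obs, mean_angle = scene$mean_angle,
                       ext_noise_sd = scene$ext_noise_sd,
                       set_size = scene$set_size,
                       azimuths = matrix(scene$azimuths, nrow = 1))$response
}

#' Response-level observer for psychometric-truth simulations
#'
#' An observer defined directly by per-condition psychometric parameters,
#' used to drive staircases for the yes/no task (cumulative Normal spread
#' and midpoint per condition) or the 2AFC shape task (Weibull threshold
#' and slope per condition). `params` must have a `condition` column plus
#' either (`spread`, `midpoint`) or (`alpha`, `beta`), and optionally
#' `lapse` (default 0) and `guess` (default 0.5, shape task only).
#'
#' @param params data.frame of per-condition truth parameters.
#' @return an object of class `pf_observer`.
#' @export
pf_observer <- function(params) {
  stopifnot(is.data.frame(params), "condition" %in% names(params))
  kind <- if (all(c("spread", "midpoint") %in% names(params))) "direction"
          else if (all(c("alpha", "beta") %in% names(params))) "shape"
          else stop("'params' must contain spread/midpoint or alpha/beta")
  if (is.null(params$lapse)) params$lapse <- 0
  if (kind == "shape" && is.null(params$guess)) params$guess <- 0.5
  structure(list(params = params, kind = kind), class = "pf_observer")
}

#' @export
print.pf_observer <- function(x, ...) {
  cat(sprintf("<pf_observer> %s task, %d condition(s)\n",
              x$kind, nrow(x$params)))
  invisible(x)
}

#' Simulate 2AFC shape-identification responses
#'
#' Bernoulli responses with success probability given by the Weibull
#' psychometric function at the presented distortion amplitude - a
#' response-level model observer (no mesh geometry is processed).
#'
#' @param amplitude vector of foil distortion amplitudes.
#' @param alpha,beta,guess,lapse Weibull parameters (see [pf_weibull()]).
#' @return character vector, "correct" / "incorrect".
#' @export
simulate_shape_response <- function(amplitude, alpha, beta, guess = 0.5,
                                    lapse = 0) {
  p <- pf_weibull(amplitude, alpha, beta, guess, lapse)
  ifelse(stats::runif(length(amplitude)) < p, "correct", "incorrect")
}
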