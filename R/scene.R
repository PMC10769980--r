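#' Object layout on the 5x5 scene grid
#'
#' Places `set_size` objects on a 5x5 grid (rows and columns indexed 0-4,
#' grid units). One object always occupies the central cell (2,2); the
#' 9-object layout adds the inner ring (Chebyshev distance 1) and the
#' 25-object layout the outer ring (distance 2). Object indices therefore
#' run centre first, then inner ring, then outer ring, each ring in
#' row-major order; per-object azimuth and reflectance vectors follow this
#' order everywhere in the package. Each object gets independent positional
#' jitter, uniform in a disc whose radius is small enough that neighbouring
#' objects cannot collide.
#'
#' @param set_size number of objects: 1, 9, or 25.
#' @param jitter_radius jitter disc radius in grid units (default 0.15; must
#'   be < 0.5 so objects stay in their cells).
#' @return data.frame with columns `row`, `col`, `jitter_x`, `jitter_y`.
#' @export
layout_objects <- function(set_size, jitter_radius = 0.15) {
  if (!set_size %in% c(1L, 9L, 25L)) {
    stop("'set_size' must be one of 1, 9, 25 (got ", set_size, ")")
  }
  if (jitter_radius < 0 || jitter_radius >= 0.5) {
    stop("'jitter_radius' must be in [0, 0.5)")
  }
  g <- expand.grid(col = 0:4, row = 0:4)[, c("row", "col")]
  ring <- pmax(abs(g$row - 2), abs(g$col - 2))
  keep <- switch(as.character(set_size),
                 "1" = ring == 0, "9" = ring <= 1, "25" = ring <= 2)
  g <- g[keep, ]
  g <- g[order(ring[keep], g$row, g$col), ]
  n <- nrow(g)
  # uniform in a disc
  th <- stats::runif(n, 0, 2 * pi)
  rr <- jitter_radius * sqrt(stats::runif(n))
  out <- data.frame(row = g$row, col = g$col,
                    jitter_x = rr * cos(th), jitter_y = rr * sin(th))
  rownames(out) <- NULL
  out
}

#' Sample object reflectances
#'
#' Diffuse (Lambertian) reflectances drawn from a Beta(1.5, 6.5)
#' distribution restricted to [0.05, 0.80], mimicking the reflectance
#' distribution of natural scenes. The truncation is by rejection sampling,
#' so draws follow the renormalised truncated density exactly (clipping
#' would create atoms at the bounds).
#'
#' @param n number of draws.
#' @param shape1,shape2 Beta shape parameters (defaults 1.5 and 6.5).
#' @param lower,upper truncation bounds (defaults 0.05 and 0.80).
#' @return numeric vector of `n` reflectances in [lower, upper].
#' @export
sample_reflectance <- function(n, shape1 = 1.5, shape2 = 6.5,
                               lower = 0.05, upper = 0.80) {
  out <- numeric(0)
  # acceptance probability is ~0.86 for the default parameters
  while (length(out) < n) {
    m <- max(16L, ceiling(1.5 * (n - length(out))))
    x <- stats::rbeta(m, shape1, shape2)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Assign per-object light-source azimuths
#'
#' Each object's light azimuth is an independent wrapped-Normal draw around
#' the scene's mean illumination angle with SD equal to the external-noise
#' level, wrapped into (-180, +180]. Zero external noise gives every object
#' the mean angle exactly.
#'
#' @param mean_angle mean illumination angle, degrees.
#' @param ext_noise_sd external noise SD, degrees (>= 0).
#' @param set_size number of objects.
#' @return numeric vector of `set_size` azimuths in (-180, +180].
#' @export
assign_azimuths <- function(mean_angle, ext_noise_sd, set_size) {
  rwrapped_normal(set_size, mean_angle, ext_noise_sd)
}

#' Construct a parametric scene specification
#'
#' Bundles everything needed to render (elsewhere) one stimulus scene:
#' layout, per-object azimuths and reflectances, shadow flag, and the
#' generating mean angle / external-noise level. No images are produced;
#' the scene is a parametric description.
#'
#' @param set_size 1, 9 or 25 objects.
#' @param mean_angle mean illumination angle, degrees in (-180, 180].
#' @param ext_noise_sd external noise SD, degrees (>= 0).
#' @param shadows logical; are cast shadows rendered?
#' @param elevation light source elevation, degrees (fixed at 40 in the
#'   designs this package models).
#' @param jitter_radius passed to [layout_objects()].
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(set_size, mean_angle, ext_noise_sd = 0,
                       shadows = TRUE, elevation = 40,
                       jitter_radius = 0.15) {
  if (ext_noise_sd < 0) stop("'ext_noise_sd' must be >= 0")
  out <- list(
    set_size = as.integer(set_size),
    positions = layout_objects(set_size, jitter_radius),
    azimuths = assign_azimuths(mean_angle, ext_noise_sd, set_size),
    elevation = elevation,
    reflectances = sample_reflectance(set_size),
    shadows = isTRUE(shadows),
    mean_angle = wrap_angle(mean_angle),
    ext_noise_sd = ext_noise_sd
  )
  class(out) <- "scene_spec"
  validate_scene_spec(out)
  out
}

#' Validate a scene specification
#'
#' Checks the structural invariants: matching lengths, azimuths in
#' (-180, +180], reflectances within bounds, layout matching the set size.
#'
#' @param x a `scene_spec`.
#' @return `x`, invisibly; errors if invalid.
#' @export
validate_scene_spec <- function(x) {
  stopifnot(inherits(x, "scene_spec"))
  n <- x$set_size
  if (nrow(x$positions) != n || length(x$azimuths) != n ||
      length(x$reflectances) != n) {
    stop("scene_spec lengths inconsistent with set_size ", n)
  }
  if (any(x$azimuths <= -180 | x$azimuths > 180)) {
    stop("azimuths must lie in (-180, +180]")
  }
  if (any(x$reflectances < 0.05 | x$reflectances > 0.80)) {
    stop("reflectances must lie in [0.05, 0.80]")
  }
  if (anyDuplicated(x$positions[, c("row", "col")])) {
    stop("grid cells repeat within a scene")
  }
  invisible(x)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %d object(s), mean angle %.2f deg, external noise %.1f deg, %s\n",
    x$set_size, x$mean_angle, x$ext_noise_sd,
    if (x$shadows) "with cast shadows" else "no cast shadows"))
  invisible(x)
}

#' Serialise a scene specification to JSON
#'
#' Stable key order; inverse of [scene_from_json()].
#'
#' @param x a `scene_spec`.
#' @param path optional file path; if missing, the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
scene_to_json <- function(x, path = NULL) {
  validate_scene_spec(x)
  j <- jsonlite::toJSON(unclass(x), dataframe = "columns", digits = NA,
                        auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}

#' Read a scene specification from JSON
#'
#' @param json a JSON string or file path produced by [scene_to_json()].
#' @return a `scene_spec`.
#' @export
scene_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$positions <- as.data.frame(x$positions)
  x$set_size <- as.integer(x$set_size)
  class(x) <- "scene_spec"
  validate_scene_spec(x)
  x
}

#' Enumerate the image-database keys for the noise experiment
#'
#' The external-noise design composites scenes from a pre-rendered database
#' indexed by light azimuth and instance. This enumerates the full Cartesian
#' product of keys, deterministically.
#'
#' @param azimuths vector of distinct light azimuths, degrees.
#' @param n_instances number of rendered instances per azimuth.
#' @return data.frame with columns `azimuth`, `instance` (1-based), one row
#'   per key.
#' @export
enumerate_database <- function(azimuths, n_instances) {
  if (anyDuplicated(azimuths)) stop("duplicate azimuths in database config")
  if (n_instances < 1) stop("'n_instances' must be >= 1")
  out <- expand.grid(instance = seq_len(n_instances), azimuth = azimuths)
  out <- out[, c("azimuth", "instance")]
  rownames(out) <- NULL
  out
}
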