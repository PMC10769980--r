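# Mesh machinery for the shape-identification stimuli: icosphere
# construction, sinusoidal "potato" distortions, and the Gaussian-weighted
# merge with a flattened sphere that preserves the bounding contour.

#' Refined icosphere mesh
#'
#' Unit sphere approximated by refining an icosahedron: each refinement
#' level splits every triangle into four, projecting new vertices back onto
#' the sphere. Level 4 has 2562 vertices and 5120 faces.
#'
#' @param subdiv number of refinement levels (>= 0).
#' @return a list of class `tri_mesh` with `vertices` (n x 3 matrix) and
#'   `faces` (m x 3 integer matrix, 1-based, counter-clockwise).
#' @export
icosphere <- function(subdiv = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    nv <- nrow(v)
    midpoint_key <- new.env(hash = TRUE, parent = emptyenv())
    new_v <- list()
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midpoint_key[[key]]
      if (!is.null(idx)) return(idx)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      new_v[[length(new_v) + 1L]] <<- m
      idx <- nv + length(new_v)
      midpoint_key[[key]] <- idx
      idx
    }
    new_f <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c_); ca <- get_mid(c_, a)
      new_f[(i - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, new_v))
    f <- new_f
  }
  structure(list(vertices = v, faces = f), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Is a triangle mesh watertight?
#'
#' A closed 2-manifold has every edge shared by exactly two faces.
#'
#' @param mesh a `tri_mesh`.
#' @return logical.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# Vertical sinusoidal distortion: every vertex is displaced along its radial
# direction by amplitude * sin(pi * frequency * (z + 1)), i.e. the sinusoid
# runs `frequency` full cycles over the height of the originating unit
# sphere, and the displacement never exceeds `amplitude` (a fraction of the
# base radius).
.sinusoid_distort <- function(v, frequency, amplitude) {
  r <- sqrt(rowSums(v^2))
  dir <- v / r
  disp <- amplitude * sin(pi * frequency * (v[, 3] + 1))
  v + dir * disp
}

.rotation_matrix <- function(rx, ry, rz) {
  cx <- cos(rx * pi / 180); sx <- sin(rx * pi / 180)
  cy <- cos(ry * pi / 180); sy <- sin(ry * pi / 180)
  cz <- cos(rz * pi / 180); sz <- sin(rz * pi / 180)
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' The 202-value distortion-amplitude grid
#'
#' Amplitude 0 (undistorted) prepended to 201 logarithmically spaced values
#' on [0.01, 0.2], for 202 amplitudes in total. Amplitudes are fractions of
#' the radius of the originating sphere.
#'
#' @param n_log number of log-spaced non-zero values (default 201).
#' @param lower,upper log-spacing range (defaults 0.01, 0.2).
#' @return numeric vector of `n_log + 1` amplitudes, increasing.
#' @export
amplitude_grid <- function(n_log = 201, lower = 0.01, upper = 0.2) {
  c(0, exp(seq(log(lower), log(upper), length.out = n_log)))
}

#' Generate a potato-object specification
#'
#' One "instance" is defined by five rounds of (vertical sinusoid, 3-axis
#' rotation) applied to an icosphere: frequencies uniform on [2, 5] cycles
#' per object, amplitudes uniform on [0.04, 0.08] of the radius, rotations
#' uniform on [0, 360) per axis. The instance's base distortions are derived
#' deterministically from `instance_id` (plus `seed`), so every amplitude of
#' the same instance shares its base geometry. On top of the base potato an
#' extra vertical sinusoid of frequency 5 and amplitude `extra_amplitude` is
#' applied, with no rotation afterwards.
#'
#' @param instance_id integer instance index (0-99 in the reference design).
#' @param extra_amplitude amplitude of the extra sinusoid, in [0, 0.2].
#' @param seed base seed from which instance geometry is derived.
#' @param merged logical; merge with the flattened sphere (default TRUE)?
#' @return an object of class `potato_spec`.
#' @export
potato_spec <- function(instance_id, extra_amplitude = 0, seed = 1L,
                        merged = TRUE) {
  if (extra_amplitude < 0 || extra_amplitude > 0.2) {
    stop("'extra_amplitude' must be in [0, 0.2]")
  }
  base <- with_seed(seed + instance_id, {
    data.frame(
      frequency = stats::runif(5, 2, 5),
      amplitude = stats::runif(5, 0.04, 0.08),
      rot_x = stats::runif(5, 0, 360),
      rot_y = stats::runif(5, 0, 360),
      rot_z = stats::runif(5, 0, 360))
  })
  structure(list(instance_id = as.integer(instance_id),
                 base_distortions = base,
                 extra_frequency = 5,
                 extra_amplitude = extra_amplitude,
                 merged = isTRUE(merged)),
            class = "potato_spec")
}

#' Enumerate all potato specifications of the reference design
#'
#' The full stimulus set crosses the object instances with the distortion
#' amplitude grid; the default configuration (100 instances x 202
#' amplitudes) enumerates 20,200 potato specifications.
#'
#' @param n_instances number of object instances (default 100).
#' @param amplitudes amplitude grid (default [amplitude_grid()]).
#' @return data.frame with columns `instance_id` (0-based) and `amplitude`,
#'   one row per specification; each pair appears exactly once.
#' @export
enumerate_potatoes <- function(n_instances = 100,
                               amplitudes = amplitude_grid()) {
  if (n_instances < 1) stop("'n_instances' must be >= 1")
  if (anyDuplicated(amplitudes)) stop("duplicate amplitudes in grid")
  out <- expand.grid(amplitude = amplitudes,
                     instance_id = seq_len(n_instances) - 1L)
  out <- out[, c("instance_id", "amplitude")]
  rownames(out) <- NULL
  out
}

#' Build a potato mesh from its specification
#'
#' Applies the five base (sinusoid, rotation) rounds, the extra sinusoid,
#' and - unless `spec$merged` is FALSE - the Gaussian-weighted merge with a
#' flattened sphere. The merge weight is w(r) = exp(-r^2 / (2 s^2)) with
#' s = 0.35 of the flattened-sphere radius, evaluated at each vertex's
#' radial position on the flattened sphere, clamped to 1 at the centre and
#' to 0 at the rim; rim vertices therefore coincide exactly across
#' amplitudes of the same instance (same bounding contour).
#'
#' @param spec a `potato_spec`.
#' @param subdiv icosphere refinement level (default 4, ~2562 vertices).
#' @param flatten z-scale of the flattened sphere (default 0.3).
#' @param merge_sd Gaussian merge width as a fraction of the radius
#'   (default 0.35).
#' @return a `tri_mesh`.
#' @export
build_potato_mesh <- function(spec, subdiv = 4, flatten = 0.3,
                              merge_sd = 0.35) {
  stopifnot(inherits(spec, "potato_spec"))
  if (spec$extra_amplitude < 0 || spec$extra_amplitude > 0.2) {
    stop("'extra_amplitude' must be in [0, 0.2]")
  }
  base <- icosphere(subdiv)
  v <- base$vertices
  for (i in 1:5) {
    d <- spec$base_distortions[i, ]
    v <- .sinusoid_distort(v, d$frequency, d$amplitude)
    v <- v %*% t(.rotation_matrix(d$rot_x, d$rot_y, d$rot_z))
  }
  v <- .sinusoid_distort(v, spec$extra_frequency, spec$extra_amplitude)
  if (spec$merged) {
    flat <- base$vertices
    flat[, 3] <- flat[, 3] * flatten
    r_xy <- sqrt(flat[, 1]^2 + flat[, 2]^2)
    w <- exp(-r_xy^2 / (2 * merge_sd^2))
    w[r_xy <= .Machine$double.eps] <- 1
    w[r_xy >= 1 - 1e-9] <- 0
    v <- v * w + flat * (1 - w)
  }
  structure(list(vertices = v, faces = base$faces,
                 merge_weight_zero = if (spec$merged)
                   which(sqrt(base$vertices[, 1]^2 + base$vertices[, 2]^2)
                         >= 1 - 1e-9) else integer(0)),
            class = "tri_mesh")
}

#' Export a mesh to Wavefront OBJ
#'
#' @param mesh a `tri_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  vl <- sprintf("v %.9g %.9g %.9g",
                mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  fl <- sprintf("f %d %d %d",
                mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  writeLines(c(vl, fl), path)
  invisible(path)
}

#' Export a mesh to ASCII PLY
#'
#' @inheritParams write_obj
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nv),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.9g %.9g %.9g",
                mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  fl <- sprintf("3 %d %d %d",
                mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                mesh$faces[, 3] - 1L)
  writeLines(c(header, vl, fl), path)
  invisible(path)
}
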