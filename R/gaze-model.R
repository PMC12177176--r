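# Mean gaze per eye section, rigid-body rotation about the centre of mass,
# and projection onto a 10 mm virtual sphere in azimuth/elevation.

#' Virtual-sphere configuration
#'
#' The sphere onto which gaze rays are projected. Its large default radius
#' (10 mm, versus a head of ~0.1 mm) makes azimuth/elevation broadly
#' independent of the exact rotation point inside the animal.
#'
#' @param radius Sphere radius in mm (default 10).
#' @param origin Sphere centre in mm, lab frame; by convention the midpoint
#'   between the left and right convergence points of all visual axes.
#' @return A list of class `sphere_config`.
#' @export
sphere_config <- function(radius = 10, origin = c(0, 0, 0)) {
  if (!is.numeric(radius) || radius <= 0) {
    abort("Sphere radius must be > 0.", class = "splitgaze_schema_error")
  }
  stopifnot(length(origin) == 3)
  structure(list(radius = radius, origin = as.numeric(origin)),
            class = "sphere_config")
}

#' Mean gaze of a set of visual axes
#'
#' The normalized vector sum of all gaze vectors of one eye section.
#'
#' @param axes n x 3 matrix (or length-3 vector) of axis vectors.
#' @return Unit length-3 vector.
#' @export
mean_gaze <- function(axes) {
  if (!is.matrix(axes)) axes <- matrix(axes, ncol = 3)
  s <- colSums(axes)
  if (vec_norm(s) < 1e-9 * nrow(axes)) {
    abort("Degenerate mean gaze: axis vectors cancel.",
          class = "splitgaze_degenerate_gaze")
  }
  unit_vector(s)
}

#' Least-squares convergence point of a set of lines
#'
#' The point minimizing the summed squared orthogonal distances to all
#' visual-axis lines — where the axes of one body side converge behind the
#' lenses. Solved in closed form from the normal equations
#' `sum(I - d d^T) p = sum(I - d d^T) o`.
#'
#' @param origins n x 3 matrix of points on the lines (circle centres).
#' @param directions n x 3 matrix of line directions (need not be unit).
#' @return Length-3 point.
#' @export
convergence_point <- function(origins, directions) {
  origins <- as.matrix(origins)
  directions <- as.matrix(directions)
  stopifnot(nrow(origins) == nrow(directions), ncol(origins) == 3)
  if (nrow(origins) < 2) {
    abort("Need at least 2 lines.", class = "splitgaze_schema_error")
  }
  A <- matrix(0, 3, 3)
  b <- numeric(3)
  for (i in seq_len(nrow(origins))) {
    d <- unit_vector(directions[i, ])
    P <- diag(3) - tcrossprod(d)
    A <- A + P
    b <- b + P %*% origins[i, ]
  }
  if (abs(det(A)) < 1e-12) {
    abort("All lines are parallel; convergence point undefined.",
          class = "splitgaze_degenerate_geometry")
  }
  as.numeric(solve(A, b))
}

#' Body rotation matrix from yaw, pitch and roll
#'
#' Intrinsic z-y-x composition `Rz(yaw) Ry(pitch) Rx(roll)`, right-handed
#' in the body frame (x anterior, y left, z dorsal). Positive yaw turns the
#' anterior axis toward +y (the animal's left); positive pitch lifts the
#' anterior axis tip dorsally; positive roll is right-handed about the
#' anterior axis.
#'
#' @param yaw,pitch,roll Angles in degrees.
#' @return 3 x 3 orthonormal matrix with determinant +1.
#' @examples
#' rotation_matrix(yaw = 90) %*% c(1, 0, 0) # ~ (0, 1, 0)
#' @export
rotation_matrix <- function(yaw = 0, pitch = 0, roll = 0) {
  psi <- deg2rad(yaw); beta <- deg2rad(pitch); phi <- deg2rad(roll)
  Rz <- matrix(c(cos(psi), sin(psi), 0,
                 -sin(psi), cos(psi), 0,
                 0, 0, 1), 3, 3)
  # nose-up positive pitch: maps (1,0,0) to (cos b, 0, sin b)
  Ry <- matrix(c(cos(beta), 0, sin(beta),
                 0, 1, 0,
                 -sin(beta), 0, cos(beta)), 3, 3)
  Rx <- matrix(c(1, 0, 0,
                 0, cos(phi), sin(phi),
                 0, -sin(phi), cos(phi)), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Project a gaze ray onto the virtual sphere
#'
#' Intersects the forward ray from `ray_origin` along `direction` with the
#' sphere and returns the spherical coordinates of the intersection point
#' about the sphere origin.
#'
#' @param ray_origin Length-3 point (mm), strictly inside the sphere.
#' @param direction Length-3 direction (need not be unit).
#' @param sphere A [sphere_config()].
#' @return A tibble with `azimuth` and `elevation` in degrees.
#' @export
project_to_sphere <- function(ray_origin, direction, sphere = sphere_config()) {
  o <- as.numeric(ray_origin) - sphere$origin
  d <- unit_vector(direction)
  r <- sphere$radius
  if (vec_norm(o) >= r) {
    abort("Ray origin must lie inside the sphere.",
          class = "splitgaze_schema_error")
  }
  od <- sum(o * d)
  t_hit <- -od + sqrt(od^2 + r^2 - sum(o^2))
  p <- o + t_hit * d
  ae <- vec_to_azel(p)
  tibble(azimuth = ae$azimuth, elevation = ae$elevation)
}

#' Angular separation between section mean gazes
#'
#' @param dorsal_axes,ventral_axes n x 3 matrices of axis vectors, one per
#'   eye section; alternatively pass a single [eye_map()] tibble as
#'   `dorsal_axes` and the sections are split internally.
#' @return Angle in degrees between the dorsal and ventral mean gaze.
#' @export
section_gaze_separation <- function(dorsal_axes, ventral_axes = NULL) {
  if (is.data.frame(dorsal_axes) && is.null(ventral_axes)) {
    map <- dorsal_axes
    ax <- as.matrix(map[c("axis_x", "axis_y", "axis_z")])
    dorsal_axes <- ax[map$section == "dorsal", , drop = FALSE]
    ventral_axes <- ax[map$section == "ventral", , drop = FALSE]
  }
  angular_difference(mean_gaze(dorsal_axes), mean_gaze(ventral_axes))
}

# Extract per-section axes (and circle centres, if present) from an
# eye_map / lens_geometry tibble.
section_axes <- function(map) {
  ax <- as.matrix(map[c("axis_x", "axis_y", "axis_z")])
  out <- list()
  for (s in c("dorsal", "ventral")) {
    idx <- which(map$section == s)
    if (length(idx) > 0) {
      item <- list(axes = ax[idx, , drop = FALSE])
      if (all(c("center_x", "center_y", "center_z") %in% names(map))) {
        item$centers <- as.matrix(
          map[idx, c("center_x", "center_y", "center_z")])
      }
      out[[s]] <- item
    }
  }
  out
}

#' Sweep body rotation and track per-section mean gaze on the sphere
#'
#' Rotates the whole eye rigidly about the centre of mass in fixed angular
#' steps about one body axis, and reports where each eye section's mean
#' gaze meets the fixed virtual sphere (lab frame: the gaze rotates, the
#' sphere does not). Body translation is ignored.
#'
#' @param map An [eye_map()] or [lens_geometry()] tibble with per-facet
#'   axes (coordinates in micrometres, head frame).
#' @param axis One of `"yaw"`, `"pitch"`, `"roll"`.
#' @param range Length-2 angle range in degrees. Defaults per axis to the
#'   envelopes typical of small free-flying insects: pitch 0..150, yaw
#'   -90..90, roll -50..50.
#' @param step Step in degrees (default 1).
#' @param base_pitch Body pitch of the reference posture about which the
#'   sweep is taken, degrees (default 0). A roll sweep at `base_pitch = 80`
#'   rolls the body at the typical flight posture; a pitch sweep adds the
#'   sweep angle to `base_pitch`.
#' @param sphere A [sphere_config()]; by default centred midway between the
#'   left and right convergence points (right-eye data are mirrored across
#'   the sagittal plane to obtain the left point).
#' @param com Centre of mass (mm, lab frame) about which the body rotates
#'   (default: the sphere origin).
#' @param coord_scale Factor from map coordinate units to mm
#'   (default 1e-3: micrometres to mm).
#' @return A tibble: `section`, `axis`, `angle`, `azimuth`, `elevation`,
#'   `flagged` (TRUE where the mean gaze was degenerate at that pose).
#' @export
gaze_sweep <- function(map, axis = c("pitch", "yaw", "roll"), range = NULL,
                       step = 1, base_pitch = 0, sphere = NULL, com = NULL,
                       coord_scale = 1e-3) {
  axis <- match.arg(axis)
  if (step <= 0) abort("step must be > 0.", class = "splitgaze_schema_error")
  if (is.null(range)) {
    range <- switch(axis, pitch = c(0, 150), yaw = c(-90, 90),
                    roll = c(-50, 50))
  }
  stopifnot(length(range) == 2, range[2] >= range[1])
  sec <- section_axes(map)
  if (length(sec) == 0) {
    abort("Map contains no dorsal/ventral facets.",
          class = "splitgaze_schema_error")
  }

  # Per-section static mean gaze and ray origins (mm).
  gazes <- lapply(sec, function(s) mean_gaze(s$axes))
  has_centers <- all(vapply(sec, function(s) !is.null(s$centers), TRUE))
  if (has_centers) {
    all_centers <- do.call(rbind, lapply(sec, `[[`, "centers")) * coord_scale
    all_axes <- do.call(rbind, lapply(sec, `[[`, "axes"))
    cp_right <- tryCatch(convergence_point(all_centers, all_axes),
                         error = function(e) colMeans(all_centers))
    cp_left <- cp_right * c(1, -1, 1)  # mirror across the sagittal plane
    sphere_origin <- (cp_right + cp_left) / 2
    ray_origins <- lapply(sec, function(s) {
      tryCatch(convergence_point(s$centers * coord_scale, s$axes),
               error = function(e) colMeans(s$centers * coord_scale))
    })
  } else {
    sphere_origin <- c(0, 0, 0)
    ray_origins <- lapply(sec, function(s) c(0, 0, 0))
  }
  if (is.null(sphere)) sphere <- sphere_config(origin = sphere_origin)
  if (is.null(com)) com <- sphere$origin

  angles <- seq(range[1], range[2], by = step)
  rows <- list()
  for (s_name in names(sec)) {
    g <- gazes[[s_name]]
    o <- ray_origins[[s_name]]
    for (a in angles) {
      R <- switch(axis,
                  yaw = rotation_matrix(yaw = a, pitch = base_pitch),
                  pitch = rotation_matrix(pitch = base_pitch + a),
                  roll = rotation_matrix(pitch = base_pitch, roll = a))
      g_rot <- as.numeric(R %*% g)
      o_rot <- com + as.numeric(R %*% (o - com))
      res <- tryCatch(project_to_sphere(o_rot, g_rot, sphere),
                      error = function(e) NULL)
      if (is.null(res)) {
        rows[[length(rows) + 1]] <- tibble(
          section = s_name, axis = axis, angle = a,
          azimuth = NA_real_, elevation = NA_real_, flagged = TRUE)
      } else {
        rows[[length(rows) + 1]] <- tibble(
          section = s_name, axis = axis, angle = a,
          azimuth = res$azimuth, elevation = res$elevation, flagged = FALSE)
      }
    }
  }
  bind_rows(rows)
}
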