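# Seeded generator of ground-truth split compound eyes: two flattened
# cap-shaped facet arrays with a radial interommatidial-angle gradient,
# per-lens spherical-cap geometry, and digitization noise added last.

#' Specification of a synthetic split eye
#'
#' Defaults emulate the female whitefly right eye: 42 dorsal + 31 ventral
#' facets, section mean gazes 53 degrees apart, lens diameter and outer
#' curvature-radius distributions per section, a 1 -> 30 degree
#' centre-to-edge interommatidial-angle gradient, and a 126 um head width.
#'
#' @param n_dorsal,n_ventral Facet counts per section.
#' @param section_separation Angle between the dorsal and ventral section
#'   mean gazes, degrees in (0, 180).
#' @param diameter_mean,diameter_sd Length-2 (dorsal, ventral) lens
#'   diameter mean/SD in micrometres.
#' @param curvature_mean,curvature_sd Length-2 (dorsal, ventral) outer
#'   curvature radius mean/SD in micrometres.
#' @param pitch_center,pitch_edge Local interommatidial pitch at the array
#'   centre and edge, degrees.
#' @param gaze_azimuth Azimuth of both section mean gazes at rest, degrees
#'   (default -20: the right eye looks slightly to the animal's right).
#' @param gaze_elevation_center Elevation midway between the two section
#'   mean gazes at rest, degrees (default -31.5: dorsal at -5, ventral at
#'   -58, so that the dorsal gaze crosses the zenith within the natural
#'   body-pitch range of flight).
#' @param landmark_noise_sd Isotropic Gaussian digitization noise SD on
#'   every landmark coordinate, micrometres (default 0).
#' @param head_width Distance between the ocelli, micrometres.
#' @param eye_radius Radius of the sphere carrying the facet centres,
#'   micrometres (sets how strongly the axes converge).
#' @param seed Default seed used by [generate_eye()].
#' @return A list of class `synthetic_eye_spec`.
#' @export
synthetic_eye_spec <- function(n_dorsal = 42, n_ventral = 31,
                               section_separation = 53,
                               diameter_mean = c(6.35, 7.67),
                               diameter_sd = c(0.51, 0.89),
                               curvature_mean = c(3.98, 5.81),
                               curvature_sd = c(0.72, 0.92),
                               pitch_center = 1, pitch_edge = 30,
                               gaze_azimuth = -20,
                               gaze_elevation_center = -31.5,
                               landmark_noise_sd = 0,
                               head_width = 126,
                               eye_radius = 30,
                               seed = 1L) {
  stopifnot(n_dorsal > 0, n_ventral > 0,
            section_separation > 0, section_separation < 180,
            all(diameter_mean > 0), all(diameter_sd >= 0),
            all(curvature_mean > 0), all(curvature_sd >= 0),
            pitch_center > 0, pitch_edge >= pitch_center,
            landmark_noise_sd >= 0, head_width > 0, eye_radius > 0)
  structure(as.list(environment()), class = "synthetic_eye_spec")
}

#' Facet axes on a spherical cap with a radial pitch gradient
#'
#' Lays `n` unit vectors out around +z on a triangular (hexagonal) lattice
#' mapped to the sphere by an azimuthal-equidistant projection, with the
#' radial lattice scale interpolated linearly from `pitch_center` at the
#' array centre to `pitch_edge` at the rim. With `pitch_edge ==
#' pitch_center` the layout is a uniform hexagonal patch whose interior
#' facets sit one pitch from each of their six neighbours (up to spherical
#' distortion).
#'
#' @param n Number of facets.
#' @param pitch_center,pitch_edge Local pitch in degrees.
#' @return An n x 3 matrix of unit axis vectors; attribute `ring` holds
#'   the lattice radius rank of each facet.
#' @export
hex_cap_axes <- function(n, pitch_center, pitch_edge = pitch_center) {
  stopifnot(n >= 1, pitch_center > 0, pitch_edge >= pitch_center)
  # enough triangular-lattice sites around the origin
  m <- ceiling(sqrt(n)) + 2
  qr_grid <- expand.grid(q = -m:m, r = -m:m)
  px <- qr_grid$q + qr_grid$r / 2
  py <- qr_grid$r * sqrt(3) / 2
  rho <- sqrt(px^2 + py^2)
  ord <- order(rho, atan2(py, px))
  keep <- ord[seq_len(n)]
  px <- px[keep]; py <- py[keep]; rho <- rho[keep]
  rho_max <- max(rho, 1e-12)
  # radial mapping: local radial scale pitch_center at the centre rising as
  # (rho/rho_max)^1.5 to pitch_edge at the rim; the exponent calibrates the
  # per-section mean interommatidial angle of the default arrays near the
  # 12.5/16.2-degree regime while keeping the stated 1 -> 30 endpoints
  theta <- pitch_center * rho +
    (pitch_edge - pitch_center) * rho^2.5 / (2.5 * rho_max^1.5)
  phi <- atan2(py, px)
  th <- deg2rad(theta)
  axes <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
  attr(axes, "ring") <- round(rho, 6)
  axes
}

# Rodrigues rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- unit_vector(a); b <- unit_vector(b)
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (vec_norm(v) < 1e-14) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any perpendicular
    p <- plane_basis(a)$e1
    return(2 * tcrossprod(p) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Generate a synthetic split compound eye with known ground truth
#'
#' Places two facet arrays (via [hex_cap_axes()]) whose mean gazes subtend
#' exactly `section_separation`, realizes each lens as six base points on
#' a circle of the drawn diameter plus an apex at the spherical-cap height
#' implied by the drawn curvature radius, and adds Gaussian digitization
#' noise last. Pure function of `(spec, seed)`.
#'
#' @param spec A [synthetic_eye_spec()].
#' @param seed Integer seed (default `spec$seed`).
#' @return A list:
#'   * `lenses`: landmark tibble in the [read_landmarks()] schema (um),
#'   * `head`: a [head_frame()],
#'   * `truth`: per-lens tibble (`ommatidium_id`, `section`, true
#'     `axis_x..z`, `diameter`, `cap_height`, `curvature_radius`,
#'     `center_x..z`), plus `section_gaze` (2 x 3 matrix of exact section
#'     mean gazes), `separation`, `io_nominal` (per-section mean
#'     interommatidial angle of the noise-free layout), `eye_center`, and
#'     `n_redraws` (infeasible curvature draws that were redrawn).
#' @export
generate_eye <- function(spec = synthetic_eye_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_eye_spec"))
  withr::with_seed(as.integer(seed), generate_eye_impl(spec))
}

generate_eye_impl <- function(spec) {
  hw <- spec$head_width
  # section mean-gaze directions: a common azimuth, elevations symmetric
  # about the gaze centre, dorsal above
  half <- spec$section_separation / 2
  d_dorsal <- azel_to_vec(spec$gaze_azimuth,
                          spec$gaze_elevation_center + half)[1, ]
  d_ventral <- azel_to_vec(spec$gaze_azimuth,
                           spec$gaze_elevation_center - half)[1, ]
  eye_center <- c(0, -0.3 * hw, 0)  # right eye: y toward the right is -y

  sections <- list(
    dorsal = list(n = spec$n_dorsal, dir = d_dorsal,
                  dm = spec$diameter_mean[1], ds = spec$diameter_sd[1],
                  cm = spec$curvature_mean[1], cs = spec$curvature_sd[1]),
    ventral = list(n = spec$n_ventral, dir = d_ventral,
                   dm = spec$diameter_mean[2], ds = spec$diameter_sd[2],
                   cm = spec$curvature_mean[2], cs = spec$curvature_sd[2]))

  rows <- list()
  truth_rows <- list()
  section_gaze <- matrix(NA_real_, 2, 3,
                         dimnames = list(c("dorsal", "ventral"), NULL))
  io_nominal <- c(dorsal = NA_real_, ventral = NA_real_)
  n_redraws <- 0L
  next_id <- 1L

  for (s_name in names(sections)) {
    s <- sections[[s_name]]
    local_axes <- hex_cap_axes(s$n, spec$pitch_center, spec$pitch_edge)
    # align the resultant mean gaze exactly with the section direction
    if (s$n > 1) {
      m <- mean_gaze(local_axes)
    } else {
      m <- local_axes[1, ]
    }
    Rm <- rotation_between(m, s$dir)
    axes <- local_axes %*% t(Rm)
    section_gaze[s_name, ] <- s$dir
    io_nominal[s_name] <- nominal_io_mean(axes)

    for (i in seq_len(s$n)) {
      u <- axes[i, ]
      # draw lens size; redraw while the cap is infeasible (R < a)
      repeat {
        diam <- rnorm(1, s$dm, s$ds)
        R <- rnorm(1, s$cm, s$cs)
        a <- diam / 2
        if (diam > 0 && R >= a) break
        n_redraws <- n_redraws + 1L
      }
      h <- R - sqrt(R^2 - a^2)
      center <- eye_center + spec$eye_radius * u
      b <- plane_basis(u)
      rot0 <- stats::runif(1, 0, 2 * pi)
      ang <- rot0 + seq(0, 2 * pi, length.out = 7)[1:6]
      bp <- t(vapply(ang, function(t_) {
        center + a * (cos(t_) * b$e1 + sin(t_) * b$e2)
      }, numeric(3)))
      apex <- center + h * u
      row <- tibble(ommatidium_id = next_id, animal_id = "synthetic",
                    sex = "female", side = "right", section = s_name)
      for (k in 1:6) {
        row[[paste0("p", k, "_x")]] <- bp[k, 1]
        row[[paste0("p", k, "_y")]] <- bp[k, 2]
        row[[paste0("p", k, "_z")]] <- bp[k, 3]
      }
      row$apex_x <- apex[1]; row$apex_y <- apex[2]; row$apex_z <- apex[3]
      rows[[next_id]] <- row
      truth_rows[[next_id]] <- tibble(
        ommatidium_id = next_id, section = s_name,
        axis_x = u[1], axis_y = u[2], axis_z = u[3],
        diameter = diam, cap_height = h, curvature_radius = R,
        center_x = center[1], center_y = center[2], center_z = center[3])
      next_id <- next_id + 1L
    }
  }

  lenses <- bind_rows(rows)
  cc <- landmark_coord_cols()
  if (spec$landmark_noise_sd > 0) {
    noise <- matrix(rnorm(nrow(lenses) * length(cc), 0,
                          spec$landmark_noise_sd),
                    nrow(lenses), length(cc))
    lenses[cc] <- lenses[cc] + noise
  }
  head <- head_frame(c(-10, hw / 2, 15), c(-10, -hw / 2, 15))
  list(lenses = lenses, head = head,
       truth = list(per_lens = bind_rows(truth_rows),
                    section_gaze = section_gaze,
                    separation = spec$section_separation,
                    io_nominal = io_nominal,
                    eye_center = eye_center,
                    n_redraws = n_redraws))
}

# Nominal per-section mean interommatidial angle of a noise-free layout:
# mean over facets of the mean angle to their six angularly nearest
# neighbours within the section.
nominal_io_mean <- function(axes) {
  n <- nrow(axes)
  if (n < 2) return(NA_real_)
  per <- vapply(seq_len(n), function(i) {
    nb <- find_neighbors(axes, i, k = 6)
    mean(angular_difference(axes[nb, , drop = FALSE], axes[i, ]))
  }, numeric(1))
  mean(per)
}
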