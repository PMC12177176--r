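# Per-lens geometry reconstruction: head-width normalization, maximum-area
# basis plane, least-squares circle fit, spherical-cap curvature and the
# unit visual axis.

#' Normalize landmark coordinates to head width
#'
#' Divides every coordinate by the distance between the two ocelli, making
#' eye geometry comparable across individuals of different size. Angles
#' between landmarks are unchanged by this pure scaling.
#'
#' @param lenses Lens-landmark tibble (see [read_landmarks()]).
#' @param head A [head_frame()] providing `head_width`.
#' @return The landmark tibble with all coordinate columns divided by
#'   head width (dimensionless).
#' @export
normalize_to_head_width <- function(lenses, head) {
  if (!inherits(head, "head_frame")) {
    abort("`head` must be a head_frame object.", class = "splitgaze_schema_error")
  }
  if (!is.finite(head$head_width) || head$head_width <= 0) {
    abort("head_width must be > 0.", class = "splitgaze_schema_error")
  }
  lenses <- as_tibble(lenses)
  cc <- intersect(landmark_coord_cols(), names(lenses))
  lenses[cc] <- lenses[cc] / head$head_width
  lenses
}

#' Fit the maximum-area basis plane of a lens
#'
#' Finds the plane onto which the orthogonal projection of the six
#' digitized base points has maximum polygon area — the plane of the lens
#' opening. A total-least-squares plane (smallest singular direction of the
#' centred points) seeds a local optimization of the projected area over
#' unit normals; a coarse spherical grid guards against a bad start.
#'
#' @param base_points 6 x 3 numeric matrix of base points.
#' @param grid_guard Logical; also scan a 10 deg hemispheric grid of
#'   candidate normals and keep the best (default TRUE).
#' @return A list: `normal` (unit vector), `centroid`, `points2d` (6 x 2
#'   in-plane coordinates about the centroid), `basis` (list of the two
#'   in-plane axes), `area` (projected polygon area).
#' @export
fit_basis_plane <- function(base_points, grid_guard = TRUE) {
  base_points <- as.matrix(base_points)
  if (nrow(base_points) < 3 || ncol(base_points) != 3) {
    abort("base_points must be an n x 3 matrix with n >= 3.",
          class = "splitgaze_schema_error")
  }
  ctr <- colMeans(base_points)
  x <- sweep(base_points, 2, ctr)
  sv <- svd(x)
  if (sv$d[2] < max(sv$d[1], 1) * 1e-12) {
    abort("Base points are collinear or coincident; no basis plane.",
          class = "splitgaze_degenerate_geometry")
  }
  # TLS seed: normal = direction of smallest spread
  n0 <- sv$v[, 3]

  obj <- function(ang) -projected_area(x, azel_to_vec(ang[1], ang[2])[1, ])
  start <- vec_to_azel(n0)
  opt <- stats::optim(c(start$azimuth, start$elevation), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  best_n <- azel_to_vec(opt$par[1], opt$par[2])[1, ]
  best_a <- -opt$value

  if (grid_guard) {
    g <- expand.grid(az = seq(-180, 170, by = 10), el = seq(0, 90, by = 10))
    for (i in seq_len(nrow(g))) {
      nn <- azel_to_vec(g$az[i], g$el[i])[1, ]
      a <- projected_area(x, nn)
      if (a > best_a + 1e-12) {
        o2 <- stats::optim(c(g$az[i], g$el[i]), obj, method = "Nelder-Mead",
                           control = list(reltol = 1e-12, maxit = 500))
        if (-o2$value > best_a) {
          best_a <- -o2$value
          best_n <- azel_to_vec(o2$par[1], o2$par[2])[1, ]
        }
      }
    }
  }
  best_n <- unit_vector(best_n)
  b <- plane_basis(best_n)
  p2 <- cbind(x %*% b$e1, x %*% b$e2)
  colnames(p2) <- c("u", "v")
  list(normal = best_n, centroid = ctr, points2d = p2, basis = b,
       area = best_a)
}

#' Least-squares circle fit in the plane
#'
#' Algebraic (Kasa) circle fit followed by Gauss-Newton refinement of the
#' geometric distance, converged to 1e-10 relative change. The lens
#' diameter is `2 * radius` and the optical aperture `pi * radius^2`.
#'
#' @param points2d n x 2 matrix of in-plane points, n >= 3, not collinear.
#' @return List with `center` (length-2), `radius`, `residual_rms` (RMS of
#'   radial residuals) and `cost` (sum of squared radial residuals).
#' @export
fit_circle <- function(points2d) {
  p <- as.matrix(points2d)
  if (nrow(p) < 3 || ncol(p) != 2) {
    abort("points2d must be an n x 2 matrix with n >= 3.",
          class = "splitgaze_schema_error")
  }
  # collinearity check on centred points
  pc <- sweep(p, 2, colMeans(p))
  if (svd(pc)$d[2] < max(svd(pc)$d[1], 1) * 1e-10) {
    abort("Points are collinear; no circle fit.",
          class = "splitgaze_degenerate_geometry")
  }
  # Kasa: minimize ||x||^2 - 2 c.x + c.c - r^2 linearly in (c, r^2 - c.c)
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  sol <- qr.solve(A, b)
  ctr <- sol[1:2]
  r <- sqrt(sol[3] + sum(ctr^2))

  # Gauss-Newton on geometric residuals d_i - r
  for (iter in 1:100) {
    dx <- p[, 1] - ctr[1]
    dy <- p[, 2] - ctr[2]
    d <- sqrt(dx^2 + dy^2)
    res <- d - r
    J <- cbind(-dx / d, -dy / d, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
    ctr_new <- ctr + step[1:2]
    r_new <- r + step[3]
    if (!is.finite(r_new) || r_new <= 0) break
    rel <- vec_norm(step) / max(r, 1e-30)
    ctr <- ctr_new
    r <- r_new
    if (rel < 1e-10) break
  }
  d <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
  res <- d - r
  list(center = unname(ctr), radius = unname(r),
       residual_rms = sqrt(mean(res^2)), cost = sum(res^2))
}

#' Unit visual axis of an ommatidium
#'
#' The gaze vector: the unit direction from the fitted circle centre on the
#' lens base out through the digitized lens-top point.
#'
#' @param apex_point Length-3 lens-top point.
#' @param circle_center_3d Length-3 fitted base-circle centre.
#' @return Unit length-3 vector pointing out of the eye.
#' @export
visual_axis <- function(apex_point, circle_center_3d) {
  unit_vector(as.numeric(apex_point) - as.numeric(circle_center_3d),
              what = "visual axis (apex coincides with circle centre)")
}

#' Spherical-cap radius of curvature
#'
#' Models the outer corneal surface as a spherical cap through the fitted
#' base circle (radius `a`) and the apex at orthogonal height `h` above the
#' basis plane: `R = (a^2 + h^2) / (2 h)`.
#'
#' @param circle_radius Base-circle radius `a` (> 0).
#' @param cap_height Apex height `h` above the basis plane (> 0).
#' @return Curvature radius in the same units.
#' @examples
#' curvature_radius(1, 1) # hemisphere: R = 1
#' curvature_radius(3, 1) # R = 5
#' @export
curvature_radius <- function(circle_radius, cap_height) {
  if (any(cap_height <= 0)) {
    abort("cap_height must be > 0 (apex on the outward side of the plane).",
          class = "splitgaze_degenerate_geometry")
  }
  if (any(circle_radius <= 0)) {
    abort("circle_radius must be > 0.", class = "splitgaze_degenerate_geometry")
  }
  (circle_radius^2 + cap_height^2) / (2 * cap_height)
}

# Full reconstruction of one landmark row. Returns a one-row tibble.
reconstruct_lens <- function(row, grid_guard = FALSE) {
  bp <- base_point_matrix(row)
  apex <- apex_point(row)
  pl <- fit_basis_plane(bp, grid_guard = grid_guard)
  # orient the normal toward the apex so cap height is positive
  h_signed <- sum((apex - pl$centroid) * pl$normal)
  if (h_signed < 0) {
    pl$normal <- -pl$normal
    pl$basis <- plane_basis(pl$normal)
    pl$points2d <- cbind(sweep(bp, 2, pl$centroid) %*% pl$basis$e1,
                         sweep(bp, 2, pl$centroid) %*% pl$basis$e2)
    h_signed <- -h_signed
  }
  circ <- fit_circle(pl$points2d)
  center3d <- pl$centroid + circ$center[1] * pl$basis$e1 +
    circ$center[2] * pl$basis$e2
  axis <- visual_axis(apex, center3d)
  # cap height: orthogonal distance from apex to the basis plane
  h <- sum((apex - pl$centroid) * pl$normal)
  R <- curvature_radius(circ$radius, h)
  tibble(
    ommatidium_id = row$ommatidium_id,
    animal_id = row$animal_id,
    side = row$side,
    section = row$section,
    center_x = center3d[1], center_y = center3d[2], center_z = center3d[3],
    diameter = 2 * circ$radius,
    aperture_area = pi * circ$radius^2,
    cap_height = h,
    curvature_radius = R,
    axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
    residual_rms = circ$residual_rms
  )
}

#' Reconstruct per-lens geometry for a whole eye
#'
#' Runs the full per-ommatidium reconstruction on a landmark table:
#' maximum-area basis plane, least-squares base circle, spherical-cap
#' curvature radius, and unit visual axis (base-circle centre through the
#' lens top).
#'
#' @param lenses Lens-landmark tibble (validated; see [read_landmarks()]).
#' @param grid_guard Logical, passed to [fit_basis_plane()]. The default
#'   `FALSE` relies on the total-least-squares start, which is exact for
#'   near-planar lens bases; set `TRUE` for pathological digitizations.
#' @return A tibble with one row per ommatidium: fitted circle centre
#'   (`center_x..z`), `diameter`, `aperture_area`, `cap_height`,
#'   `curvature_radius`, unit `axis_x..z` and `residual_rms` of the circle
#'   fit, in the input units.
#' @export
lens_geometry <- function(lenses, grid_guard = FALSE) {
  lenses <- validate_landmarks(lenses)
  if (nrow(lenses) == 0) {
    return(reconstruct_lens(demo_lens_row(), grid_guard = FALSE)[0, ])
  }
  purrr::map_dfr(seq_len(nrow(lenses)), function(i) {
    tryCatch(
      reconstruct_lens(lenses[i, ], grid_guard = grid_guard),
      error = function(e) {
        abort(sprintf("Lens reconstruction failed for ommatidium_id %s: %s",
                      lenses$ommatidium_id[i], conditionMessage(e)),
              class = "splitgaze_geometry_error")
      })
  })
}

# A minimal valid row used to derive the empty-geometry schema.
demo_lens_row <- function() {
  hexa <- azel_to_vec(seq(0, 300, by = 60), 0)[, 1:2]
  row <- tibble(ommatidium_id = 1L, animal_id = "demo", sex = "unknown",
                side = "right", section = "dorsal")
  for (i in 1:6) {
    row[[paste0("p", i, "_x")]] <- hexa[i, 1]
    row[[paste0("p", i, "_y")]] <- hexa[i, 2]
    row[[paste0("p", i, "_z")]] <- 0
  }
  row$apex_x <- 0; row$apex_y <- 0; row$apex_z <- 0.5
  row
}
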