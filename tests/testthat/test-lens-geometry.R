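# Per-lens geometry: normalization, basis plane, circle fit, curvature,
# visual axis, and the equivariance/recovery properties.

test_that("head-width normalization scales coordinates and preserves angles", {
  eye <- generate_eye(synthetic_eye_spec(n_dorsal = 6, n_ventral = 5))
  head2 <- head_frame(c(0, 1, 0), c(0, -1, 0))  # width 2
  norm2 <- normalize_to_head_width(eye$lenses, head2)
  expect_equal(norm2$p1_x, eye$lenses$p1_x / 2)
  expect_equal(norm2$apex_z, eye$lenses$apex_z / 2)

  head1 <- head_frame(c(0, 0.5, 0), c(0, -0.5, 0))  # width 1: identity
  expect_equal(as.data.frame(normalize_to_head_width(eye$lenses, head1)),
               as.data.frame(eye$lenses))

  # interommatidial angles are scale-invariant
  m_raw <- eye_map(lens_geometry(eye$lenses))
  m_norm <- eye_map(lens_geometry(normalize_to_head_width(eye$lenses,
                                                          eye$head)))
  expect_equal(m_norm$interommatidial_angle, m_raw$interommatidial_angle,
               tolerance = 1e-9)

  degenerate <- head_frame(c(0, 1, 0), c(0, -1, 0))
  degenerate$head_width <- 0
  expect_error(normalize_to_head_width(eye$lenses, degenerate),
               class = "splitgaze_schema_error")
})

test_that("basis plane maximizes the projected lens-base area", {
  hexa <- regular_hexagon(r = 1, z0 = 3)
  pl <- fit_basis_plane(hexa)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-9)
  expect_equal(pl$area, 3 * sqrt(3) / 2, tolerance = 1e-9)

  # jittered hexagons: fitted plane beats every normal on a 2-degree grid
  withr::with_seed(42, {
    grid <- normal_grid(by = 2)
    for (rep in 1:5) {
      pts <- regular_hexagon(r = 1) + cbind(0, 0, rnorm(6, 0, 0.05))
      pl <- fit_basis_plane(pts)
      ctr <- sweep(pts, 2, colMeans(pts))
      grid_areas <- apply(grid, 1, function(n) oracle_projected_area(ctr, n))
      expect_gte(pl$area + 1e-9, max(grid_areas))
    }
  })

  expect_error(fit_basis_plane(matrix(1, 6, 3), grid_guard = FALSE),
               class = "splitgaze_degenerate_geometry")
  collinear <- cbind(1:6, 2 * (1:6), 3 * (1:6))
  expect_error(fit_basis_plane(collinear, grid_guard = FALSE),
               class = "splitgaze_degenerate_geometry")
})

test_that("circle fit is exact on hexagons and optimal under noise", {
  f <- fit_circle(regular_hexagon(r = 1)[, 1:2])
  expect_equal(f$center, c(0, 0), tolerance = 1e-10)
  expect_equal(f$radius, 1, tolerance = 1e-10)

  # half the 6.35 um mean dorsal lens diameter
  f2 <- fit_circle(regular_hexagon(r = 3.175)[, 1:2])
  expect_equal(f2$radius, 3.175, tolerance = 1e-10)
  expect_equal(2 * f2$radius, 6.35, tolerance = 1e-10)

  withr::with_seed(7, {
    for (rep in 1:3) {
      p2 <- regular_hexagon(r = 1)[, 1:2] + matrix(rnorm(12, 0, 0.1), 6, 2)
      fit <- fit_circle(p2)
      expect_lte(fit$cost, grid_circle_cost(p2) + 1e-6)
    }
  })

  expect_error(fit_circle(cbind(1:5, 2 * (1:5))),
               class = "splitgaze_degenerate_geometry")
})

test_that("visual axis points from the circle centre through the apex", {
  expect_equal(visual_axis(c(0, 0, 1), c(0, 0, 0)), c(0, 0, 1))
  expect_equal(visual_axis(c(2, 2, 2), c(1, 1, 1)), rep(1 / sqrt(3), 3))
  expect_error(visual_axis(c(1, 2, 3), c(1, 2, 3)),
               class = "splitgaze_degenerate_geometry")
})

test_that("spherical-cap curvature radius follows R = (a^2 + h^2) / 2h", {
  expect_equal(curvature_radius(1, 1), 1)    # hemisphere
  expect_equal(curvature_radius(3, 1), 5)
  expect_error(curvature_radius(1, 0), class = "splitgaze_degenerate_geometry")
  expect_error(curvature_radius(1, -0.2),
               class = "splitgaze_degenerate_geometry")

  # base circle + apex sampled exactly from a 3.98 um sphere is recovered
  R <- 3.98; a <- 2.5
  h <- R - sqrt(R^2 - a^2)
  row <- make_lens_row(center = c(5, -3, 2), axis = c(1, 2, 2), a = a, h = h)
  g <- lens_geometry(row)
  expect_equal(g$curvature_radius, R, tolerance = 1e-9)
})

test_that("geometry is rigid-motion equivariant and scale covariant", {
  withr::with_seed(11, {
    row <- make_lens_row(center = c(2, 1, -1), axis = c(1, -1, 2),
                         a = 3, h = 1.2, phase = 0.3)
    g0 <- lens_geometry(row)
    for (rep in 1:3) {
      Q <- random_rotation()
      tr <- rnorm(3, 0, 5)
      moved <- row
      cc <- matrix(as.numeric(row[1, -(1:5)]), ncol = 3, byrow = TRUE)
      mc <- t(Q %*% t(cc)) + matrix(tr, nrow(cc), 3, byrow = TRUE)
      moved[1, -(1:5)] <- as.list(as.numeric(t(mc)))
      g1 <- lens_geometry(moved)
      expect_equal(g1$diameter, g0$diameter, tolerance = 1e-9)
      expect_equal(g1$aperture_area, g0$aperture_area, tolerance = 1e-9)
      expect_equal(g1$cap_height, g0$cap_height, tolerance = 1e-9)
      expect_equal(g1$curvature_radius, g0$curvature_radius, tolerance = 1e-9)
      ax0 <- c(g0$axis_x, g0$axis_y, g0$axis_z)
      ax1 <- c(g1$axis_x, g1$axis_y, g1$axis_z)
      expect_lt(angular_difference(ax1, as.numeric(Q %*% ax0)), 1e-7)
    }

    s <- 2.5
    scaled <- row
    scaled[1, -(1:5)] <- as.list(as.numeric(row[1, -(1:5)]) * s)
    gs <- lens_geometry(scaled)
    expect_equal(gs$diameter, s * g0$diameter, tolerance = 1e-9)
    expect_equal(gs$cap_height, s * g0$cap_height, tolerance = 1e-9)
    expect_equal(gs$curvature_radius, s * g0$curvature_radius,
                 tolerance = 1e-9)
    expect_equal(gs$aperture_area, s^2 * g0$aperture_area, tolerance = 1e-9)
    expect_equal(c(gs$axis_x, gs$axis_y, gs$axis_z),
                 c(g0$axis_x, g0$axis_y, g0$axis_z), tolerance = 1e-9)
  })
})

test_that("zero-noise synthetic eyes are recovered to numerical precision", {
  eye <- generate_eye(synthetic_eye_spec(n_dorsal = 12, n_ventral = 9))
  g <- lens_geometry(eye$lenses)
  tr <- eye$truth$per_lens
  expect_equal(g$diameter, tr$diameter, tolerance = 1e-6)
  expect_equal(g$curvature_radius, tr$curvature_radius, tolerance = 1e-6)
  expect_equal(g$cap_height, tr$cap_height, tolerance = 1e-6)
  expect_equal(g$aperture_area, pi * tr$diameter^2 / 4, tolerance = 1e-6)
  axerr <- vapply(seq_len(nrow(g)), function(i) {
    angular_difference(c(g$axis_x[i], g$axis_y[i], g$axis_z[i]),
                       c(tr$axis_x[i], tr$axis_y[i], tr$axis_z[i]))
  }, numeric(1))
  expect_lt(max(axerr), 1e-6)
})

test_that("median axis error grows monotonically with landmark noise", {
  sigmas <- c(0, 0.1, 0.3)
  med_err <- vapply(seq_along(sigmas), function(k) {
    eye <- generate_eye(synthetic_eye_spec(n_dorsal = 30, n_ventral = 20,
                                           landmark_noise_sd = sigmas[k]),
                        seed = 100 + k)
    g <- lens_geometry(eye$lenses)
    tr <- eye$truth$per_lens
    stats::median(vapply(seq_len(nrow(g)), function(i) {
      angular_difference(c(g$axis_x[i], g$axis_y[i], g$axis_z[i]),
                         c(tr$axis_x[i], tr$axis_y[i], tr$axis_z[i]))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_err) > 0))
})
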