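# Mean gaze, convergence point, rotations, sphere projection and sweeps.

test_that("mean gaze is the normalized vector sum", {
  v <- c(0.2, -0.4, 0.89)
  expect_equal(mean_gaze(v), v / sqrt(sum(v^2)))
  sym <- rbind(c(1, 0, 0.01), c(1, 0, -0.01))
  expect_equal(mean_gaze(sym), c(1, 0, 0), tolerance = 1e-12)
  anti <- rbind(c(0, 0, 1), c(0, 0, -1))
  expect_error(mean_gaze(anti), class = "splitgaze_degenerate_gaze")
})

test_that("convergence point solves the least-squares line intersection", {
  P <- c(1, -2, 3)
  withr::with_seed(21, {
    dirs <- matrix(rnorm(30), 10, 3)
    origins <- matrix(P, 10, 3, byrow = TRUE) + 5 * dirs
    expect_equal(convergence_point(origins, dirs), P, tolerance = 1e-9)

    # two perpendicular skew lines: midpoint of the common perpendicular
    o <- rbind(c(0, 0, 0), c(0, 0, 1))
    d <- rbind(c(1, 0, 0), c(0, 1, 0))
    expect_equal(convergence_point(o, d), c(0, 0, 0.5), tolerance = 1e-12)

    # noisy bundle matches the explicit normal-equations oracle exactly
    dirs <- matrix(rnorm(60), 20, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    origins <- matrix(P, 20, 3, byrow = TRUE) + 3 * dirs +
      matrix(rnorm(60, 0, 0.05), 20, 3)
    A <- matrix(0, 3, 3); b <- numeric(3)
    for (i in 1:20) {
      Pr <- diag(3) - tcrossprod(dirs[i, ])
      A <- A + Pr; b <- b + Pr %*% origins[i, ]
    }
    expect_equal(convergence_point(origins, dirs),
                 as.numeric(solve(A, b)), tolerance = 1e-9)
    expect_lt(sqrt(sum((convergence_point(origins, dirs) - P)^2)), 3 * 0.05 * 3)
  })
  par <- rbind(c(1, 1, 1), c(1, 1, 1))
  expect_error(convergence_point(rbind(c(0, 0, 0), c(1, 0, 0)), par),
               class = "splitgaze_degenerate_geometry")
})

test_that("rotation matrices follow the z-y-x nose-up convention", {
  expect_equal(rotation_matrix(), diag(3))
  expect_equal(as.numeric(rotation_matrix(yaw = 90) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  expect_equal(as.numeric(rotation_matrix(pitch = 90) %*% c(1, 0, 0)),
               c(0, 0, 1), tolerance = 1e-12)
  withr::with_seed(3, {
    for (rep in 1:20) {
      y <- stats::runif(1, -180, 180)
      p <- stats::runif(1, -180, 180)
      r <- stats::runif(1, -180, 180)
      R <- rotation_matrix(y, p, r)
      expect_equal(R, quat_rotation_oracle(y, p, r), tolerance = 1e-12)
      expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
      expect_equal(det(R), 1, tolerance = 1e-12)
    }
  })
})

test_that("sphere projection returns spherical coordinates of the hit point", {
  s <- sphere_config()
  expect_equal(as.numeric(project_to_sphere(c(0, 0, 0), c(1, 0, 0), s)),
               c(0, 0))
  expect_equal(project_to_sphere(c(0, 0, 0), c(0, 0, 1), s)$elevation, 90)
  off <- project_to_sphere(c(0, 1, 0), c(1, 0, 0), s)
  expect_equal(off$azimuth, atan2(1, sqrt(99)) * 180 / pi, tolerance = 1e-9)
  expect_equal(off$elevation, 0, tolerance = 1e-12)
  expect_error(project_to_sphere(c(11, 0, 0), c(1, 0, 0), s),
               class = "splitgaze_schema_error")
})

test_that("section gaze separation matches construction", {
  expect_equal(section_gaze_separation(rbind(c(1, 0, 0)), rbind(c(1, 0, 0))), 0)
  expect_equal(section_gaze_separation(rbind(c(1, 0, 0)), rbind(c(0, 1, 0))),
               90)
  eye <- generate_eye()
  m <- eye_map(lens_geometry(eye$lenses))
  expect_equal(section_gaze_separation(m), 53, tolerance = 1e-6)
})

test_that("yaw sweeps change azimuth degree-for-degree at fixed elevation", {
  map <- dplyr::bind_rows(
    tibble::tibble(section = "dorsal", axis_x = cos(0.3), axis_y = 0,
                   axis_z = sin(0.3)),
    tibble::tibble(section = "ventral", axis_x = cos(0.5), axis_y = 0.2,
                   axis_z = -sin(0.5)))
  sw <- gaze_sweep(map, axis = "yaw", range = c(-90, 90), step = 1)
  for (s in c("dorsal", "ventral")) {
    el <- sw$elevation[sw$section == s]
    az <- sw$azimuth[sw$section == s]
    expect_lt(diff(range(el)), 1e-6)
    expect_equal(diff(az), rep(1, length(az) - 1), tolerance = 1e-9)
  }
})

test_that("pitch sweeps move a sagittal gaze degree-for-degree in elevation", {
  map <- tibble::tibble(section = c("dorsal", "ventral"),
                        axis_x = c(cos(pi / 9), -cos(pi / 3)),
                        axis_y = c(0, 0),
                        axis_z = c(sin(pi / 9), sin(pi / 3)))
  sw <- gaze_sweep(map, axis = "pitch", range = c(0, 50), step = 1)
  # forward-pointing gaze at elevation 20: EL rises degree-for-degree
  eld <- sw$elevation[sw$section == "dorsal"]
  expect_equal(diff(eld), rep(1, 50), tolerance = 1e-9)
  expect_lt(diff(range(sw$azimuth[sw$section == "dorsal"])), 1e-9)
  # up-and-backward gaze (past vertical): EL falls degree-for-degree
  elv <- sw$elevation[sw$section == "ventral"]
  expect_equal(diff(elv), rep(-1, 50), tolerance = 1e-9)
})

test_that("1 mm ray-origin offsets move the projection by at most asin(1/10)", {
  bound <- asin(1 / 10) * 180 / pi  # 5.739 deg on the 10 mm sphere
  s <- sphere_config()
  withr::with_seed(17, {
    worst <- 0
    for (rep in 1:1000) {
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      o <- rnorm(3, 0, 0.2)
      shift <- rnorm(3); shift <- shift / sqrt(sum(shift^2)) *
        stats::runif(1, 0, 1)
      a <- project_to_sphere(o, d, s)
      b <- project_to_sphere(o + shift, d, s)
      gc <- angular_difference(azel_dir(a$azimuth, a$elevation)[1, ],
                               azel_dir(b$azimuth, b$elevation)[1, ])
      worst <- max(worst, gc)
      expect_lte(gc, bound + 1e-9)
    }
    expect_gt(worst, 1)  # the bound is approached, not vacuous
  })
})

test_that("sweep samples are continuous and degenerate poses are flagged", {
  eye <- generate_eye()
  m <- eye_map(lens_geometry(eye$lenses))
  for (ax in c("pitch", "roll")) {
    sw <- gaze_sweep(m, axis = ax, step = 1)
    expect_false(any(sw$flagged))
    for (s in unique(sw$section)) {
      sub <- sw[sw$section == s, ]
      v1 <- azel_dir(sub$azimuth[-nrow(sub)], sub$elevation[-nrow(sub)])
      v2 <- azel_dir(sub$azimuth[-1], sub$elevation[-1])
      step_gc <- acos(pmin(1, rowSums(v1 * v2))) * 180 / pi
      expect_lt(max(step_gc), 3)
    }
  }
})

test_that("pitch and roll sweeps show complementary Az/EL dominance", {
  # matched +/-30 degree sweeps about the typical flight posture
  eye <- generate_eye()
  m <- eye_map(lens_geometry(eye$lenses))
  pw <- gaze_sweep(m, axis = "pitch", range = c(-30, 30), step = 1,
                   base_pitch = 80)
  rw <- gaze_sweep(m, axis = "roll", range = c(-30, 30), step = 1,
                   base_pitch = 80)
  path_lengths <- function(sw, s) {
    sub <- sw[sw$section == s, ]
    daz <- diff(sub$azimuth)
    daz <- ifelse(daz > 180, daz - 360, ifelse(daz < -180, daz + 360, daz))
    elm <- (sub$elevation[-1] + sub$elevation[-nrow(sub)]) / 2
    c(h = sum(abs(daz * cos(elm * pi / 180))),
      v = sum(abs(diff(sub$elevation))))
  }
  pd <- path_lengths(pw, "dorsal"); pv <- path_lengths(pw, "ventral")
  rd <- path_lengths(rw, "dorsal"); rv <- path_lengths(rw, "ventral")
  # pitch: dorsal dominates horizontally, ventral vertically
  expect_gt(pd["h"], pv["h"])
  expect_gt(pv["v"], pd["v"])
  # roll: the ordering flips
  expect_gt(rv["h"], rd["h"])
  expect_gt(rd["v"], rv["v"])
})

test_that("a zero-width sweep returns the static gaze", {
  eye <- generate_eye(synthetic_eye_spec(n_dorsal = 6, n_ventral = 5))
  m <- eye_map(lens_geometry(eye$lenses))
  sw <- gaze_sweep(m, axis = "pitch", range = c(0, 0))
  expect_equal(nrow(sw), 2)
  expect_equal(sort(unique(sw$section)), c("dorsal", "ventral"))
})
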