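# Shared fixtures and independent oracles used across the suite.

# Regular hexagon (n=6) vertices of circumradius r in the z = z0 plane,
# optionally rotated/translated afterwards.
regular_hexagon <- function(r = 1, z0 = 0, phase = 0) {
  ang <- phase + seq(0, 2 * pi, length.out = 7)[1:6]
  cbind(r * cos(ang), r * sin(ang), z0)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Brute-force circle-fit oracle: dense grid search over (cx, cy, r)
# around a starting guess, returning the best summed squared radial
# residual found.
grid_circle_cost <- function(p2, span = 0.5, n_grid = 21) {
  cx0 <- mean(p2[, 1]); cy0 <- mean(p2[, 2])
  r0 <- mean(sqrt((p2[, 1] - cx0)^2 + (p2[, 2] - cy0)^2))
  best <- Inf
  for (cx in seq(cx0 - span, cx0 + span, length.out = n_grid))
    for (cy in seq(cy0 - span, cy0 + span, length.out = n_grid))
      for (r in seq(max(r0 - span, 1e-3), r0 + span, length.out = n_grid)) {
        cost <- sum((sqrt((p2[, 1] - cx)^2 + (p2[, 2] - cy)^2) - r)^2)
        if (cost < best) best <- cost
      }
  best
}

# Projected polygon area of 3D points for an arbitrary unit normal
# (independent re-derivation used as the hemispheric-grid oracle).
oracle_projected_area <- function(pts, n) {
  n <- n / sqrt(sum(n^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(ref[2] * n[3] - ref[3] * n[2],
          ref[3] * n[1] - ref[1] * n[3],
          ref[1] * n[2] - ref[2] * n[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  u <- pts %*% e1; v <- pts %*% e2
  ctr <- c(mean(u), mean(v))
  o <- order(atan2(v - ctr[2], u - ctr[1]))
  u <- u[o]; v <- v[o]
  i2 <- c(seq_along(u)[-1], 1)
  abs(sum(u * v[i2] - u[i2] * v)) / 2
}

# Hemispheric grid of unit normals at `by` degree resolution.
normal_grid <- function(by = 2) {
  g <- expand.grid(az = seq(-180, 180 - by, by = by),
                   el = seq(0, 90, by = by))
  cbind(cos(g$el * pi / 180) * cos(g$az * pi / 180),
        cos(g$el * pi / 180) * sin(g$az * pi / 180),
        sin(g$el * pi / 180))
}

# Quaternion composition oracle for z-y-x intrinsic Euler rotations.
quat_mul <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}

quat_axis <- function(axis, deg) {
  h <- deg * pi / 360
  c(cos(h), sin(h) * axis)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

quat_rotation_oracle <- function(yaw, pitch, roll) {
  # pitch uses the nose-up convention: rotation about -y by the standard
  # right-handed matrix equals rotation about +y with flipped sign
  q <- quat_mul(quat_axis(c(0, 0, 1), yaw),
                quat_mul(quat_axis(c(0, -1, 0), pitch),
                         quat_axis(c(1, 0, 0), roll)))
  quat_to_matrix(q)
}

# A small valid landmark tibble built around exact lens geometry.
make_lens_row <- function(id = 1L, center = c(0, 0, 0), axis = c(0, 0, 1),
                          a = 3, h = 1, section = "dorsal", phase = 0) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(ref[2] * axis[3] - ref[3] * axis[2],
          ref[3] * axis[1] - ref[1] * axis[3],
          ref[1] * axis[2] - ref[2] * axis[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  ang <- phase + seq(0, 2 * pi, length.out = 7)[1:6]
  row <- tibble::tibble(ommatidium_id = id, animal_id = "fix",
                        sex = "unknown", side = "right", section = section)
  for (k in 1:6) {
    p <- center + a * (cos(ang[k]) * e1 + sin(ang[k]) * e2)
    row[[paste0("p", k, "_x")]] <- p[1]
    row[[paste0("p", k, "_y")]] <- p[2]
    row[[paste0("p", k, "_z")]] <- p[3]
  }
  apex <- center + h * axis
  row$apex_x <- apex[1]; row$apex_y <- apex[2]; row$apex_z <- apex[3]
  row
}

# Unit direction(s) from azimuth/elevation in degrees (vectorized; rows).
azel_dir <- function(az, el) {
  az <- az * pi / 180; el <- el * pi / 180
  cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}
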