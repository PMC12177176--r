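# Small 3D vector helpers shared by the geometry, map and gaze modules.
# All take plain numeric vectors of length 3 (or n x 3 matrices where noted);
# angles are in degrees at the API surface, radians internally.

vec_norm <- function(v) sqrt(sum(v^2))

unit_vector <- function(v, what = "vector") {
  n <- vec_norm(v)
  if (!is.finite(n) || n < .Machine$double.eps * 100) {
    abort(sprintf("Cannot normalize a zero-length %s.", what),
          class = "splitgaze_degenerate_geometry")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angular difference between two direction vectors
#'
#' Returns the unsigned angle between two 3D direction vectors, the primitive
#' behind all interommatidial-angle and gaze-separation computations. Inputs
#' need not be unit length; they are normalized first.
#'
#' @param v1,v2 Numeric length-3 vectors (or n x 3 matrices for `v1` to
#'   compute many angles against a single `v2`).
#' @return Angle(s) in degrees, in \[0, 180\].
#' @examples
#' angular_difference(c(1, 0, 0), c(0, 1, 0)) # 90
#' @export
angular_difference <- function(v1, v2) {
  if (is.matrix(v1) && nrow(v1) == 1) v1 <- v1[1, ]
  if (is.matrix(v2)) v2 <- v2[1, ]
  if (is.matrix(v1)) {
    n1 <- sqrt(rowSums(v1^2))
    if (any(n1 < .Machine$double.eps * 100)) {
      abort("Zero-length vector in angular_difference().",
            class = "splitgaze_degenerate_geometry")
    }
    u2 <- unit_vector(v2)
    d <- as.vector(v1 %*% u2) / n1
    return(rad2deg(acos(pmin(1, pmax(-1, d)))))
  }
  u1 <- unit_vector(v1)
  u2 <- unit_vector(v2)
  rad2deg(acos(min(1, max(-1, sum(u1 * u2)))))
}

# Orthonormal in-plane basis (e1, e2) for a plane with unit normal `n`,
# right-handed so that cross(e1, e2) = n.
plane_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vector(cross3(ref, n))
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2)
}

# Area of the polygon formed by 2D points sorted by angle about their
# centroid (shoelace). Input: n x 2 matrix.
polygon_area <- function(pts2d) {
  ctr <- colMeans(pts2d)
  ang <- atan2(pts2d[, 2] - ctr[2], pts2d[, 1] - ctr[1])
  p <- pts2d[order(ang), , drop = FALSE]
  x <- p[, 1]; y <- p[, 2]
  i2 <- c(seq_len(nrow(p))[-1], 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

# Projected polygon area of 3D points onto the plane orthogonal to unit
# normal `n`.
projected_area <- function(pts3d, n) {
  b <- plane_basis(n)
  polygon_area(cbind(pts3d %*% b$e1, pts3d %*% b$e2))
}

# Spherical direction from azimuth/elevation in degrees. Azimuth from +x
# (anterior) toward +y (animal's left), elevation positive dorsal (+z).
azel_to_vec <- function(az, el) {
  az <- deg2rad(az); el <- deg2rad(el)
  cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

vec_to_azel <- function(v) {
  if (!is.matrix(v)) v <- matrix(v, ncol = 3)
  n <- sqrt(rowSums(v^2))
  list(azimuth = rad2deg(atan2(v[, 2], v[, 1])),
       elevation = rad2deg(asin(pmin(1, pmax(-1, v[, 3] / n)))))
}
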