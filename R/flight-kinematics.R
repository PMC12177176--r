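# Flight and head kinematics from high-speed 3D tracks: body pitch,
# forward velocity, spline time-normalization, speed-binned pitch
# statistics, body length, and tethered head roll/pitch wobble.

#' Body pitch angle from the head and thorax points
#'
#' The angle in [0, 180] degrees between the thorax-to-head vector and the
#' horizontal forward direction, measured in the vertical plane: 0 =
#' horizontal head-forward, 90 = vertical, > 90 = pitched past vertical
#' (head above and behind the thorax). Invariant to yaw: the forward
#' reference is rotated with the body.
#'
#' @param head_pt,thorax_pt Length-3 points (mm, lab frame, z up), or
#'   n x 3 matrices for per-frame series.
#' @param forward Horizontal forward direction used to orient the "past
#'   vertical" branch; length-3 (z ignored), default +x.
#' @return Pitch angle(s) in degrees, in [0, 180].
#' @examples
#' body_pitch(c(0, 0, 1), c(0, 0, 0)) # 90
#' @export
body_pitch <- function(head_pt, thorax_pt, forward = c(1, 0, 0)) {
  H <- if (is.matrix(head_pt)) head_pt else matrix(head_pt, ncol = 3)
  Tx <- if (is.matrix(thorax_pt)) thorax_pt else matrix(thorax_pt, ncol = 3)
  stopifnot(nrow(H) == nrow(Tx))
  v <- H - Tx
  nv <- sqrt(rowSums(v^2))
  if (any(nv < .Machine$double.eps * 100)) {
    abort("Coincident head and thorax points.",
          class = "splitgaze_degenerate_geometry")
  }
  f <- c(forward[1], forward[2], 0)
  f <- unit_vector(f, what = "forward direction (must have a horizontal part)")
  # in the vertical plane containing v: signed horizontal component along
  # the forward direction, vertical component up
  hmag <- sqrt(v[, 1]^2 + v[, 2]^2)
  hsign <- ifelse(as.vector(v[, 1:2, drop = FALSE] %*% f[1:2]) >= 0, 1, -1)
  ang <- rad2deg(atan2(v[, 3], hsign * hmag))
  # fold the lower half-plane onto [0, 180]: reported pitch is unsigned
  abs(ang)
}

#' Instantaneous forward velocity of a flight track
#'
#' Horizontal-plane speed of the tracked point by central differences at
#' interior frames and one-sided differences at the ends. Coordinates are
#' in mm, output in cm/s.
#'
#' @param track A `flight_track` tibble (see [read_flight_track()]).
#' @param point `"head"` (default) or `"midpoint"` (head-thorax midpoint).
#' @param horizontal If TRUE (default) use only x/y motion ("horizontal
#'   forward speed"); if FALSE, the full 3D speed.
#' @return Numeric vector of speeds in cm/s, one per frame.
#' @export
forward_velocity <- function(track, point = c("head", "midpoint"),
                             horizontal = TRUE) {
  point <- match.arg(point)
  if (nrow(track) < 3) {
    abort("Need >= 3 frames for velocity estimation.",
          class = "splitgaze_schema_error")
  }
  if (length(unique(round(diff(track$t), 12))) > 1) {
    abort("Non-uniform timestamps; resample the track first.",
          class = "splitgaze_schema_error")
  }
  P <- as.matrix(track[paste0("head_", c("x", "y", "z"))])
  if (point == "midpoint") {
    P <- (P + as.matrix(track[paste0("thorax_", c("x", "y", "z"))])) / 2
  }
  if (horizontal) P[, 3] <- 0
  dt <- track$t[2] - track$t[1]
  n <- nrow(P)
  V <- matrix(0, n, 3)
  V[2:(n - 1), ] <- (P[3:n, ] - P[1:(n - 2), ]) / (2 * dt)
  V[1, ] <- (P[2, ] - P[1, ]) / dt
  V[n, ] <- (P[n, ] - P[n - 1, ]) / dt
  sqrt(rowSums(V^2)) / 10  # mm/s -> cm/s
}

#' Spline time-normalization of a series
#'
#' Resamples a series onto `n_out` points over normalized time [0, 1] with
#' a natural cubic spline, so that flights of different duration can be
#' averaged sample-by-sample. Endpoints are preserved exactly.
#'
#' @param series Numeric vector, length >= 4.
#' @param n_out Number of output samples (>= 2).
#' @return Numeric vector of length `n_out`.
#' @export
normalize_time <- function(series, n_out = 100) {
  if (length(series) < 4) {
    abort("Need >= 4 samples for cubic-spline normalization.",
          class = "splitgaze_schema_error")
  }
  if (n_out < 2) abort("n_out must be >= 2.", class = "splitgaze_schema_error")
  x <- seq(0, 1, length.out = length(series))
  stats::spline(x, series, xout = seq(0, 1, length.out = n_out),
                method = "natural")$y
}

#' Bin body pitch by forward speed
#'
#' Groups frames into contiguous speed bins and reports per-bin mean, SD
#' and count of the pitch angle. Bins with a single observation report
#' `NA` SD (not 0); empty bins are absent from the output.
#'
#' @param speeds Speeds in cm/s.
#' @param pitches Pitch angles in degrees, same length.
#' @param bin_width Bin width in cm/s (default 2.0).
#' @return A tibble: `bin_center`, `speed_mean` (mean speed of the frames
#'   in the bin), `pitch_mean`, `pitch_sd`, `n`.
#' @export
bin_pitch_by_speed <- function(speeds, pitches, bin_width = 2.0) {
  if (length(speeds) != length(pitches)) {
    abort("speeds and pitches must have equal length.",
          class = "splitgaze_schema_error")
  }
  if (bin_width <= 0) {
    abort("bin_width must be > 0.", class = "splitgaze_schema_error")
  }
  idx <- floor(speeds / bin_width)
  tibble(idx = idx, speed = speeds, pitch = pitches) %>%
    group_by(.data$idx) %>%
    summarise(speed_mean = mean(.data$speed),
              pitch_mean = mean(.data$pitch),
              pitch_sd = if (dplyr::n() > 1) sd(.data$pitch) else NA_real_,
              n = dplyr::n(), .groups = "drop") %>%
    mutate(bin_center = (.data$idx + 0.5) * bin_width) %>%
    select("bin_center", "speed_mean", "pitch_mean", "pitch_sd", "n") %>%
    arrange(.data$bin_center)
}

#' Body length from head and abdomen-tip points
#'
#' @param head_pt,abdomen_tip_pt Length-3 points (mm) or n x 3 matrices.
#' @return Euclidean distance(s) in mm.
#' @export
body_length <- function(head_pt, abdomen_tip_pt) {
  H <- if (is.matrix(head_pt)) head_pt else matrix(head_pt, ncol = 3)
  A <- if (is.matrix(abdomen_tip_pt)) abdomen_tip_pt else
    matrix(abdomen_tip_pt, ncol = 3)
  L <- sqrt(rowSums((H - A)^2))
  if (any(L <= 0)) {
    abort("Zero body length.", class = "splitgaze_degenerate_geometry")
  }
  L
}

#' Convert speed to body lengths per second
#'
#' @param speed Speed in cm/s.
#' @param body_length_mm Body length in mm, > 0.
#' @return Speed in body lengths per second.
#' @examples
#' speed_in_body_lengths(53, 0.92) # ~576
#' @export
speed_in_body_lengths <- function(speed, body_length_mm) {
  if (any(body_length_mm <= 0)) {
    abort("body_length_mm must be > 0.", class = "splitgaze_schema_error")
  }
  speed * 10 / body_length_mm
}

#' Head angle series from a two-marker track
#'
#' Angle of the line connecting the two markers against the horizontal
#' image axis, per frame, reported as the deviation from its series mean —
#' head roll in the frontal view, head pitch in the side view. Frames with
#' coincident markers are flagged and excluded from the statistics.
#'
#' @param track A `head_marker_track` (see [read_head_markers()]).
#' @return A tibble with `frame`, `t`, `angle`, `delta` (degrees) and
#'   `flagged`; attributes `mean_abs_change` (mean |frame-to-frame
#'   change|), `peak_to_peak` (max - min of `delta`) and `amplitude_p2p`
#'   (`2 * sqrt(2) * sd(delta)`: the peak-to-peak of the best-fitting
#'   sinusoid, robust to per-frame tracking noise).
#' @export
head_angle <- function(track) {
  dx <- track$bx - track$ax
  dy <- track$by - track$ay
  flagged <- sqrt(dx^2 + dy^2) < .Machine$double.eps * 100
  ang <- rad2deg(atan2(dy, dx))
  ang[flagged] <- NA_real_
  delta <- ang - mean(ang, na.rm = TRUE)
  out <- tibble(frame = track$frame, t = track$t, angle = ang,
                delta = delta, flagged = flagged)
  attr(out, "mean_abs_change") <-
    mean(abs(diff(ang[!flagged])), na.rm = TRUE)
  attr(out, "peak_to_peak") <-
    max(delta, na.rm = TRUE) - min(delta, na.rm = TRUE)
  attr(out, "amplitude_p2p") <- 2 * sqrt(2) * sd(delta[!flagged])
  attr(out, "view") <- attr(track, "view")
  out
}

#' Per-frame flight kinematics
#'
#' Convenience wrapper deriving speed and body pitch for every frame of a
#' track, with the forward reference for the pitch branch taken from the
#' horizontal displacement over the whole flight.
#'
#' @param track A `flight_track` tibble.
#' @param point Tracked point for the speed (see [forward_velocity()]).
#' @param horizontal Horizontal-plane speed (default) or 3D speed.
#' @return The track tibble plus `speed` (cm/s) and `pitch` (degrees).
#' @export
flight_kinematics <- function(track, point = c("head", "midpoint"),
                              horizontal = TRUE) {
  point <- match.arg(point)
  H <- as.matrix(track[paste0("head_", c("x", "y", "z"))])
  Tx <- as.matrix(track[paste0("thorax_", c("x", "y", "z"))])
  disp <- colMeans(H[max(1, nrow(H) - 4):nrow(H), , drop = FALSE]) -
    colMeans(H[1:min(5, nrow(H)), , drop = FALSE])
  fwd <- if (vec_norm(disp[1:2]) > 1e-9) c(disp[1:2], 0) else c(1, 0, 0)
  out <- as_tibble(track)
  out$speed <- forward_velocity(track, point = point, horizontal = horizontal)
  out$pitch <- body_pitch(H, Tx, forward = fwd)
  attr(out, "frame_rate") <- attr(track, "frame_rate")
  out
}
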