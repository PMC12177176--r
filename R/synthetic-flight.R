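# Seeded generators for free-flight trajectories (speed profile + linear
# pitch-versus-speed model) and tethered head-wobble marker tracks.

#' Specification of a synthetic flight bout
#'
#' The pitch model is linear in forward speed, beta = b0 + b1 * v, with
#' defaults through the two anchor states of free whitefly flight: stable
#' forward flight (27.5 cm/s at 48.1 deg) and the landing approach
#' (17.8 cm/s at 113 deg), giving slope -6.691 deg per cm/s. The speed
#' profile rises smoothly from the take-off speed to a peak and decays
#' toward the landing speed.
#'
#' @param duration_frames Number of video frames (>= 4, default 400).
#' @param fps Frame rate (default 7000).
#' @param v_peak Peak forward speed, cm/s (default 27.5).
#' @param v_land Speed approached at landing, cm/s (default 17.8).
#' @param v_start Speed just after take-off, cm/s (default 14). Kept well
#'   above hovering so that the linear pitch model stays inside the
#'   physical 0-150 degree range over the whole profile.
#' @param t_peak Normalized time of the speed peak (default 0.25).
#' @param pitch_intercept,pitch_slope Linear pitch model coefficients
#'   (degrees; degrees per cm/s). Defaults are derived from the two anchor
#'   states above.
#' @param pitch_jitter_sd SD of the smooth Gaussian jitter added to the
#'   pitch series, degrees (default 3). The jitter is band-limited (a
#'   natural spline through coarse Gaussian knots, ~20 per bout) so that
#'   the body axis moves at physically plausible angular rates.
#' @param tracking_noise_sd SD of Gaussian noise on tracked points, mm
#'   (default 0).
#' @param body_length_mm Body length, mm (default 0.92).
#' @param seed Default seed used by [generate_flight()].
#' @return A list of class `synthetic_flight_spec`.
#' @export
synthetic_flight_spec <- function(duration_frames = 400, fps = 7000,
                                  v_peak = 27.5, v_land = 17.8,
                                  v_start = 14, t_peak = 0.25,
                                  pitch_slope = (48.1 - 113) / (27.5 - 17.8),
                                  pitch_intercept = 113 - pitch_slope * 17.8,
                                  pitch_jitter_sd = 3,
                                  tracking_noise_sd = 0,
                                  body_length_mm = 0.92,
                                  seed = 1L) {
  stopifnot(duration_frames >= 4, fps > 0, v_peak > 0, v_land >= 0,
            v_start >= 0, t_peak > 0, t_peak < 1, pitch_jitter_sd >= 0,
            tracking_noise_sd >= 0, body_length_mm > 0)
  structure(as.list(environment()), class = "synthetic_flight_spec")
}

# Smooth take-off -> peak -> landing speed profile on normalized time:
# a smoothstep from the take-off speed to the landing speed carrying a
# gamma-shaped acceleration bump that peaks at t_peak.
flight_speed_profile <- function(tau, v_peak, v_land, t_peak,
                                 v_start = 14) {
  base <- v_start + (v_land - v_start) * (3 * tau^2 - 2 * tau^3)
  bump <- (tau / t_peak)^2 * exp(2 * (1 - tau / t_peak))
  base + (v_peak - max(base)) * bump
}

#' Generate a synthetic flight track with known ground truth
#'
#' Builds the body-axis midpoint path by integrating the horizontal speed
#' profile, sets body pitch from the linear pitch-versus-speed model plus
#' Gaussian jitter, and places head, thorax and abdomen-tip points along
#' the pitched body axis. Pure function of `(spec, seed)`.
#'
#' @param spec A [synthetic_flight_spec()].
#' @param seed Integer seed (default `spec$seed`).
#' @return A list: `track` (a `flight_track` tibble with head, thorax and
#'   abdomen-tip points in mm) and `truth` (tibble of true per-frame
#'   `speed` (cm/s) and `pitch` (deg), plus the model parameters as
#'   attributes `pitch_intercept`, `pitch_slope`, `body_length_mm`).
#' @export
generate_flight <- function(spec = synthetic_flight_spec(),
                            seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_flight_spec"))
  withr::with_seed(as.integer(seed), generate_flight_impl(spec))
}

generate_flight_impl <- function(spec) {
  n <- spec$duration_frames
  dt <- 1 / spec$fps
  tau <- seq(0, 1, length.out = n)
  v <- flight_speed_profile(tau, spec$v_peak, spec$v_land, spec$t_peak,
                            spec$v_start)
  beta <- spec$pitch_intercept + spec$pitch_slope * v +
    smooth_jitter(n, spec$pitch_jitter_sd)
  beta <- pmin(pmax(beta, 0), 180)

  # midpoint path: horizontal, along +x; v in cm/s -> mm per frame
  x <- cumsum(c(0, (v[-1] + v[-n]) / 2 * 10 * dt))
  mid <- cbind(x, 0, 5)  # 5 mm above the chamber floor

  dir <- cbind(cos(deg2rad(beta)), 0, sin(deg2rad(beta)))
  L <- spec$body_length_mm
  head_pt <- mid + 0.5 * L * dir
  thorax_pt <- mid - 0.1 * L * dir   # thorax-abdomen transition
  abd_pt <- head_pt - L * dir        # abdomen tip: body length from head

  if (spec$tracking_noise_sd > 0) {
    head_pt <- head_pt + matrix(rnorm(3 * n, 0, spec$tracking_noise_sd), n, 3)
    thorax_pt <- thorax_pt + matrix(rnorm(3 * n, 0, spec$tracking_noise_sd), n, 3)
    abd_pt <- abd_pt + matrix(rnorm(3 * n, 0, spec$tracking_noise_sd), n, 3)
  }

  track <- tibble(
    frame = seq_len(n),
    head_x = head_pt[, 1], head_y = head_pt[, 2], head_z = head_pt[, 3],
    thorax_x = thorax_pt[, 1], thorax_y = thorax_pt[, 2],
    thorax_z = thorax_pt[, 3],
    abd_x = abd_pt[, 1], abd_y = abd_pt[, 2], abd_z = abd_pt[, 3])
  track <- as_flight_track(track, spec$fps)

  truth <- tibble(frame = seq_len(n), speed = v, pitch = beta)
  attr(truth, "pitch_intercept") <- spec$pitch_intercept
  attr(truth, "pitch_slope") <- spec$pitch_slope
  attr(truth, "body_length_mm") <- spec$body_length_mm
  list(track = track, truth = truth)
}

# Band-limited Gaussian jitter: natural spline through ~20 Gaussian
# knots over the bout, so angular rates stay physical at high frame rates.
smooth_jitter <- function(n, sd, knots = 20) {
  if (sd <= 0) return(numeric(n))
  k <- max(4, min(knots, n))
  y <- rnorm(k, 0, sd)
  stats::spline(seq(0, 1, length.out = k), y,
                xout = seq(0, 1, length.out = n), method = "natural")$y
}

#' Generate a tethered head-wobble marker track
#'
#' Two markers rotating about their fixed midpoint with a sinusoidal angle
#' of the requested amplitude (peak-to-peak twice the amplitude), plus
#' Gaussian position noise — the geometry scored in tethered head-roll /
#' head-pitch videography.
#'
#' @param amplitude Sinusoid amplitude in degrees (default 0.5, i.e. 1.0
#'   degree peak-to-peak).
#' @param frequency_hz Wobble frequency (default 150, of the order of the
#'   wingbeat the head jitter is synchronized with).
#' @param frames Number of frames (default 700).
#' @param fps Frame rate (default 7000).
#' @param marker_sep Marker separation in mm (default 0.5).
#' @param noise_sd Gaussian position noise SD on each marker coordinate,
#'   mm (default 0).
#' @param view `"frontal"` (roll) or `"side"` (pitch).
#' @param seed Integer seed.
#' @return A list: `track` (a `head_marker_track`) and `truth` (list with
#'   `amplitude`, `peak_to_peak`, the true `angle` series in degrees).
#' @export
generate_head_wobble <- function(amplitude = 0.5, frequency_hz = 150,
                                 frames = 700, fps = 7000,
                                 marker_sep = 0.5, noise_sd = 0,
                                 view = c("frontal", "side"), seed = 1L) {
  view <- match.arg(view)
  stopifnot(amplitude >= 0, frequency_hz > 0, frames >= 2, fps > 0,
            marker_sep > 0, noise_sd >= 0)
  withr::with_seed(as.integer(seed), {
    t_s <- (seq_len(frames) - 1) / fps
    ang <- amplitude * sin(2 * pi * frequency_hz * t_s)
    half <- marker_sep / 2
    ca <- cos(deg2rad(ang)); sa <- sin(deg2rad(ang))
    df <- tibble(frame = seq_len(frames),
                 ax = -half * ca, ay = -half * sa,
                 bx = half * ca, by = half * sa)
    if (noise_sd > 0) {
      df[c("ax", "ay", "bx", "by")] <- df[c("ax", "ay", "bx", "by")] +
        matrix(rnorm(4 * frames, 0, noise_sd), frames, 4)
    }
    track <- as_head_marker_track(df, fps, view)
    list(track = track,
         truth = list(amplitude = amplitude, peak_to_peak = 2 * amplitude,
                      angle = ang))
  })
}
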