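# End-to-end orchestration: landmarks -> geometry -> map -> optics ->
# gaze sweeps, and tracks -> kinematics, with persisted stage tables and
# a summary report of the comparative statistics.

#' Run the full eye-reconstruction pipeline
#'
#' Composes the reconstruction stages on one landmark table: per-lens
#' geometry, single-surface optics, the ommatidial map with
#' interommatidial angles, per-section summaries, the dorsal-ventral mean
#' gaze separation, the comparative percentage statistics, and (optionally)
#' gaze sweeps about all three body axes. Deterministic for fixed inputs.
#'
#' @param lenses Lens-landmark tibble (see [read_landmarks()]).
#' @param head Optional [head_frame()]; required when `normalize = TRUE`.
#' @param normalize Normalize coordinates to head width before
#'   reconstruction (dimensionless output lengths; default FALSE, which
#'   keeps micrometres).
#' @param optics An [optics_config()].
#' @param k,pool_sections,cutoff Neighbour-graph options, see [eye_map()].
#' @param sweeps Character vector of rotation axes to sweep (subset of
#'   yaw/pitch/roll; default all three; `character()` to skip).
#' @param sweep_step Sweep step in degrees (default 1).
#' @param sphere_radius Virtual-sphere radius in mm (default 10).
#' @return An object of class `eye_report`: a list with `geometry`, `map`,
#'   `sections`, `separation`, `ratios`, `sweeps`, and the configuration.
#' @export
run_eye_pipeline <- function(lenses, head = NULL, normalize = FALSE,
                             optics = optics_config(), k = 6,
                             pool_sections = TRUE, cutoff = 45,
                             sweeps = c("pitch", "yaw", "roll"),
                             sweep_step = 1, sphere_radius = 10) {
  if (nrow(lenses) == 0) {
    abort("No lens landmarks to reconstruct.", class = "splitgaze_io_error")
  }
  lenses <- validate_landmarks(lenses)
  if (normalize) {
    if (is.null(head)) {
      abort("normalize = TRUE needs a head_frame.",
            class = "splitgaze_schema_error")
    }
    lenses <- normalize_to_head_width(lenses, head)
  }
  geometry <- lens_geometry(lenses)
  geometry <- add_lens_optics(geometry, optics)
  map <- eye_map(geometry, k = k, pool_sections = pool_sections,
                 cutoff = cutoff)
  sections <- section_summary(map)
  sections <- map %>%
    group_by(.data$section) %>%
    summarise(area_mean = mean(.data$aperture_area),
              area_sd = sd(.data$aperture_area),
              curvature_mean = mean(.data$curvature_radius),
              curvature_sd = sd(.data$curvature_radius),
              focal_mean = mean(.data$focal_length),
              focal_sd = sd(.data$focal_length),
              focal_depth_mean = mean(.data$focal_depth_fraction),
              .groups = "drop") %>%
    left_join(sections, ., by = "section")

  separation <- tryCatch(section_gaze_separation(map),
                         error = function(e) NA_real_)

  ratios <- NULL
  if (all(c("dorsal", "ventral") %in% sections$section)) {
    d <- sections[sections$section == "dorsal", ]
    v <- sections[sections$section == "ventral", ]
    ratios <- tibble(
      quantity = c("diameter", "aperture_area", "curvature_radius",
                   "focal_length", "interommatidial_angle"),
      dorsal = c(d$diameter_mean, d$area_mean, d$curvature_mean,
                 d$focal_mean, d$interommatidial_mean),
      ventral = c(v$diameter_mean, v$area_mean, v$curvature_mean,
                  v$focal_mean, v$interommatidial_mean)) %>%
      mutate(percent_difference =
               relative_difference(.data$dorsal, .data$ventral))
  }

  sweep_tbl <- NULL
  if (length(sweeps) > 0) {
    coord_scale <- if (normalize) 1e-3 * (if (is.null(head)) 126 else
      head$head_width) else 1e-3
    sweep_tbl <- bind_rows(lapply(sweeps, function(ax) {
      gaze_sweep(map, axis = ax, step = sweep_step,
                 coord_scale = coord_scale,
                 sphere = NULL)
    }))
  }

  structure(list(geometry = geometry, map = map, sections = sections,
                 separation = separation, ratios = ratios,
                 sweeps = sweep_tbl,
                 config = list(normalize = normalize, optics = optics,
                               k = k, pool_sections = pool_sections,
                               cutoff = cutoff, sweep_step = sweep_step,
                               sphere_radius = sphere_radius)),
            class = "eye_report")
}

#' Run the flight-kinematics pipeline
#'
#' Derives per-frame speed and body pitch, the speed-binned pitch curve,
#' a linear fit of binned pitch on speed, spline time-normalized series,
#' and a flight summary.
#'
#' @param track A `flight_track` tibble (see [read_flight_track()]).
#' @param bin_width Speed bin width in cm/s (default 2).
#' @param n_norm Samples for spline time-normalization (default 100).
#' @param point,horizontal Passed to [forward_velocity()].
#' @return An object of class `flight_report`: `frames` (per-frame
#'   kinematics), `binned`, `fit` (lm of binned pitch means on bin
#'   centres), `normalized` (tibble with normalized time, speed, pitch),
#'   `summary` (one-row tibble).
#' @export
run_flight_pipeline <- function(track, bin_width = 2, n_norm = 100,
                                point = "head", horizontal = TRUE) {
  frames <- flight_kinematics(track, point = point, horizontal = horizontal)
  binned <- bin_pitch_by_speed(frames$speed, frames$pitch,
                               bin_width = bin_width)
  fit <- if (nrow(binned) >= 3) {
    lm(pitch_mean ~ speed_mean, data = binned)
  } else NULL
  normalized <- tibble(
    tau = seq(0, 1, length.out = n_norm),
    speed = normalize_time(frames$speed, n_norm),
    pitch = normalize_time(frames$pitch, n_norm))
  n <- nrow(frames)
  w <- max(1, round(0.1 * n))
  bl <- if (all(paste0("abd_", c("x", "y", "z")) %in% names(frames))) {
    mean(body_length(as.matrix(frames[paste0("head_", c("x", "y", "z"))]),
                     as.matrix(frames[paste0("abd_", c("x", "y", "z"))])))
  } else NA_real_
  summary <- tibble(
    n_frames = n,
    duration_s = frames$t[n] - frames$t[1],
    speed_mean = mean(frames$speed),
    speed_max = max(frames$speed),
    pitch_start = mean(frames$pitch[1:w]),
    pitch_end = mean(frames$pitch[(n - w + 1):n]),
    slope = if (is.null(fit)) NA_real_ else unname(coef(fit)[2]),
    body_length_mm = bl,
    max_speed_body_lengths =
      if (is.na(bl)) NA_real_ else speed_in_body_lengths(max(frames$speed), bl))
  structure(list(frames = frames, binned = binned, fit = fit,
                 normalized = normalized, summary = summary,
                 config = list(bin_width = bin_width, n_norm = n_norm,
                               point = point, horizontal = horizontal)),
            class = "flight_report")
}

#' @export
print.eye_report <- function(x, ...) {
  cat("<eye_report>\n")
  cat(sprintf("  %d ommatidia (%s)\n", nrow(x$map),
              paste(sprintf("%s: %d", x$sections$section, x$sections$n),
                    collapse = ", ")))
  cat(sprintf("  section mean-gaze separation: %.1f deg\n", x$separation))
  if (!is.null(x$ratios)) {
    for (i in seq_len(nrow(x$ratios))) {
      cat(sprintf("  %s: dorsal %.3g / ventral %.3g (%.1f%% difference)\n",
                  x$ratios$quantity[i], x$ratios$dorsal[i],
                  x$ratios$ventral[i], x$ratios$percent_difference[i]))
    }
  }
  invisible(x)
}

#' @export
print.flight_report <- function(x, ...) {
  s <- x$summary
  cat("<flight_report>\n")
  cat(sprintf("  %d frames, %.1f ms\n", s$n_frames, 1000 * s$duration_s))
  cat(sprintf("  speed: mean %.1f, max %.1f cm/s\n", s$speed_mean,
              s$speed_max))
  cat(sprintf("  pitch: start %.1f deg -> end %.1f deg (slope %.2f deg per cm/s)\n",
              s$pitch_start, s$pitch_end, s$slope))
  invisible(x)
}

#' Write an eye report's stage tables to a directory
#'
#' Persists `geometry.csv`, `map.csv` (neighbour ids collapsed to a
#' semicolon-separated string), `sections.csv`, `ratios.csv`,
#' `sweeps.csv` and `summary.json`.
#'
#' @param report An `eye_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_eye_report <- function(report, dir) {
  stopifnot(inherits(report, "eye_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$geometry, file.path(dir, "geometry.csv"),
            row.names = FALSE)
  map_flat <- report$map
  map_flat$neighbor_ids <- vapply(map_flat$neighbor_ids,
                                  function(v) paste(v, collapse = ";"), "")
  write.csv(map_flat, file.path(dir, "map.csv"), row.names = FALSE)
  write.csv(report$sections, file.path(dir, "sections.csv"),
            row.names = FALSE)
  if (!is.null(report$ratios)) {
    write.csv(report$ratios, file.path(dir, "ratios.csv"), row.names = FALSE)
  }
  if (!is.null(report$sweeps)) {
    write.csv(report$sweeps, file.path(dir, "sweeps.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(sections = report$sections, separation = report$separation,
         ratios = report$ratios),
    file.path(dir, "summary.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname tidy.eye_report
#' @method glance eye_report
#' @export
glance.eye_report <- function(x, ...) {
  out <- tibble(n_ommatidia = nrow(x$map), separation = x$separation)
  for (s in x$sections$section) {
    r <- x$sections[x$sections$section == s, ]
    out[[paste0("n_", s)]] <- r$n
    out[[paste0("diameter_", s)]] <- r$diameter_mean
    out[[paste0("interommatidial_", s)]] <- r$interommatidial_mean
    out[[paste0("focal_", s)]] <- r$focal_mean
  }
  out
}

#' Tidy methods for pipeline reports
#'
#' `tidy()` on an `eye_report` returns the per-ommatidium map table;
#' `glance()` a one-row summary (counts, section means, gaze separation).
#' On a `flight_report`, `tidy()` returns the per-frame kinematics and
#' `glance()` the one-row flight summary.
#'
#' @param x An `eye_report` or `flight_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy eye_report
#' @export
tidy.eye_report <- function(x, ...) {
  out <- x$map
  out$neighbor_ids <- NULL
  out
}

#' @rdname tidy.eye_report
#' @method tidy flight_report
#' @export
tidy.flight_report <- function(x, ...) {
  as_tibble(x$frames)[, c("frame", "t", "speed", "pitch")]
}

#' @rdname tidy.eye_report
#' @method glance flight_report
#' @export
glance.flight_report <- function(x, ...) {
  x$summary
}
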