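# Data model and CSV/JSON readers/writers for digitized eye landmarks,
# head reference landmarks, and tracked flight points.
#
# Landmark table schema (one row per ommatidium, micrometres, head frame;
# right-handed axes: x anterior, y toward the animal's left, z dorsal):
#   ommatidium_id (integer), animal_id (character), sex (male/female/unknown),
#   side (left/right), section (dorsal/ventral),
#   p1_x p1_y p1_z ... p6_x p6_y p6_z  -- six lens-base points
#   apex_x apex_y apex_z               -- the lens-top point
#
# Flight-track CSV (millimetres, lab frame, z vertical-up):
#   frame, head_x, head_y, head_z, thorax_x, thorax_y, thorax_z
#   [, abd_x, abd_y, abd_z]

landmark_coord_cols <- function() {
  c(t(outer(paste0("p", 1:6), c("x", "y", "z"),
            function(a, b) paste(a, b, sep = "_"))),
    paste0("apex_", c("x", "y", "z")))
}

landmark_cols <- function() {
  c("ommatidium_id", "animal_id", "sex", "side", "section",
    landmark_coord_cols())
}

#' Head reference frame from the two ocelli
#'
#' The distance between the two ocelli defines the head width used to
#' normalize eye coordinates across individuals.
#'
#' @param ocellus_left,ocellus_right Numeric length-3 points (micrometres,
#'   head frame).
#' @return An object of class `head_frame`: a list with the two ocellus
#'   positions and the derived `head_width`.
#' @examples
#' head_frame(c(0, 63, 0), c(0, -63, 0))$head_width # 126
#' @export
head_frame <- function(ocellus_left, ocellus_right) {
  stopifnot(length(ocellus_left) == 3, length(ocellus_right) == 3)
  if (!all(is.finite(c(ocellus_left, ocellus_right)))) {
    abort("Ocellus coordinates must be finite.", class = "splitgaze_schema_error")
  }
  w <- vec_norm(ocellus_left - ocellus_right)
  if (w <= 0) {
    abort("head_width must be > 0 (coincident ocelli).",
          class = "splitgaze_schema_error")
  }
  structure(list(ocellus_left = as.numeric(ocellus_left),
                 ocellus_right = as.numeric(ocellus_right),
                 head_width = w),
            class = "head_frame")
}

#' @export
print.head_frame <- function(x, ...) {
  cat(sprintf("<head_frame> head_width = %.4g um\n", x$head_width))
  invisible(x)
}

#' Validate a lens-landmark table
#'
#' Checks the documented schema: all columns present, coordinates finite,
#' six distinct base points per row, apex distinct from the base-point
#' centroid, and known factor levels. Errors name the offending row /
#' ommatidium id.
#'
#' @param lenses A data frame of lens landmarks (see the schema in
#'   [read_landmarks()]).
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
validate_landmarks <- function(lenses) {
  lenses <- as_tibble(lenses)
  missing_cols <- setdiff(landmark_cols(), names(lenses))
  if (length(missing_cols) > 0) {
    abort(paste0("Landmark table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "splitgaze_schema_error")
  }
  bad_sex <- !lenses$sex %in% c("male", "female", "unknown")
  if (any(bad_sex)) {
    abort(sprintf("Row %d: sex must be male/female/unknown (got '%s').",
                  which(bad_sex)[1], lenses$sex[which(bad_sex)[1]]),
          class = "splitgaze_schema_error")
  }
  bad_side <- !lenses$side %in% c("left", "right")
  if (any(bad_side)) {
    abort(sprintf("Row %d: side must be left/right.", which(bad_side)[1]),
          class = "splitgaze_schema_error")
  }
  bad_sec <- !lenses$section %in% c("dorsal", "ventral")
  if (any(bad_sec)) {
    abort(sprintf("Row %d: section must be dorsal/ventral.", which(bad_sec)[1]),
          class = "splitgaze_schema_error")
  }
  coords <- as.matrix(lenses[landmark_coord_cols()])
  if (!is.numeric(coords)) {
    abort("All landmark coordinates must be numeric.",
          class = "splitgaze_schema_error")
  }
  nf <- which(!is.finite(coords), arr.ind = TRUE)
  if (nrow(nf) > 0) {
    abort(sprintf(
      "Row %d (ommatidium_id %s): non-finite coordinate in column '%s'.",
      nf[1, 1], lenses$ommatidium_id[nf[1, 1]],
      landmark_coord_cols()[nf[1, 2]]), class = "splitgaze_schema_error")
  }
  for (i in seq_len(nrow(lenses))) {
    bp <- base_point_matrix(lenses[i, ])
    if (nrow(unique(as.data.frame(bp))) < 6) {
      abort(sprintf(
        "Ommatidium_id %s: expected six distinct base points.",
        lenses$ommatidium_id[i]), class = "splitgaze_schema_error")
    }
    apex <- apex_point(lenses[i, ])
    if (vec_norm(apex - colMeans(bp)) < 1e-12) {
      abort(sprintf(
        "Ommatidium_id %s: apex coincides with the base-point centroid.",
        lenses$ommatidium_id[i]), class = "splitgaze_schema_error")
    }
  }
  lenses
}

# Row helpers: 6 x 3 base-point matrix and apex point of one landmark row.
base_point_matrix <- function(row) {
  m <- matrix(as.numeric(row[1, landmark_coord_cols()[1:18]]),
              nrow = 6, ncol = 3, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  m
}

apex_point <- function(row) {
  as.numeric(row[1, paste0("apex_", c("x", "y", "z"))])
}

#' Read digitized lens landmarks
#'
#' Reads a lens-landmark table plus (for JSON) the head reference frame.
#' The CSV format holds one lens per row under the documented header; the
#' JSON format wraps the same rows in a `lenses` field next to a `head`
#' field with the two ocellus positions.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return A list with `lenses` (validated tibble) and `head` (a
#'   [head_frame()], `NULL` for CSV input unless supplied separately).
#' @seealso [write_landmarks()], [read_head_frame()]
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "splitgaze_io_error")
  }
  if (format == "csv") {
    raw <- read.csv(path, stringsAsFactors = FALSE)
    lenses <- if (nrow(raw) == 0) {
      empty_landmark_table(names(raw))
    } else {
      validate_landmarks(raw)
    }
    return(list(lenses = lenses, head = NULL))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lenses <- if (is.null(obj$lenses) || NROW(obj$lenses) == 0) {
    empty_landmark_table(landmark_cols())
  } else {
    validate_landmarks(as_tibble(obj$lenses))
  }
  head_fr <- NULL
  if (!is.null(obj$head)) {
    head_fr <- head_frame(unlist(obj$head$ocellus_left),
                          unlist(obj$head$ocellus_right))
  }
  list(lenses = lenses, head = head_fr)
}

empty_landmark_table <- function(nms) {
  missing_cols <- setdiff(landmark_cols(), nms)
  if (length(missing_cols) > 0) {
    abort(paste0("Landmark table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "splitgaze_schema_error")
  }
  tb <- tibble(ommatidium_id = integer(), animal_id = character(),
               sex = character(), side = character(), section = character())
  for (cc in landmark_coord_cols()) tb[[cc]] <- numeric()
  tb
}

#' Write lens landmarks to CSV or JSON
#'
#' @param lenses Validated lens-landmark tibble.
#' @param path Output path; `.json` selects the JSON representation.
#' @param head Optional [head_frame()]; stored only in the JSON format.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lenses, path, head = NULL) {
  lenses <- validate_landmarks(lenses)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(lenses = lenses)
    if (!is.null(head)) {
      obj$head <- list(ocellus_left = head$ocellus_left,
                       ocellus_right = head$ocellus_right)
    }
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  } else {
    write.csv(lenses, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read head reference landmarks (ocelli) from CSV
#'
#' Expects columns `landmark` (values `ocellus_left`, `ocellus_right`),
#' `x`, `y`, `z` in micrometres.
#'
#' @param path CSV path.
#' @return A [head_frame()].
#' @export
read_head_frame <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("landmark", "x", "y", "z")
  if (!all(need %in% names(raw))) {
    abort("Head-frame CSV needs columns landmark, x, y, z.",
          class = "splitgaze_schema_error")
  }
  get_pt <- function(nm) {
    r <- raw[raw$landmark == nm, , drop = FALSE]
    if (nrow(r) != 1) {
      abort(sprintf("Head-frame CSV needs exactly one '%s' row.", nm),
            class = "splitgaze_schema_error")
    }
    as.numeric(r[1, c("x", "y", "z")])
  }
  head_frame(get_pt("ocellus_left"), get_pt("ocellus_right"))
}

#' Read a 3D flight track
#'
#' Reads per-frame head and thorax positions (mm, lab frame, z up) from CSV
#' and attaches a uniform time base at the stated frame rate. The abdomen
#' tip columns are optional; body-length-dependent quantities are then
#' unavailable.
#'
#' @param path CSV with columns `frame`, `head_x..z`, `thorax_x..z`
#'   and optionally `abd_x..z`.
#' @param frame_rate Recording rate in frames per second.
#' @return A tibble of class `flight_track` with a `t` column in seconds
#'   and attribute `frame_rate`.
#' @export
read_flight_track <- function(path, frame_rate) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "splitgaze_io_error")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE)
  as_flight_track(raw, frame_rate)
}

#' Coerce a data frame to a flight track
#'
#' @param df Data frame with the flight-track columns (see
#'   [read_flight_track()]).
#' @param frame_rate Frames per second; must be > 0.
#' @return A `flight_track` tibble.
#' @export
as_flight_track <- function(df, frame_rate) {
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    abort("frame_rate must be a positive number.",
          class = "splitgaze_schema_error")
  }
  need <- c("frame", paste0("head_", c("x", "y", "z")),
            paste0("thorax_", c("x", "y", "z")))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Flight-track table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "splitgaze_schema_error")
  }
  if (nrow(df) < 2) {
    abort("A flight track needs at least 2 frames.",
          class = "splitgaze_schema_error")
  }
  if (any(duplicated(df$frame))) {
    abort(sprintf("Duplicated frame index: %d.",
                  df$frame[duplicated(df$frame)][1]),
          class = "splitgaze_schema_error")
  }
  if (any(diff(df$frame) <= 0)) {
    abort("Frame index must be strictly increasing.",
          class = "splitgaze_schema_error")
  }
  gaps <- which(diff(df$frame) != 1)
  if (length(gaps) > 0) {
    warn(sprintf("Flight track has %d gap(s) in the frame index (first after frame %d).",
                 length(gaps), df$frame[gaps[1]]))
  }
  coord_cols <- intersect(
    c(paste0("head_", c("x", "y", "z")), paste0("thorax_", c("x", "y", "z")),
      paste0("abd_", c("x", "y", "z"))), names(df))
  cm <- as.matrix(df[coord_cols])
  if (any(!is.finite(cm))) {
    abort("Non-finite coordinate in flight track.",
          class = "splitgaze_schema_error")
  }
  out <- as_tibble(df)
  out$t <- (out$frame - out$frame[1]) / frame_rate
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("flight_track", class(out))
  out
}

#' Read a tethered head-marker track
#'
#' Two markers per frame, digitized in the frontal view (head roll) or the
#' side view (head pitch).
#'
#' @param path CSV with columns `frame`, `ax`, `ay`, `bx`, `by`.
#' @param frame_rate Frames per second.
#' @param view `"frontal"` (roll) or `"side"` (pitch).
#' @return A tibble of class `head_marker_track` with attributes
#'   `frame_rate` and `view`.
#' @export
read_head_markers <- function(path, frame_rate, view = c("frontal", "side")) {
  view <- match.arg(view)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  as_head_marker_track(raw, frame_rate, view)
}

#' @rdname read_head_markers
#' @param df Data frame with the marker columns.
#' @export
as_head_marker_track <- function(df, frame_rate, view = c("frontal", "side")) {
  view <- match.arg(view)
  need <- c("frame", "ax", "ay", "bx", "by")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Head-marker table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "splitgaze_schema_error")
  }
  if (nrow(df) < 2) {
    abort("A head-marker track needs at least 2 frames.",
          class = "splitgaze_schema_error")
  }
  cm <- as.matrix(df[c("ax", "ay", "bx", "by")])
  if (any(!is.finite(cm))) {
    abort("Both markers must be present (finite) in every frame.",
          class = "splitgaze_schema_error")
  }
  out <- as_tibble(df)
  out$t <- (out$frame - out$frame[1]) / frame_rate
  attr(out, "frame_rate") <- frame_rate
  attr(out, "view") <- view
  class(out) <- c("head_marker_track", class(out))
  out
}

#' Write a flight track to CSV
#'
#' @param track A `flight_track` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flight_track <- function(track, path) {
  drop <- intersect("t", names(track))
  write.csv(as.data.frame(track)[setdiff(names(track), drop)], path,
            row.names = FALSE)
  invisible(path)
}
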