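# The per-eye map of visual axes: azimuth/elevation per ommatidium,
# six-nearest-neighbour graph, per-ommatidium mean interommatidial angle
# and cross-individual eye averaging.

#' Angularly nearest neighbours of a visual axis
#'
#' Returns the indices of the `k` axes with smallest angular difference to
#' the indexed axis — the "six surrounding facets" of the interommatidial
#' angle definition. Ties are broken in favour of the lower index. The
#' neighbour relation is not assumed (and need not be) symmetric.
#'
#' @param axes n x 3 matrix of axis vectors (rows need not be unit length).
#' @param index Row index of the focal axis.
#' @param k Number of neighbours (clipped to n - 1).
#' @return Integer vector of row indices, ordered by increasing angle.
#' @export
find_neighbors <- function(axes, index, k = 6) {
  axes <- as.matrix(axes)
  n <- nrow(axes)
  if (n < 2) {
    abort("Need at least 2 axes to define neighbours.",
          class = "splitgaze_schema_error")
  }
  if (index < 1 || index > n) {
    abort(sprintf("index %d out of range 1..%d.", index, n),
          class = "splitgaze_schema_error")
  }
  ang <- angular_difference(axes, axes[index, ])
  ang[index] <- Inf
  ord <- order(ang, seq_len(n))
  head(ord, min(k, n - 1))
}

#' Mean interommatidial angle of one ommatidium
#'
#' Arithmetic mean of the angular differences between a focal visual axis
#' and each of its neighbouring axes.
#'
#' @param center_axis Length-3 focal axis.
#' @param neighbor_axes m x 3 matrix (m >= 1) of neighbour axes.
#' @return Mean angle in degrees.
#' @export
mean_interommatidial_angle <- function(center_axis, neighbor_axes) {
  neighbor_axes <- rbind(as.matrix(neighbor_axes))
  if (nrow(neighbor_axes) < 1) {
    abort("At least one neighbour axis is required.",
          class = "splitgaze_schema_error")
  }
  mean(angular_difference(neighbor_axes, center_axis))
}

#' Azimuth/elevation of visual axes in a pitched body frame
#'
#' Expresses gaze vectors in spherical coordinates: azimuth measured from
#' anterior (+x) positive toward the animal's left (+y), elevation positive
#' dorsal. `body_pitch` rotates the reference frame nose-up by that angle,
#' so an axis fixed in the head appears at lower elevation when the body is
#' pitched up.
#'
#' @param axes n x 3 matrix (or length-3 vector) of axis vectors.
#' @param body_pitch Body pitch of the reference frame in degrees
#'   (default 0: longitudinal axis horizontal).
#' @return A tibble with `azimuth` (degrees, (-180, 180]) and `elevation`
#'   (degrees, [-90, 90]).
#' @export
axis_to_azel <- function(axes, body_pitch = 0) {
  if (!is.matrix(axes)) axes <- matrix(axes, ncol = 3)
  if (body_pitch != 0) {
    R <- rotation_matrix(pitch = body_pitch)
    axes <- axes %*% R  # == t(R %*% t(axes)) inverse-rotated: R^T v per row
  }
  ae <- vec_to_azel(axes)
  tibble(azimuth = ae$azimuth, elevation = ae$elevation)
}

#' Build the per-eye ommatidial map
#'
#' Attaches to a per-lens geometry table the spherical gaze coordinates,
#' the angularly nearest-neighbour ids and the per-ommatidium mean
#' interommatidial angle. Neighbour search pools both eye sections of one
#' eye by default (a facet at the section border may have neighbours across
#' the divide); records whose k-th neighbour lies beyond `cutoff` are
#' flagged rather than dropped.
#'
#' @param geometry Tibble from [lens_geometry()] (needs `axis_x..z`,
#'   `section`, `ommatidium_id`).
#' @param k Neighbours per facet (default 6).
#' @param pool_sections Pool dorsal and ventral facets for the neighbour
#'   search (default TRUE); if FALSE, neighbours are restricted to the
#'   facet's own section.
#' @param cutoff Flag facets whose k-th neighbour exceeds this angle
#'   (degrees, default 45).
#' @param body_pitch Reference-frame pitch for the azimuth/elevation
#'   columns (degrees, default 0).
#' @return The geometry tibble plus `azimuth`, `elevation`,
#'   `neighbor_ids` (list column of ommatidium ids), `interommatidial_angle`
#'   and `flagged`.
#' @export
eye_map <- function(geometry, k = 6, pool_sections = TRUE, cutoff = 45,
                    body_pitch = 0) {
  geometry <- as_tibble(geometry)
  axes <- as.matrix(geometry[c("axis_x", "axis_y", "axis_z")])
  n <- nrow(geometry)
  ae <- axis_to_azel(axes, body_pitch = body_pitch)
  geometry$azimuth <- ae$azimuth
  geometry$elevation <- ae$elevation
  nb <- vector("list", n)
  io <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    pool <- if (pool_sections) seq_len(n) else
      which(geometry$section == geometry$section[i])
    if (length(pool) < 2) {
      nb[[i]] <- integer()
      flagged[i] <- TRUE
      next
    }
    local_idx <- match(i, pool)
    nn_local <- find_neighbors(axes[pool, , drop = FALSE], local_idx, k = k)
    nn <- pool[nn_local]
    nb[[i]] <- geometry$ommatidium_id[nn]
    angs <- angular_difference(axes[nn, , drop = FALSE], axes[i, ])
    io[i] <- mean(angs)
    flagged[i] <- max(angs) > cutoff
  }
  geometry$neighbor_ids <- nb
  geometry$interommatidial_angle <- io
  geometry$flagged <- flagged
  geometry
}

#' Per-section summary statistics of an eye map
#'
#' @param map Tibble from [eye_map()].
#' @return One row per section: facet count, mean/SD lens diameter, mean/SD
#'   interommatidial angle.
#' @export
section_summary <- function(map) {
  map %>%
    group_by(.data$section) %>%
    summarise(
      n = dplyr::n(),
      diameter_mean = mean(.data$diameter),
      diameter_sd = sd(.data$diameter),
      interommatidial_mean = mean(.data$interommatidial_angle),
      interommatidial_sd = sd(.data$interommatidial_angle),
      .groups = "drop")
}

#' Average homologous eye landmarks across individuals
#'
#' Given head-width-normalized landmark tables from several individuals,
#' averages the coordinates of homologous landmarks — matched by
#' `(section, ommatidium_id)`, the digitization order within section —
#' producing one averaged eye on which downstream geometry is computed.
#'
#' @param lens_sets A list of normalized landmark tibbles, one per
#'   individual (see [normalize_to_head_width()]).
#' @return A single landmark tibble with per-landmark mean coordinates;
#'   metadata columns are taken from the first set, `animal_id` becomes
#'   `"average"`.
#' @export
average_eyes <- function(lens_sets) {
  stopifnot(is.list(lens_sets), length(lens_sets) >= 1)
  keys <- lapply(lens_sets, function(s) paste(s$section, s$ommatidium_id))
  ref <- keys[[1]]
  for (j in seq_along(keys)[-1]) {
    missing_k <- union(setdiff(ref, keys[[j]]), setdiff(keys[[j]], ref))
    if (length(missing_k) > 0) {
      abort(paste0("Mismatched landmark correspondence; absent homolog(s): ",
                   paste(missing_k, collapse = ", ")),
            class = "splitgaze_schema_error")
    }
  }
  cc <- landmark_coord_cols()
  base <- as_tibble(lens_sets[[1]])
  ord <- order(ref)
  acc <- matrix(0, nrow(base), length(cc))
  for (s in lens_sets) {
    s <- as_tibble(s)
    s <- s[order(paste(s$section, s$ommatidium_id)), ]
    acc <- acc + as.matrix(s[cc])
  }
  out <- base[ord, ]
  out[cc] <- acc / length(lens_sets)
  out$animal_id <- "average"
  out[order(out$section, out$ommatidium_id), ]
}
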