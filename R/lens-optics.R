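# Single-surface lens optics: focal length from curvature radius, focal
# depth within the ommatidium, expected aperture area from a diameter
# distribution, and the comparative percentage statistics.

#' Optics configuration
#'
#' @param refractive_index Corneal refractive index `n` (> 1, default 1.4;
#'   only refraction at the air-cornea transition is modelled).
#' @param formula `"front_focal"` (`f = R / (n - 1)`, the default) or
#'   `"back_focal"` (`f = n R / (n - 1)`).
#' @param ommatidium_length Mean ommatidium length `L` in micrometres
#'   (default 34), the depth available to the rhabdomere.
#' @return A list of class `optics_config`.
#' @export
optics_config <- function(refractive_index = 1.4,
                          formula = c("front_focal", "back_focal"),
                          ommatidium_length = 34) {
  formula <- match.arg(formula)
  if (refractive_index <= 1) {
    abort("refractive_index must be > 1.", class = "splitgaze_schema_error")
  }
  if (ommatidium_length <= 0) {
    abort("ommatidium_length must be > 0.", class = "splitgaze_schema_error")
  }
  structure(list(refractive_index = refractive_index, formula = formula,
                 ommatidium_length = ommatidium_length),
            class = "optics_config")
}

#' Focal length of a single refracting spherical surface
#'
#' @param R Outer curvature radius (micrometres), > 0. Vectorized.
#' @param config An [optics_config()].
#' @return Focal length(s) in micrometres; the formula used is attached as
#'   attribute `formula`.
#' @examples
#' focal_length(0.4) # 1.0 with the defaults
#' @export
focal_length <- function(R, config = optics_config()) {
  if (any(R <= 0)) {
    abort("Curvature radius must be > 0.", class = "splitgaze_schema_error")
  }
  n <- config$refractive_index
  f <- switch(config$formula,
              front_focal = R / (n - 1),
              back_focal = n * R / (n - 1))
  attr(f, "formula") <- config$formula
  f
}

#' Depth of the focal point as a fraction of ommatidium length
#'
#' @param f Focal length (micrometres), > 0. Vectorized.
#' @param L Ommatidium length (micrometres), > 0.
#' @return Dimensionless fraction `f / L`.
#' @export
focal_depth_fraction <- function(f, L = 34) {
  if (any(f <= 0) || any(L <= 0)) {
    abort("f and L must be > 0.", class = "splitgaze_schema_error")
  }
  f / L
}

#' Relative difference between two positive quantities, in percent
#'
#' `|a - b| / max(a, b) * 100` — the convention behind "section A differs
#' by X% from section B" comparisons.
#'
#' @param a,b Positive scalars.
#' @return Percentage in `[0, 100)`.
#' @examples
#' relative_difference(6.35, 7.67) # ~17.2
#' @export
relative_difference <- function(a, b) {
  if (any(c(a, b) <= 0)) {
    abort("relative_difference() needs positive inputs.",
          class = "splitgaze_schema_error")
  }
  abs(a - b) / pmax(a, b) * 100
}

#' Expected lens aperture area from a diameter distribution
#'
#' Population mean of per-lens disc areas when the lens diameter has mean
#' `mu` and standard deviation `sigma`: `pi/4 * (mu^2 + sigma^2)`. The
#' closed form is distribution-free given the first two moments.
#'
#' @param diameter_mean Mean diameter `mu` in micrometres, > 0.
#' @param diameter_sd Diameter SD `sigma` in micrometres, >= 0.
#' @return Expected aperture area in square micrometres.
#' @examples
#' mean_aperture_area(2, 0) # pi
#' @export
mean_aperture_area <- function(diameter_mean, diameter_sd = 0) {
  if (any(diameter_mean <= 0) || any(diameter_sd < 0)) {
    abort("Need diameter_mean > 0 and diameter_sd >= 0.",
          class = "splitgaze_schema_error")
  }
  pi / 4 * (diameter_mean^2 + diameter_sd^2)
}

#' Append per-lens optics to a geometry table
#'
#' @param geometry Tibble from [lens_geometry()] (needs `curvature_radius`).
#' @param config An [optics_config()].
#' @return The geometry tibble plus `focal_length`,
#'   `focal_depth_fraction` and `focal_formula`.
#' @export
add_lens_optics <- function(geometry, config = optics_config()) {
  geometry <- as_tibble(geometry)
  f <- as.numeric(focal_length(geometry$curvature_radius, config))
  geometry$focal_length <- f
  geometry$focal_depth_fraction <-
    focal_depth_fraction(f, config$ommatidium_length)
  geometry$focal_formula <- config$formula
  geometry
}
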