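# Tangent-screen geometry: all metric conversions between visual-field
# degrees, screen centimetres, pixels and time.

#' Screen geometry for a tangent-screen (campimetry) setup
#'
#' Describes the flat testing screen: viewing distance, physical extent,
#' pixel density, refresh rate and where the fixation target sits on the
#' screen. All degree/centimetre conversions in the package go through the
#' separable tangent projection `x_cm = D * tan(x_deg)` (and likewise for
#' `y`), so a vertical line in the visual field maps to a vertical line on
#' the screen.
#'
#' The default geometry is a 21.4 cm x 14.1 cm tested area (442 px
#' horizontally) viewed at 40 cm. The fixation target is placed so that the
#' nasal field extends 10 degrees to the screen edge; the remaining width
#' lies temporally and covers the blind spot at 15 degrees.
#'
#' @param viewing_distance_cm Eye-to-screen distance in cm.
#' @param screen_width_cm,screen_height_cm Physical extent of the tested
#'   screen area in cm.
#' @param px_per_cm Linear pixel density (defaults to 442 px / 21.4 cm).
#' @param frame_rate_hz Display refresh rate used to sample stimulus motion.
#' @param fixation_x_cm,fixation_y_cm Position of the fixation target,
#'   measured from the lower-left screen corner. Defaults: 10 degrees of
#'   nasal field to the left edge (clamped to the screen centre for narrow
#'   screens) and vertical centring.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' tested_region_edge_cm(geom) # ~14.1 cm for the central +/-10 degrees
#' @export
screen_geometry <- function(viewing_distance_cm = 40,
                            screen_width_cm = 21.4,
                            screen_height_cm = 14.1,
                            px_per_cm = 442 / 21.4,
                            frame_rate_hz = 60,
                            fixation_x_cm = NULL,
                            fixation_y_cm = NULL) {
  vals <- c(viewing_distance_cm, screen_width_cm, screen_height_cm,
            px_per_cm, frame_rate_hz)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen geometry parameters must be finite and strictly positive")
  }
  if (is.null(fixation_x_cm)) {
    fixation_x_cm <- min(viewing_distance_cm * tan(10 * pi / 180),
                         screen_width_cm / 2)
  }
  if (is.null(fixation_y_cm)) fixation_y_cm <- screen_height_cm / 2
  if (fixation_x_cm <= 0 || fixation_x_cm >= screen_width_cm ||
      fixation_y_cm <= 0 || fixation_y_cm >= screen_height_cm) {
    stop("fixation target must lie strictly inside the screen")
  }
  structure(list(viewing_distance_cm = viewing_distance_cm,
                 screen_width_cm = screen_width_cm,
                 screen_height_cm = screen_height_cm,
                 px_per_cm = px_per_cm,
                 frame_rate_hz = frame_rate_hz,
                 fixation_x_cm = fixation_x_cm,
                 fixation_y_cm = fixation_y_cm),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat("Tangent-screen geometry\n")
  cat(sprintf("  viewing distance: %.1f cm\n", x$viewing_distance_cm))
  cat(sprintf("  screen: %.1f x %.1f cm at %.3f px/cm (%d Hz)\n",
              x$screen_width_cm, x$screen_height_cm, x$px_per_cm,
              round(x$frame_rate_hz)))
  b <- screen_bounds_cm(x)
  cat(sprintf("  field extent: x [%.2f, %.2f] cm, y [%.2f, %.2f] cm about fixation\n",
              b$x[1], b$x[2], b$y[1], b$y[2]))
  invisible(x)
}

#' Stimulus specification for the moving test dot
#'
#' Carries the eccentricity-dependent diameter law (linear between the
#' calibrated endpoints `d0_mm` at fixation and `d15_mm` at `ecc_max_deg`,
#' clamped outside), the dot and background luminances (metadata; nothing is
#' rendered photometrically), the fixation-cross size and the running speed
#' of the dot on the screen.
#'
#' @param d0_mm Dot diameter at 0 degrees eccentricity (mm).
#' @param d15_mm Dot diameter at `ecc_max_deg` (mm).
#' @param ecc_max_deg Eccentricity at which the diameter law saturates.
#' @param dot_luminance_cdm2,background_luminance_cdm2 Luminances in cd/m2.
#' @param fixation_diameter_deg Fixation cross diameter in degrees.
#' @param speed_cm_s Linear running speed of the dot on the screen, cm/s.
#'   Must lie within the tested range `[0.18, 24]`.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(d0_mm = 1.05,
                          d15_mm = 2.72,
                          ecc_max_deg = 15,
                          dot_luminance_cdm2 = 140,
                          background_luminance_cdm2 = 0.8,
                          fixation_diameter_deg = 1.39,
                          speed_cm_s = 3.0) {
  if (!(d15_mm > d0_mm && d0_mm > 0)) {
    stop("diameter law endpoints must satisfy d15_mm > d0_mm > 0")
  }
  if (ecc_max_deg <= 0) stop("ecc_max_deg must be positive")
  if (speed_cm_s < 0.18 || speed_cm_s > 24) {
    stop("speed_cm_s must lie within the legal range [0.18, 24] cm/s")
  }
  if (dot_luminance_cdm2 <= background_luminance_cdm2) {
    stop("the dot must be brighter than the background")
  }
  structure(list(d0_mm = d0_mm, d15_mm = d15_mm, ecc_max_deg = ecc_max_deg,
                 dot_luminance_cdm2 = dot_luminance_cdm2,
                 background_luminance_cdm2 = background_luminance_cdm2,
                 fixation_diameter_deg = fixation_diameter_deg,
                 speed_cm_s = speed_cm_s),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("Campimetry stimulus\n")
  cat(sprintf("  diameter law: %.2f mm at 0 deg -> %.2f mm at %.0f deg (clamped)\n",
              x$d0_mm, x$d15_mm, x$ecc_max_deg))
  cat(sprintf("  luminance: %g on %g cd/m2; speed %.2f cm/s\n",
              x$dot_luminance_cdm2, x$background_luminance_cdm2, x$speed_cm_s))
  invisible(x)
}

# Coerce a point argument (length-2 vector, n x 2 matrix, or data frame) to
# an n x 2 numeric matrix.
as_field_points <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) {
    if (length(p) != 2) stop("a field point must have exactly two coordinates")
    p <- matrix(as.numeric(p), nrow = 1)
  }
  if (ncol(p) != 2) stop("points must be given as an n x 2 matrix")
  storage.mode(p) <- "double"
  if (any(!is.finite(p))) stop("field points must be finite")
  p
}

#' Convert visual-field degrees to screen centimetres
#'
#' Separable per-axis tangent projection with the fixation target at the
#' origin: `x_cm = D * tan(x_deg)` and likewise for `y`. The mapping is
#' invertible and monotone per axis; see [cm_to_deg()].
#'
#' @param p A field point `c(x_deg, y_deg)` or an n x 2 matrix/data frame.
#' @param geom A [screen_geometry()].
#' @return An n x 2 matrix with columns `x_cm`, `y_cm`.
#' @examples
#' deg_to_cm(c(10, 0), screen_geometry()) # ~7.05 cm
#' @export
deg_to_cm <- function(p, geom) {
  p <- as_field_points(p)
  if (any(abs(p) >= 90)) {
    stop("angles must lie strictly within +/-90 degrees of fixation")
  }
  out <- geom$viewing_distance_cm * tan(p * pi / 180)
  colnames(out) <- c("x_cm", "y_cm")
  out
}

#' Convert screen centimetres to visual-field degrees
#'
#' Inverse of [deg_to_cm()]: `x_deg = atan(x_cm / D)` per axis.
#'
#' @param p A screen point `c(x_cm, y_cm)` relative to fixation, or an
#'   n x 2 matrix/data frame.
#' @inheritParams deg_to_cm
#' @return An n x 2 matrix with columns `x_deg`, `y_deg`.
#' @export
cm_to_deg <- function(p, geom) {
  p <- as_field_points(p)
  out <- atan(p / geom$viewing_distance_cm) * 180 / pi
  colnames(out) <- c("x_deg", "y_deg")
  out
}

#' Radial eccentricity of field points
#'
#' Euclidean distance from fixation in visual-field degree coordinates;
#' this radius governs the dot size law.
#'
#' @inheritParams deg_to_cm
#' @return Numeric vector of eccentricities in degrees.
#' @export
eccentricity_deg <- function(p) {
  p <- as_field_points(p)
  sqrt(rowSums(p^2))
}

#' Eccentricity-dependent dot diameter (mm)
#'
#' Linear interpolation between the calibrated endpoints: `d0_mm` at
#' fixation and `d15_mm` at `ecc_max_deg`, clamped to `[d0_mm, d15_mm]`
#' beyond. With the defaults the slope is (2.72 - 1.05)/15 ~ 0.111 mm per
#' degree, and the law reproduces the published size ladder at 0, 1, 2.5,
#' 5, 7.5, 10, 12.5 and 15 degrees to within 0.03 mm.
#'
#' @param ecc_deg Eccentricity in degrees (vectorised, non-negative).
#' @param spec A [stimulus_spec()].
#' @return Dot diameter(s) in mm.
#' @examples
#' dot_diameter_mm(c(0, 7.5, 15), stimulus_spec())
#' @export
dot_diameter_mm <- function(ecc_deg, spec = stimulus_spec()) {
  if (any(!is.finite(ecc_deg)) || any(ecc_deg < 0)) {
    stop("eccentricity must be finite and non-negative")
  }
  d <- spec$d0_mm + (spec$d15_mm - spec$d0_mm) / spec$ecc_max_deg * ecc_deg
  pmin(pmax(d, spec$d0_mm), spec$d15_mm)
}

#' Angular subtense of a dot of given physical diameter
#'
#' Small-angle conversion `d / D` expressed in degrees. This matches the
#' published angular-diameter column of the size ladder for rows at and
#' above 1 degree of eccentricity (the 0-degree row of that table is a
#' rounding anomaly: 1.05 mm at 40 cm subtends 0.150 degrees).
#'
#' @param d_mm Dot diameter(s) in mm (non-negative).
#' @inheritParams deg_to_cm
#' @return Angular diameter(s) in degrees.
#' @examples
#' angular_diameter_deg(2.72, screen_geometry()) # ~0.39 deg
#' @export
angular_diameter_deg <- function(d_mm, geom = screen_geometry()) {
  if (any(!is.finite(d_mm)) || any(d_mm < 0)) {
    stop("diameter must be finite and non-negative")
  }
  d_mm / (10 * geom$viewing_distance_cm) * 180 / pi
}

#' Dot angular diameter at a given eccentricity
#'
#' Convenience composition of [dot_diameter_mm()] and
#' [angular_diameter_deg()].
#'
#' @inheritParams dot_diameter_mm
#' @inheritParams deg_to_cm
#' @return Angular diameter(s) in degrees.
#' @export
dot_diameter_deg <- function(ecc_deg, spec = stimulus_spec(),
                             geom = screen_geometry()) {
  angular_diameter_deg(dot_diameter_mm(ecc_deg, spec), geom)
}

#' Angular-speed ratio of constant linear motion on a flat screen
#'
#' A dot moving at constant linear speed on the tangent screen slows in
#' angular terms away from the axis; the instantaneous angular speed
#' relative to the on-axis value is `cos^2(ecc)`. At 10 degrees the
#' deviation from 1 is about 3 percent, which is why the flat screen is a
#' valid stand-in for a curved perimeter bowl over the central field.
#'
#' @param ecc_deg Eccentricity in degrees, `0 <= ecc < 90` (vectorised).
#' @return Dimensionless ratio(s) in `(0, 1]`.
#' @export
angular_speed_ratio <- function(ecc_deg) {
  if (any(!is.finite(ecc_deg)) || any(ecc_deg < 0) || any(ecc_deg >= 90)) {
    stop("eccentricity must lie in [0, 90) degrees")
  }
  cos(ecc_deg * pi / 180)^2
}

#' Time to traverse a path at constant speed
#'
#' @param length_cm Path length(s) in cm (non-negative).
#' @param speed_cm_s Speed in cm/s (strictly positive).
#' @return Duration(s) in seconds.
#' @examples
#' traversal_time_s(14.1, 3) # 4.7 s across the central 10-degree square
#' @export
traversal_time_s <- function(length_cm, speed_cm_s) {
  if (any(!is.finite(length_cm)) || any(length_cm < 0)) {
    stop("length must be finite and non-negative")
  }
  if (any(!is.finite(speed_cm_s)) || any(speed_cm_s <= 0)) {
    stop("speed must be strictly positive")
  }
  length_cm / speed_cm_s
}

#' Edge length of the tested central square
#'
#' `2 * D * tan(half_width_deg)`: about 14.1 cm for the central +/-10
#' degrees at 40 cm viewing distance.
#'
#' @inheritParams deg_to_cm
#' @param half_width_deg Half-width of the square in degrees.
#' @return Edge length in cm.
#' @export
tested_region_edge_cm <- function(geom = screen_geometry(),
                                  half_width_deg = 10) {
  2 * geom$viewing_distance_cm * tan(half_width_deg * pi / 180)
}

# Screen bounds in cm relative to the fixation target.
screen_bounds_cm <- function(geom) {
  list(x = c(-geom$fixation_x_cm, geom$screen_width_cm - geom$fixation_x_cm),
       y = c(-geom$fixation_y_cm, geom$screen_height_cm - geom$fixation_y_cm))
}
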