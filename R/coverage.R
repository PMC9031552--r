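# Coverage-area accounting: how much of the central field the moving dot
# actually paints, versus a static test grid.

#' Trapezoid model of the area swept by one path
#'
#' The dot grows linearly with eccentricity, so the band it sweeps along a
#' path is approximately two mirror-image trapezoids; laid side by side
#' they form a rectangle whose sides are half the running distance and the
#' sum of the largest and smallest dot diameters on the path. The swept
#' area is therefore `(thickest + thinnest) * half_run`.
#'
#' @param thickest_cm,thinnest_cm Largest and smallest dot diameter on the
#'   path, in cm (`thickest >= thinnest > 0`).
#' @param half_run_cm Half the running distance of the dot, in cm.
#' @return Swept area(s) in cm^2 (vectorised).
#' @examples
#' trapezoid_path_area(0.26, 0.22, 7) # ~3.36 cm^2
#' @export
trapezoid_path_area <- function(thickest_cm, thinnest_cm, half_run_cm) {
  if (any(!is.finite(c(thickest_cm, thinnest_cm, half_run_cm)))) {
    stop("trapezoid inputs must be finite")
  }
  if (any(thinnest_cm <= 0) || any(half_run_cm <= 0)) {
    stop("thicknesses and half-run must be strictly positive")
  }
  if (any(thickest_cm < thinnest_cm)) {
    stop("thickest_cm must be at least thinnest_cm")
  }
  (thickest_cm + thinnest_cm) * half_run_cm
}

#' Area of the tested central square
#'
#' The square spanned by the horizontal and vertical diameters of the
#' 10-degree area; with the nominal 14.1 cm edge this is 198.81 cm^2.
#'
#' @param edge_cm Edge length in cm.
#' @return Area in cm^2.
#' @export
tested_square_area_cm2 <- function(edge_cm = 14.1) {
  if (!is.finite(edge_cm) || edge_cm <= 0) stop("edge must be positive")
  edge_cm^2
}

#' Area of a disc-shaped test region
#'
#' `pi * r^2`; with the 5.28 cm radius of the central 10-degree area at
#' 30 cm this is 87.58 cm^2.
#'
#' @param radius_cm Disc radius in cm.
#' @return Area in cm^2.
#' @export
disc_region_area_cm2 <- function(radius_cm) {
  if (any(!is.finite(radius_cm)) || any(radius_cm <= 0)) {
    stop("radius must be strictly positive")
  }
  pi * radius_cm^2
}

#' Canonical per-path coverage inputs for the default layout
#'
#' The greatest and smallest dot thickness and half running distance for
#' each path group of the default screening layout at 40 cm, quoted at
#' instrument precision (thickness to 0.01 cm; the vertical half-run to the
#' nearest cm). [screening_coverage_rows()] recomputes the same quantities
#' from any layout.
#'
#' @return A data frame with columns `label`, `thickest_cm`, `thinnest_cm`,
#'   `half_run_cm`.
#' @export
reference_coverage_rows <- function() {
  data.frame(label = c("vertical_1", "vertical_2", "vertical_3",
                       "diagonal_1_2", "horizontal_1_2"),
             thickest_cm = c(0.26, 0.24, 0.22, 0.24, 0.19),
             thinnest_cm = c(0.22, 0.18, 0.13, 0.14, 0.14),
             half_run_cm = c(7, 7, 7, 7.44, 5.6),
             stringsAsFactors = FALSE)
}

#' Per-path coverage inputs computed from a trajectory
#'
#' Samples the dot diameter densely along each screening path and reports,
#' per path group (verticals individually; the two diagonals and the two
#' horizontals pooled, as they are congruent), the largest and smallest dot
#' thickness in cm and half the group's running distance. The blind-spot
#' pass is excluded: it lies outside the central square being accounted.
#'
#' @param trajectory A `trajectory` from [build_screening_trajectory()].
#' @param spec A [stimulus_spec()].
#' @inheritParams deg_to_cm
#' @param thickness_digits Decimals to which thicknesses are rounded
#'   (half-up); `NULL` for unrounded.
#' @param n_samples Samples per path for the thickness extrema.
#' @return A data frame like [reference_coverage_rows()].
#' @export
screening_coverage_rows <- function(trajectory, spec = stimulus_spec(),
                                    geom = screen_geometry(),
                                    thickness_digits = 2,
                                    n_samples = 2001) {
  labs <- vapply(trajectory, function(p) p$label, character(1))
  groups <- list()
  for (i in seq_along(trajectory)) {
    lab <- labs[i]
    if (lab == "blind_spot_line") next
    g <- sub("^(diagonal|horizontal)_[0-9]+$", "\\1_1_2", lab)
    groups[[g]] <- c(groups[[g]], i)
  }
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    dmm <- c(); total_len <- 0
    for (i in idx) {
      p <- trajectory[[i]]
      len <- path_length_cm(p, geom)
      pts <- path_point_deg(p, seq(0, len, length.out = n_samples), geom)
      dmm <- c(dmm, dot_diameter_mm(eccentricity_deg(pts), spec))
      total_len <- total_len + len
    }
    thick <- c(max(dmm), min(dmm)) / 10
    if (!is.null(thickness_digits)) {
      thick <- round_half_up(thick, thickness_digits)
    }
    data.frame(label = g, thickest_cm = thick[1], thinnest_cm = thick[2],
               half_run_cm = total_len / 2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Coverage report for a set of path rows
#'
#' Applies the trapezoid model to each row, totals the swept area, and
#' expresses it as a percentage of the tested region. On the canonical
#' rows of [reference_coverage_rows()] with the 198.81 cm^2 square the
#' total is ~13.42 cm^2, i.e. 6.75 percent of the paracentral field.
#'
#' @param rows Data frame with columns `label`, `thickest_cm`,
#'   `thinnest_cm`, `half_run_cm`.
#' @param region_area_cm2 Area of the tested region in cm^2.
#' @return An object of class `coverage_report`: the rows with an
#'   `area_cm2` column plus `total_area_cm2`, `region_area_cm2` and
#'   `percent_covered`.
#' @examples
#' coverage_report(reference_coverage_rows())
#' @export
coverage_report <- function(rows, region_area_cm2 = tested_square_area_cm2()) {
  if (!is.data.frame(rows) || nrow(rows) < 1) {
    stop("at least one path row is required")
  }
  need <- c("label", "thickest_cm", "thinnest_cm", "half_run_cm")
  if (!all(need %in% names(rows))) {
    stop("rows must have columns label, thickest_cm, thinnest_cm, half_run_cm")
  }
  if (!is.finite(region_area_cm2) || region_area_cm2 <= 0) {
    stop("region area must be strictly positive")
  }
  rows <- rows[, need]
  rows$area_cm2 <- trapezoid_path_area(rows$thickest_cm, rows$thinnest_cm,
                                       rows$half_run_cm)
  total <- sum(rows$area_cm2)
  pct <- 100 * total / region_area_cm2
  if (pct >= 100) stop("swept area exceeds the tested region; check inputs")
  structure(list(rows = rows, total_area_cm2 = total,
                 region_area_cm2 = region_area_cm2, percent_covered = pct),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Coverage of the tested visual field\n")
  print(x$rows, row.names = FALSE)
  cat(sprintf("  total %.2f cm^2 of %.2f cm^2 (%.2f%%)\n",
              x$total_area_cm2, x$region_area_cm2, x$percent_covered))
  invisible(x)
}

#' Coverage of a static test-point grid
#'
#' Total stimulus area of a static perimetry program as a percentage of
#' the tested region: `100 * n * a / region`. With 68 points of 4 mm^2
#' over the 87.58 cm^2 central 10-degree disc this is 3.1 percent.
#'
#' @param n_points Number of grid points.
#' @param stimulus_area_mm2 Area of one stimulus in mm^2.
#' @param region_area_cm2 Tested region area in cm^2.
#' @return Percent of the region covered.
#' @examples
#' static_grid_coverage_percent(68, 4, disc_region_area_cm2(5.28))
#' @export
static_grid_coverage_percent <- function(n_points, stimulus_area_mm2 = 4,
                                         region_area_cm2 =
                                           disc_region_area_cm2(5.28)) {
  if (n_points < 0 || stimulus_area_mm2 <= 0 || region_area_cm2 <= 0) {
    stop("grid coverage inputs must be positive (n_points may be zero)")
  }
  100 * n_points * (stimulus_area_mm2 / 100) / region_area_cm2
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention used for comparing
#' computed values against printed tables), unlike base `round()`'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
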