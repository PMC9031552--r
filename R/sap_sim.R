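# Geometric proxy of a 10-2 static perimetry exam, for comparing static
# and kinetic testing on the same ground-truth field.

#' The 10-2 static test grid
#'
#' The 68-point central grid: all points with odd integer coordinates
#' `x, y in {+/-1, ..., +/-9}` satisfying `x^2 + y^2 <= 82` -- the unique
#' odd-lattice radius cutoff yielding exactly 68 points with 2-degree
#' spacing offset 1 degree from both meridians. The default stimulus is
#' the 0.43-degree Goldmann size III equivalent.
#'
#' @param stimulus_diameter_deg Angular diameter of the static stimulus.
#' @return An object of class `static_grid` with a 68-row `points` data
#'   frame.
#' @export
grid_10_2 <- function(stimulus_diameter_deg = 0.43) {
  if (stimulus_diameter_deg <= 0) stop("stimulus diameter must be positive")
  v <- seq(-9, 9, by = 2)
  g <- expand.grid(x_deg = v, y_deg = v)
  g <- g[g$x_deg^2 + g$y_deg^2 <= 82, ]
  g <- g[order(-g$y_deg, g$x_deg), ]
  rownames(g) <- NULL
  structure(list(points = g, stimulus_diameter_deg = stimulus_diameter_deg,
                 label = "10-2"),
            class = "static_grid")
}

#' Simulate a static perimetry exam on a ground-truth field
#'
#' Purely geometric classification of each grid point by stimulus
#' containment -- no staircases or dB thresholds. A point is an
#' `absolute_defect` iff the whole static stimulus disc fits inside
#' absolute scotoma; it is a `relative_defect` if the disc partially
#' overlaps absolute scotoma or its centre lies in a relative region;
#' otherwise it is `normal`. Because the 0.43-degree stimulus cannot fit
#' inside a 0.35-degree band, narrow arcuate defects are never classified
#' deeper than relative by the static exam.
#'
#' @param field A [visual_field()].
#' @param grid A [grid_10_2()] (or any `static_grid`).
#' @return An object of class `static_exam_result` with per-point
#'   classifications and summary counts.
#' @examples
#' res <- simulate_static_exam(make_preset_field("narrow_arcuate_035"))
#' res$counts["absolute_defect"] # 0
#' @export
simulate_static_exam <- function(field, grid = grid_10_2()) {
  if (!inherits(field, "visual_field")) stop("field must be a visual_field")
  if (!inherits(grid, "static_grid")) stop("grid must be a static_grid")
  pts <- grid$points
  fr <- disc_coverage_fractions(field, pts$x_deg, pts$y_deg,
                                grid$stimulus_diameter_deg, "absolute")
  ctr <- classify_points(field, pts$x_deg, pts$y_deg)
  cls <- ifelse(fr >= 1 - 1e-12, "absolute_defect",
                ifelse(fr > 0 | ctr == "relative", "relative_defect",
                       "normal"))
  pts$classification <- cls
  counts <- c(normal = sum(cls == "normal"),
              relative_defect = sum(cls == "relative_defect"),
              absolute_defect = sum(cls == "absolute_defect"))
  structure(list(grid = grid, points = pts, counts = counts,
                 field_signature = field_signature(field)),
            class = "static_exam_result")
}

#' @export
print.static_exam_result <- function(x, ...) {
  cat(sprintf("Static %s exam (%d points, %.2f deg stimulus)\n",
              x$grid$label, nrow(x$points), x$grid$stimulus_diameter_deg))
  print(x$counts)
  invisible(x)
}

#' Compare kinetic screening against the static exam
#'
#' For each ground-truth scotoma (the blind spot is excluded), reports
#' whether each method flagged it as an absolute defect: the kinetic
#' screening counts off/on segments whose midpoint lies in the region; the
#' static exam counts defect points inside it. A region is *discordant*
#' when the kinetic exam finds an absolute defect there while the static
#' exam classifies it at most relative -- the signature pattern for narrow
#' arcuate scotomas.
#'
#' @param exam An `exam_record` from [run_screening()].
#' @param static_result A `static_exam_result` from
#'   [simulate_static_exam()].
#' @param field The [visual_field()] both exams were run on.
#' @return An object of class `method_comparison`: a per-region data frame
#'   plus overall positivity flags for both methods.
#' @export
compare_methods <- function(exam, static_result, field) {
  if (!inherits(exam, "exam_record")) stop("exam must be an exam_record")
  if (!inherits(static_result, "static_exam_result")) {
    stop("static_result must be a static_exam_result")
  }
  sig <- field_signature(field)
  if (!identical(exam$field_signature, sig) ||
      !identical(static_result$field_signature, sig)) {
    stop("exam and static result must derive from the given field")
  }
  segs <- exam$segments
  sp <- static_result$points
  rows <- list()
  for (i in seq_along(field$scotomas)) {
    rg <- field$scotomas[[i]]
    n_seg <- 0L
    if (nrow(segs) > 0) {
      mx <- (segs$x_off_deg + segs$x_on_deg) / 2
      my <- (segs$y_off_deg + segs$y_on_deg) / 2
      n_seg <- sum(region_contains(rg, mx, my))
    }
    in_rg <- region_contains(rg, sp$x_deg, sp$y_deg)
    n_abs <- sum(in_rg & sp$classification == "absolute_defect")
    n_def <- sum(in_rg & sp$classification != "normal")
    camp_abs <- rg$depth == "absolute" && n_seg > 0
    stat_abs <- n_abs > 0
    rows[[i]] <- data.frame(region = i, type = class(rg)[1],
                            depth = rg$depth,
                            campimetry_segments = n_seg,
                            campimetry_absolute = camp_abs,
                            static_defect_points = n_def,
                            static_absolute_points = n_abs,
                            static_absolute = stat_abs,
                            discordant = camp_abs && !stat_abs,
                            stringsAsFactors = FALSE)
  }
  regions <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
             else data.frame()
  camp_pos <- nrow(segs) > 0 && any(segs$path != "blind_spot_line")
  stat_pos <- any(sp$classification != "normal")
  structure(list(regions = regions,
                 campimetry_positive = camp_pos,
                 static_positive = stat_pos,
                 any_discordant = length(rows) > 0 && any(regions$discordant)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Kinetic campimetry vs static perimetry\n")
  cat(sprintf("  campimetry positive: %s; static positive: %s\n",
              x$campimetry_positive, x$static_positive))
  if (nrow(x$regions) > 0) print(x$regions, row.names = FALSE)
  if (isTRUE(x$any_discordant)) {
    cat("  discordance: absolute on kinetic testing, at most relative on static\n")
  }
  invisible(x)
}
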