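# The screening trajectory: ordered straight paths on the screen, plus the
# pixel ("test point") accounting of the run.

#' A single straight test-point path
#'
#' Paths are straight lines on the screen; endpoints are stored in
#' visual-field degrees. `speed_divisor` slows the path for delineation
#' (1 for screening).
#'
#' @param label Path label, e.g. `"vertical_1"` or `"blind_spot_line"`.
#' @param start,end Endpoints as `c(x_deg, y_deg)`; must differ.
#' @param speed_divisor Positive integer divisor applied to the stimulus
#'   speed on this path.
#' @return An object of class `path_spec`.
#' @export
path_spec <- function(label, start, end, speed_divisor = 1L) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 2 || length(end) != 2 ||
      any(!is.finite(c(start, end)))) {
    stop("path endpoints must be finite length-2 coordinates")
  }
  if (all(start == end)) stop("path start and end must differ")
  if (!is.finite(speed_divisor) || speed_divisor < 1) {
    stop("speed_divisor must be a positive integer")
  }
  structure(list(label = as.character(label), start = start, end = end,
                 speed_divisor = as.integer(speed_divisor)),
            class = "path_spec")
}

#' Default layout of the screening trajectory
#'
#' The published description fixes the path count (one blind-spot pass,
#' three verticals, two diagonals, two horizontals) but not the exact line
#' placements, which are back-solved here from the per-path coverage table:
#' the vertical mid-path dot thicknesses imply verticals at 10, 6.5 and 2.5
#' degrees temporal spanning +/-10 degrees; the diagonal and horizontal
#' half-runs imply 7.44 cm diagonals at +/-45 degrees and 5.6 cm
#' horizontals at y = +/-3.2 degrees. Every entry can be overridden.
#'
#' @return A list of layout parameters consumed by
#'   [build_screening_trajectory()].
#' @export
default_screening_layout <- function() {
  list(blind_spot_x_deg = 15,
       blind_spot_y_span_deg = c(-7, 7),
       vertical_x_deg = c(10, 6.5, 2.5),
       vertical_y_span_deg = c(-10, 10),
       diagonal_start_cm = c(2.07, -0.76),
       diagonal_length_cm = 7.44,
       horizontal_y_deg = 3.2,
       horizontal_x_span_cm = c(-0.5, 5.1))
}

#' Build the screening trajectory
#'
#' Orders the paths as run in the exam: the blind-spot pass at 15 degrees
#' temporal first (so the subject learns the response rule on a defect they
#' are guaranteed to have), then three verticals from temporal to nasal,
#' two +/-45-degree diagonals and two horizontals. The seven central paths
#' total about 68.4 cm of screen travel. Coordinates follow the
#' temporal-positive-x convention of the tested eye.
#'
#' @inheritParams deg_to_cm
#' @param layout Layout parameters, see [default_screening_layout()].
#' @param include_blind_spot Include the introductory blind-spot pass?
#' @param eye `"OD"` or `"OS"`; carried as metadata on the trajectory.
#' @return A list of [path_spec()] objects with class `trajectory`.
#' @examples
#' traj <- build_screening_trajectory(screen_geometry())
#' length(traj) # 8 paths: blind-spot line + 7
#' @export
build_screening_trajectory <- function(geom = screen_geometry(),
                                       layout = default_screening_layout(),
                                       include_blind_spot = TRUE,
                                       eye = c("OD", "OS")) {
  eye <- match.arg(eye)
  paths <- list()
  if (include_blind_spot) {
    ys <- layout$blind_spot_y_span_deg
    paths <- c(paths, list(path_spec("blind_spot_line",
                                     c(layout$blind_spot_x_deg, ys[1]),
                                     c(layout$blind_spot_x_deg, ys[2]))))
  }
  vy <- layout$vertical_y_span_deg
  for (i in seq_along(layout$vertical_x_deg)) {
    x <- layout$vertical_x_deg[i]
    paths <- c(paths, list(path_spec(paste0("vertical_", i),
                                     c(x, vy[1]), c(x, vy[2]))))
  }
  a_cm <- layout$diagonal_start_cm
  b_cm <- a_cm + layout$diagonal_length_cm / sqrt(2) * c(1, 1)
  d1s <- cm_to_deg(a_cm, geom)[1, ]; d1e <- cm_to_deg(b_cm, geom)[1, ]
  paths <- c(paths,
             list(path_spec("diagonal_1", d1s, d1e),
                  path_spec("diagonal_2", d1s * c(1, -1), d1e * c(1, -1))))
  hy <- layout$horizontal_y_deg
  hx <- layout$horizontal_x_span_cm
  hxd <- cm_to_deg(cbind(hx, c(0, 0)), geom)[, 1]
  paths <- c(paths,
             list(path_spec("horizontal_1", c(hxd[1], hy), c(hxd[2], hy)),
                  path_spec("horizontal_2", c(hxd[1], -hy), c(hxd[2], -hy))))
  traj <- structure(paths, class = "trajectory", eye = eye)
  check_trajectory_on_screen(traj, geom)
  traj
}

# Endpoints may overhang the screen by less than half a pixel: nominal
# screen dimensions are rounded to the mm while path spans are exact
# (2 * 40 * tan(10 deg) = 14.106 cm on a screen quoted as 14.1 cm).
check_trajectory_on_screen <- function(trajectory, geom, tol = 0.5 / geom$px_per_cm) {
  b <- screen_bounds_cm(geom)
  for (p in trajectory) {
    ends <- deg_to_cm(rbind(p$start, p$end), geom)
    if (any(ends[, 1] < b$x[1] - tol) || any(ends[, 1] > b$x[2] + tol) ||
        any(ends[, 2] < b$y[1] - tol) || any(ends[, 2] > b$y[2] + tol)) {
      stop(sprintf("path '%s' leaves the screen: check layout and geometry",
                   p$label))
    }
  }
  invisible(trajectory)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Screening trajectory (%s), %d paths\n",
              attr(x, "eye"), length(x)))
  for (p in x) {
    cat(sprintf("  %-16s (%6.2f, %6.2f) -> (%6.2f, %6.2f) deg, divisor %d\n",
                p$label, p$start[1], p$start[2], p$end[1], p$end[2],
                p$speed_divisor))
  }
  invisible(x)
}

#' Screen length of a path in cm
#'
#' @param path A [path_spec()].
#' @inheritParams deg_to_cm
#' @return Length in cm.
#' @export
path_length_cm <- function(path, geom = screen_geometry()) {
  ends <- deg_to_cm(rbind(path$start, path$end), geom)
  sqrt(sum((ends[2, ] - ends[1, ])^2))
}

#' Total screen length of a trajectory
#'
#' @param trajectory A `trajectory` (list of [path_spec()]).
#' @inheritParams deg_to_cm
#' @param include_blind_spot Include the blind-spot pass in the sum?
#' @return Total length in cm.
#' @export
trajectory_length_cm <- function(trajectory, geom = screen_geometry(),
                                 include_blind_spot = FALSE) {
  keep <- vapply(trajectory, function(p) {
    include_blind_spot || p$label != "blind_spot_line"
  }, logical(1))
  sum(vapply(trajectory[keep], path_length_cm, numeric(1), geom = geom))
}

#' Count distinct pixels traversed by the dot centre
#'
#' Rasterises each path onto the screen's pixel grid (cells of size
#' `1/px_per_cm`, clamped to the physical pixel array) by dense
#' supersampling at a quarter-pixel step, and counts the distinct cells
#' visited across all paths. Each visited pixel is one "test point" of the
#' run; the default seven-path trajectory visits about 1500 at the default
#' 442 px / 21.4 cm resolution.
#'
#' @param paths A `trajectory`, or a list of objects with `start`/`end`
#'   fields in degrees (a zero-length path counts one pixel).
#' @inheritParams deg_to_cm
#' @return Integer count of distinct pixel cells.
#' @export
path_pixel_count <- function(paths, geom = screen_geometry()) {
  if (length(paths) == 0) stop("at least one path is required")
  if (!is.null(paths$start)) paths <- list(paths)
  pp <- geom$px_per_cm
  nx <- max(1L, round(geom$screen_width_cm * pp))
  ny <- max(1L, round(geom$screen_height_cm * pp))
  cells <- integer(0)
  for (p in paths) {
    ends <- deg_to_cm(rbind(p$start, p$end), geom)
    len <- sqrt(sum((ends[2, ] - ends[1, ])^2))
    n <- max(2L, ceiling(len * pp * 4) + 1L)
    t <- seq(0, 1, length.out = n)
    x <- ends[1, 1] + t * (ends[2, 1] - ends[1, 1]) + geom$fixation_x_cm
    y <- ends[1, 2] + t * (ends[2, 2] - ends[1, 2]) + geom$fixation_y_cm
    ix <- pmin(pmax(floor(x * pp), 0), nx - 1L)
    iy <- pmin(pmax(floor(y * pp), 0), ny - 1L)
    cells <- c(cells, unique(ix + nx * iy))
  }
  length(unique(cells))
}

# Position along a path at arc length s (cm), returned in degrees.
# Internal; vectorised over s.
path_point_deg <- function(path, s_cm, geom) {
  ends <- deg_to_cm(rbind(path$start, path$end), geom)
  len <- sqrt(sum((ends[2, ] - ends[1, ])^2))
  u <- if (len > 0) pmin(pmax(s_cm / len, 0), 1) else rep(0, length(s_cm))
  cm_to_deg(cbind(ends[1, 1] + u * (ends[2, 1] - ends[1, 1]),
                  ends[1, 2] + u * (ends[2, 2] - ends[1, 2])), geom)
}
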