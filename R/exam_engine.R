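# Exam engine: runs the screening trajectory and the slow delineation mode
# against a ground-truth field and a simulated observer, reconstructing
# scotoma segments from off/on events.

FRAME_EPS <- 1e-12

# Frame-by-frame execution of one path. The dot centre advances by
# speed/frame_rate cm per frame along the straight screen path; the dot
# diameter is re-evaluated every frame from the current eccentricity.
run_single_path <- function(field, observer, path, geom, spec, t0 = 0,
                            min_invisible_frames = 1) {
  ends <- deg_to_cm(rbind(path$start, path$end), geom)
  L <- sqrt(sum((ends[2, ] - ends[1, ])^2))
  v <- spec$speed_cm_s / path$speed_divisor
  dt <- 1 / geom$frame_rate_hz
  K <- max(1L, ceiling(L / (v * dt) - FRAME_EPS))
  s <- pmin((0:K) * v * dt, L)
  u <- s / L
  x_cm <- ends[1, 1] + u * (ends[2, 1] - ends[1, 1])
  y_cm <- ends[1, 2] + u * (ends[2, 2] - ends[1, 2])
  pdeg <- cm_to_deg(cbind(x_cm, y_cm), geom)
  ecc <- eccentricity_deg(pdeg)
  dmm <- dot_diameter_mm(ecc, spec)
  ddeg <- angular_diameter_deg(dmm, geom)
  vis <- stimulus_visible(field, observer, pdeg, ddeg)
  vis <- suppress_short_invisible(vis, min_invisible_frames)
  t <- t0 + (0:K) * dt
  ev <- respond(vis, t, observer, seed = NA)
  frames <- data.frame(path = path$label, frame = 0:K, t_s = t,
                       x_deg = pdeg[, 1], y_deg = pdeg[, 2],
                       diameter_mm = dmm, diameter_deg = ddeg,
                       visible = vis, stringsAsFactors = FALSE)
  if (nrow(ev) > 0) {
    s_resp <- pmin(s[ev$frame] + ev$latency_s * v, L)
    u_r <- s_resp / L
    pr <- cm_to_deg(cbind(ends[1, 1] + u_r * (ends[2, 1] - ends[1, 1]),
                          ends[1, 2] + u_r * (ends[2, 2] - ends[1, 2])), geom)
    events <- data.frame(path = path$label, frame = ev$frame,
                         event = ev$event, t_s = ev$t_response_s,
                         latency_s = ev$latency_s, x_deg = pr[, 1],
                         y_deg = pr[, 2], s_cm = s_resp,
                         stringsAsFactors = FALSE)
  } else {
    events <- empty_events_df()
  }
  list(frames = frames, events = events, K = K, L = L, v = v,
       duration_s = L / v, t_next = t0 + (K + 1) * dt)
}

suppress_short_invisible <- function(vis, min_frames) {
  if (min_frames <= 1) return(vis)
  r <- rle(vis)
  r$values[!r$values & r$lengths < min_frames] <- TRUE
  inverse.rle(r)
}

# Per-path timing/geometry table shared by the engine and pair_events.
path_frame_meta <- function(trajectory, geom, spec) {
  dt <- 1 / geom$frame_rate_hz
  t0 <- 0
  rows <- lapply(trajectory, function(p) {
    L <- path_length_cm(p, geom)
    v <- spec$speed_cm_s / p$speed_divisor
    K <- max(1L, ceiling(L / (v * dt) - FRAME_EPS))
    row <- data.frame(path = p$label, length_cm = L, speed_cm_s = v,
                      n_frames = K + 1L, t0_s = t0, t_end_s = t0 + K * dt,
                      start_x = p$start[1], start_y = p$start[2],
                      end_x = p$end[1], end_y = p$end[2],
                      stringsAsFactors = FALSE)
    t0 <<- t0 + (K + 1L) * dt
    row
  })
  do.call(rbind, rows)
}

#' Run the screening exam
#'
#' Executes the trajectory frame by frame at the display frame rate: the
#' dot centre advances by `speed / frame_rate` cm per frame along each
#' straight screen path, its diameter is re-evaluated every frame from the
#' current eccentricity, the observer converts visibility transitions into
#' timed off/on events, and [pair_events()] joins them into scotoma
#' segments. On a clean field the only segment lies on the blind-spot
#' line; the seven central paths complete in under 30 s at 3 cm/s.
#'
#' @param field A [visual_field()].
#' @param observer An [observer_params()].
#' @param trajectory A `trajectory`; defaults to the standard screening
#'   layout for `geom`.
#' @inheritParams deg_to_cm
#' @param spec A [stimulus_spec()].
#' @param min_invisible_frames Minimum invisible run length (in frames)
#'   that registers as a disappearance. The default 1 keeps every sampled
#'   invisible frame: the narrowest clinically relevant bands are fully
#'   contained for only about one frame at screening speed, and the
#'   geometric observer produces no rasterisation flicker that would need
#'   suppressing.
#' @return An object of class `exam_record` with elements `frames`
#'   (per-frame trace), `events`, `segments`, durations, and full
#'   configuration provenance.
#' @examples
#' exam <- run_screening(make_preset_field("clean"), observer_params())
#' exam$segments$path # only the blind-spot line
#' @export
run_screening <- function(field, observer = observer_params(),
                          trajectory = NULL, geom = screen_geometry(),
                          spec = stimulus_spec(),
                          min_invisible_frames = 1) {
  if (!inherits(field, "visual_field")) stop("field must be a visual_field")
  if (is.null(trajectory)) trajectory <- build_screening_trajectory(geom)
  traj_eye <- attr(trajectory, "eye")
  if (!is.null(traj_eye) && traj_eye != field$eye) {
    stop("field and trajectory were built for different eyes")
  }
  check_trajectory_on_screen(trajectory, geom)
  if (observer_is_stochastic(observer)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(observer$rng_seed)
  }
  t0 <- 0
  frames <- list(); events <- list(); durations <- numeric(0)
  for (p in trajectory) {
    res <- run_single_path(field, observer, p, geom, spec, t0,
                           min_invisible_frames)
    frames[[p$label]] <- res$frames
    events[[p$label]] <- res$events
    durations[p$label] <- res$duration_s
    t0 <- res$t_next
  }
  frames <- do.call(rbind, c(frames, make.row.names = FALSE))
  events <- do.call(rbind, c(events, make.row.names = FALSE))
  meta <- path_frame_meta(trajectory, geom, spec)
  segments <- pair_events_meta(events, meta)
  central <- names(durations) != "blind_spot_line"
  structure(list(schema_version = "1.0",
                 geometry = geom, stimulus = spec, observer = observer,
                 trajectory = trajectory,
                 field_signature = field_signature(field),
                 frames = frames, events = events, segments = segments,
                 duration_s = sum(durations),
                 duration_central_s = sum(durations[central])),
            class = "exam_record")
}

#' @export
print.exam_record <- function(x, ...) {
  cat("Campimetry exam record\n")
  cat(sprintf("  %d paths, %d frames, %.1f s total (%.1f s central paths)\n",
              length(x$trajectory), nrow(x$frames), x$duration_s,
              x$duration_central_s))
  cat(sprintf("  %d events, %d scotoma segment(s)\n",
              nrow(x$events), nrow(x$segments)))
  if (nrow(x$segments) > 0) {
    print(x$segments[, c("path", "x_off_deg", "y_off_deg",
                         "x_on_deg", "y_on_deg")], row.names = FALSE)
  }
  invisible(x)
}

empty_segments_df <- function() {
  data.frame(path = character(0), t_off_s = numeric(0),
             x_off_deg = numeric(0), y_off_deg = numeric(0),
             t_on_s = numeric(0), x_on_deg = numeric(0),
             y_on_deg = numeric(0), opened_at_start = logical(0),
             closed_at_end = logical(0), stringsAsFactors = FALSE)
}

pair_events_meta <- function(events, meta) {
  if (is.null(events) || nrow(events) == 0) return(empty_segments_df())
  out <- list()
  for (lab in unique(events$path)) {
    ev <- events[events$path == lab, ]
    ev <- ev[order(ev$frame), ]
    m <- meta[meta$path == lab, ]
    if (nrow(m) != 1) stop(sprintf("events refer to unknown path '%s'", lab))
    open <- NULL
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      if (e$event == "off") {
        if (!is.null(open)) {
          stop(sprintf("malformed event stream: two consecutive off events on path '%s'",
                       lab))
        }
        open <- e
      } else {
        if (is.null(open)) {
          # unmatched on: the dot was invisible from the path start
          open <- data.frame(t_s = m$t0_s, x_deg = m$start_x,
                             y_deg = m$start_y, stringsAsFactors = FALSE)
          open$at_bound <- TRUE
        }
        out[[length(out) + 1]] <- data.frame(
          path = lab, t_off_s = open$t_s, x_off_deg = open$x_deg,
          y_off_deg = open$y_deg, t_on_s = e$t_s, x_on_deg = e$x_deg,
          y_on_deg = e$y_deg,
          opened_at_start = isTRUE(open$at_bound), closed_at_end = FALSE,
          stringsAsFactors = FALSE)
        open <- NULL
      }
    }
    if (!is.null(open)) {
      out[[length(out) + 1]] <- data.frame(
        path = lab, t_off_s = open$t_s, x_off_deg = open$x_deg,
        y_off_deg = open$y_deg, t_on_s = m$t_end_s, x_on_deg = m$end_x,
        y_on_deg = m$end_y, opened_at_start = isTRUE(open$at_bound),
        closed_at_end = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_segments_df())
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$t_off_s), , drop = FALSE]
}

#' Pair off/on events into scotoma segments
#'
#' Joins each `"off"` event with the next `"on"` event on the same path.
#' An off that never resolves closes at the path's endpoint; an on with no
#' preceding off opens at the path's start. Two consecutive off events on
#' one path signal a malformed stream and raise an error.
#'
#' @param events Event data frame with columns `path`, `frame`, `event`,
#'   `t_s`, `x_deg`, `y_deg` (as produced by [run_screening()]).
#' @param trajectory The `trajectory` the events were recorded on.
#' @inheritParams deg_to_cm
#' @param spec The [stimulus_spec()] used.
#' @return A data frame of segments (off point, on point, path label and
#'   boundary-closure flags).
#' @export
pair_events <- function(events, trajectory, geom = screen_geometry(),
                        spec = stimulus_spec()) {
  pair_events_meta(events, path_frame_meta(trajectory, geom, spec))
}

#' Analytic path-region scotoma segments
#'
#' Continuous-domain counterpart of the frame-sampled engine: for each
#' path, the arc-length interval over which the dot disc is fully
#' contained in absolute scotoma is located by dense scanning plus
#' bisection to sub-micron tolerance, independent of the frame rate and of
#' the observer. Used as the reference against which event positions are
#' validated (they must agree to within one frame step).
#'
#' @param field A [visual_field()].
#' @param trajectory A `trajectory`.
#' @param spec A [stimulus_spec()].
#' @inheritParams deg_to_cm
#' @param scan_step_cm Scan step locating containment intervals.
#' @param tol_cm Bisection tolerance.
#' @return A segments data frame in the format of [run_screening()].
#' @export
analytic_segments <- function(field, trajectory, spec = stimulus_spec(),
                              geom = screen_geometry(),
                              scan_step_cm = 0.01, tol_cm = 1e-7) {
  meta <- path_frame_meta(trajectory, geom, spec)
  out <- list()
  for (p in trajectory) {
    m <- meta[meta$path == p$label, ]
    L <- m$length_cm; v <- m$speed_cm_s
    contained <- function(s) {
      pd <- path_point_deg(p, s, geom)
      dd <- dot_diameter_deg(eccentricity_deg(pd), spec, geom)
      disc_coverage_fractions(field, pd[, 1], pd[, 2], dd, "absolute") >=
        1 - 1e-12
    }
    sgrid <- unique(c(seq(0, L, by = scan_step_cm), L))
    cv <- contained(sgrid)
    i <- 1
    while (i <= length(sgrid)) {
      if (!cv[i]) { i <- i + 1; next }
      # containment starts at or before sgrid[i]
      s_off <- if (i == 1) 0 else
        bisect_edge(contained, sgrid[i - 1], sgrid[i], tol_cm)
      j <- i
      while (j <= length(sgrid) && cv[j]) j <- j + 1
      s_on <- if (j > length(sgrid)) L else
        bisect_edge(contained, sgrid[j - 1], sgrid[j], tol_cm)
      po <- path_point_deg(p, s_off, geom)
      pn <- path_point_deg(p, s_on, geom)
      out[[length(out) + 1]] <- data.frame(
        path = p$label, t_off_s = m$t0_s + s_off / v,
        x_off_deg = po[1, 1], y_off_deg = po[1, 2],
        t_on_s = m$t0_s + s_on / v, x_on_deg = pn[1, 1], y_on_deg = pn[1, 2],
        opened_at_start = i == 1, closed_at_end = j > length(sgrid),
        stringsAsFactors = FALSE)
      i <- j
    }
  }
  if (length(out) == 0) return(empty_segments_df())
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Locate the boundary between f(a) and f(b) (f logical, f(a) != f(b)).
bisect_edge <- function(f, a, b, tol) {
  fa <- f(a)
  while (b - a > tol) {
    mid <- (a + b) / 2
    if (identical(f(mid), fa)) a <- mid else b <- mid
  }
  (a + b) / 2
}

#' Delineate a scotoma by slow kinetic sweeps
#'
#' Reproduces scotoma-delineation campimetry: around a screening segment,
#' the dot is swept vertically at `speed / divisor` (divisor 4 or 8 in
#' practice) across a window padded by `pad_deg` on each side, and every
#' sweep contributes the off/on crossing points of the scotoma boundary.
#' The geometric boundary estimate corrects each crossing by the local dot
#' radius (the dot disappears only once fully inside), and the recovered
#' band width per sweep is `(y_on - y_off) + dot diameter`. Slower sweeps
#' shrink both the frame-quantisation error and the latency displacement
#' `latency * speed / divisor`, which is the rationale for slowing the
#' automatic movement during delineation.
#'
#' @param field A [visual_field()].
#' @param observer An [observer_params()].
#' @param segment One row of an exam's `segments` data frame (or an
#'   equivalent list).
#' @inheritParams deg_to_cm
#' @param spec A [stimulus_spec()].
#' @param divisor Speed divisor (>= 1; 4 or 8 in practice).
#' @param sweep_step_deg Horizontal spacing of the vertical sweeps.
#' @param pad_deg Padding of the sweep window around the segment.
#' @param min_invisible_frames See [run_screening()].
#' @return An object of class `delineation_result`: `crossings` (one row
#'   per boundary crossing), `outline` (closed polygon of boundary
#'   estimates, or `NULL`), `recovered_width_deg`, and the sweep
#'   configuration.
#' @export
run_delineation <- function(field, observer = observer_params(), segment,
                            geom = screen_geometry(), spec = stimulus_spec(),
                            divisor = 8, sweep_step_deg = 0.5, pad_deg = 2,
                            min_invisible_frames = 1) {
  if (divisor < 1) stop("divisor must be at least 1")
  if (sweep_step_deg <= 0) stop("sweep_step_deg must be positive")
  segment <- as.list(segment)
  need <- c("x_off_deg", "y_off_deg", "x_on_deg", "y_on_deg")
  if (!all(need %in% names(segment)) ||
      !all(vapply(segment[need], function(v) is.numeric(v) && is.finite(v),
                  logical(1)))) {
    stop("segment must carry finite off/on coordinates (a row of exam$segments)")
  }
  xw <- range(segment$x_off_deg, segment$x_on_deg) + c(-pad_deg, pad_deg)
  yw <- range(segment$y_off_deg, segment$y_on_deg) + c(-pad_deg, pad_deg)
  b <- screen_bounds_cm(geom)
  bd <- cm_to_deg(rbind(c(b$x[1], b$y[1]), c(b$x[2], b$y[2])), geom)
  xw <- pmin(pmax(xw, bd[1, 1]), bd[2, 1])
  yw <- pmin(pmax(yw, bd[1, 2]), bd[2, 2])
  sweep_x <- seq(xw[1], xw[2], by = sweep_step_deg)
  if (observer_is_stochastic(observer)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(observer$rng_seed)
  }
  crossings <- list()
  for (x in sweep_x) {
    path <- path_spec(sprintf("sweep_x_%.3f", x), c(x, yw[1]), c(x, yw[2]),
                      speed_divisor = divisor)
    res <- run_single_path(field, observer, path, geom, spec, 0,
                           min_invisible_frames)
    meta <- data.frame(path = path$label, t0_s = 0,
                       t_end_s = res$K / geom$frame_rate_hz,
                       start_x = x, start_y = yw[1], end_x = x, end_y = yw[2],
                       stringsAsFactors = FALSE)
    segs <- pair_events_meta(res$events, meta)
    if (nrow(segs) == 0) next
    mid_ecc <- eccentricity_deg(cbind(segs$x_off_deg + segs$x_on_deg,
                                      segs$y_off_deg + segs$y_on_deg) / 2)
    dot <- dot_diameter_deg(mid_ecc, spec, geom)
    crossings[[length(crossings) + 1]] <- data.frame(
      sweep_x_deg = x, y_off_deg = segs$y_off_deg, y_on_deg = segs$y_on_deg,
      dot_deg = dot,
      width_est_deg = segs$y_on_deg - segs$y_off_deg + dot,
      clipped = segs$opened_at_start | segs$closed_at_end,
      stringsAsFactors = FALSE)
  }
  crossings <- if (length(crossings)) {
    do.call(rbind, c(crossings, make.row.names = FALSE))
  } else {
    data.frame(sweep_x_deg = numeric(0), y_off_deg = numeric(0),
               y_on_deg = numeric(0), dot_deg = numeric(0),
               width_est_deg = numeric(0), clipped = logical(0),
               stringsAsFactors = FALSE)
  }
  ok <- crossings[!crossings$clipped, , drop = FALSE]
  outline <- NULL
  if (nrow(ok) > 0) {
    lower <- cbind(x_deg = ok$sweep_x_deg, y_deg = ok$y_off_deg - ok$dot_deg / 2)
    upper <- cbind(x_deg = ok$sweep_x_deg, y_deg = ok$y_on_deg + ok$dot_deg / 2)
    outline <- rbind(lower, upper[rev(seq_len(nrow(upper))), , drop = FALSE])
    outline <- rbind(outline, outline[1, ])
  }
  structure(list(segment = segment, crossings = crossings, outline = outline,
                 divisor = as.integer(divisor),
                 sweep_step_deg = sweep_step_deg,
                 window = list(x_deg = xw, y_deg = yw),
                 recovered_width_deg = if (nrow(ok)) mean(ok$width_est_deg)
                                       else NA_real_),
            class = "delineation_result")
}

#' @export
print.delineation_result <- function(x, ...) {
  cat(sprintf("Scotoma delineation (divisor %d, %d crossing(s))\n",
              x$divisor, nrow(x$crossings)))
  if (!is.na(x$recovered_width_deg)) {
    cat(sprintf("  recovered band width: %.3f deg\n", x$recovered_width_deg))
  }
  invisible(x)
}

#' Mean boundary error of a delineation
#'
#' Mean distance (in degrees) from the delineation's dot-radius-corrected
#' boundary estimates to the true boundary polyline of a ground-truth
#' region. Grows with response latency times sweep speed, and shrinks as
#' the speed divisor increases.
#'
#' @param delineation A `delineation_result`.
#' @param field The ground-truth [visual_field()].
#' @param region_index Region index as in [region_boundary_polyline()].
#' @param resolution_deg Resolution of the reference polyline.
#' @return Mean distance in degrees (`NA` if there are no crossings).
#' @export
delineation_boundary_error <- function(delineation, field, region_index,
                                       resolution_deg = 0.02) {
  ok <- delineation$crossings[!delineation$crossings$clipped, , drop = FALSE]
  if (nrow(ok) == 0) return(NA_real_)
  poly <- region_boundary_polyline(field, region_index, resolution_deg)
  px <- c(ok$sweep_x_deg, ok$sweep_x_deg)
  py <- c(ok$y_off_deg - ok$dot_deg / 2, ok$y_on_deg + ok$dot_deg / 2)
  mean(polyline_min_distance(px, py, poly))
}
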