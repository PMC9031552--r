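# Serialization (JSON/CSV), SVG rendering of exam results, and the
# deterministic fixture bundle. Degrees are the canonical unit in every
# file; screen centimetres appear only inside geometry computations.

SCHEMA_VERSION <- "1.0"

region_to_list <- function(rg) {
  base <- list(type = class(rg)[1], depth = rg$depth)
  if (!is.null(rg$attenuation_db)) base$attenuation_db <- rg$attenuation_db
  c(base, switch(class(rg)[1],
    blind_spot = list(center = rg$center, semi_axes_deg = rg$semi_axes_deg),
    arcuate_scotoma = list(arc_center = rg$arc_center,
                           arc_radius_deg = rg$arc_radius_deg,
                           angular_span_deg = rg$angular_span_deg,
                           width_deg = rg$width_deg),
    wedge_scotoma = list(apex = rg$apex, sector_deg = rg$sector_deg,
                         radial_deg = rg$radial_deg),
    stop("unknown region type")))
}

region_from_list <- function(l) {
  att <- l$attenuation_db
  switch(l$type,
    blind_spot = blind_spot(l$center, l$semi_axes_deg),
    arcuate_scotoma = arcuate_scotoma(l$arc_center, l$arc_radius_deg,
                                      l$angular_span_deg, l$width_deg,
                                      depth = l$depth, attenuation_db = att),
    wedge_scotoma = wedge_scotoma(l$apex, l$sector_deg, l$radial_deg,
                                  depth = l$depth, attenuation_db = att),
    stop("unknown region type in file"))
}

field_to_list <- function(field) {
  list(schema_version = SCHEMA_VERSION, eye = field$eye,
       blind_spot = region_to_list(field$blind_spot),
       scotomas = lapply(field$scotomas, region_to_list))
}

check_schema <- function(l, what) {
  if (is.null(l$schema_version)) {
    stop(sprintf("not a %s file: missing schema_version", what))
  }
  if (!identical(as.character(l$schema_version), SCHEMA_VERSION)) {
    stop(sprintf("unsupported %s schema version '%s' (supported: %s)",
                 what, l$schema_version, SCHEMA_VERSION))
  }
}

#' Deterministic signature of a visual field
#'
#' A content string over the field's serialised parameters, used to check
#' that exams being compared were run on the same ground truth.
#'
#' @param field A [visual_field()].
#' @return A single character string.
#' @export
field_signature <- function(field) {
  as.character(jsonlite::toJSON(field_to_list(field), auto_unbox = TRUE,
                                digits = 10))
}

#' Write / read a visual field as JSON
#'
#' Fields round-trip losslessly through a small versioned JSON schema
#' (eye, blind spot, typed scotoma list) with degrees as the only unit.
#'
#' @param field A [visual_field()].
#' @param path File path.
#' @return `write_field_json` returns `path` invisibly; `read_field_json`
#'   returns the reconstructed [visual_field()].
#' @export
write_field_json <- function(field, path) {
  jsonlite::write_json(field_to_list(field), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_field_json
#' @export
read_field_json <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  check_schema(l, "visual field")
  visual_field(eye = l$eye, blind_spot = region_from_list(l$blind_spot),
               scotomas = lapply(l$scotomas, region_from_list))
}

df_or_empty <- function(x, template) {
  if (is.data.frame(x) && nrow(x) > 0) {
    for (nm in names(template)) storage.mode(x[[nm]]) <- storage.mode(template[[nm]])
    x[, names(template), drop = FALSE]
  } else {
    template
  }
}

#' Write / read an exam record as JSON
#'
#' Serialises the full exam record (configuration provenance, per-frame
#' trace, events and segments) under a versioned schema; reading an
#' unknown version raises an error.
#'
#' @param exam An `exam_record` from [run_screening()].
#' @param path File path.
#' @return `write_exam_json` returns `path` invisibly; `read_exam_json`
#'   the reconstructed `exam_record`.
#' @export
write_exam_json <- function(exam, path) {
  traj <- lapply(exam$trajectory, function(p) {
    list(label = p$label, start = p$start, end = p$end,
         speed_divisor = p$speed_divisor)
  })
  out <- list(schema_version = exam$schema_version,
              geometry = unclass(exam$geometry),
              stimulus = unclass(exam$stimulus),
              observer = unclass(exam$observer),
              trajectory = traj,
              trajectory_eye = attr(exam$trajectory, "eye") %||% NA,
              field_signature = exam$field_signature,
              frames = exam$frames, events = exam$events,
              segments = exam$segments,
              duration_s = exam$duration_s,
              duration_central_s = exam$duration_central_s)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_exam_json
#' @export
read_exam_json <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(l, "exam record")
  geom <- do.call(screen_geometry, l$geometry)
  spec <- do.call(stimulus_spec, l$stimulus)
  obs <- do.call(observer_params, l$observer)
  tr <- l$trajectory  # simplifies to a row-wise data frame with list columns
  paths <- if (is.data.frame(tr)) {
    lapply(seq_len(nrow(tr)), function(i) {
      path_spec(tr$label[i], unlist(tr$start[i]), unlist(tr$end[i]),
                tr$speed_divisor[i])
    })
  } else {
    lapply(tr, function(p) path_spec(p$label, p$start, p$end, p$speed_divisor))
  }
  eye <- l$trajectory_eye
  if (!is.character(eye) || length(eye) != 1 || is.na(eye)) eye <- NULL
  traj <- structure(paths, class = "trajectory")
  if (!is.null(eye)) attr(traj, "eye") <- eye
  frames <- as.data.frame(l$frames, stringsAsFactors = FALSE)
  events <- df_or_empty(as.data.frame(l$events, stringsAsFactors = FALSE),
                        empty_events_df())
  segments <- df_or_empty(as.data.frame(l$segments, stringsAsFactors = FALSE),
                          empty_segments_df())
  structure(list(schema_version = as.character(l$schema_version),
                 geometry = geom, stimulus = spec, observer = obs,
                 trajectory = traj, field_signature = l$field_signature,
                 frames = frames, events = events, segments = segments,
                 duration_s = l$duration_s,
                 duration_central_s = l$duration_central_s),
            class = "exam_record")
}

empty_events_df <- function() {
  data.frame(path = character(0), frame = integer(0), event = character(0),
             t_s = numeric(0), latency_s = numeric(0), x_deg = numeric(0),
             y_deg = numeric(0), s_cm = numeric(0), stringsAsFactors = FALSE)
}

#' Export exam events as CSV
#'
#' One row per off/on event: frame, time, position in degrees and event
#' type. Comma separator, dot decimal, header row.
#'
#' @param exam An `exam_record`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(exam, path) {
  ev <- exam$events[, c("frame", "t_s", "x_deg", "y_deg", "event")]
  names(ev) <- c("frame", "time_s", "x_deg", "y_deg", "event")
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' Export a coverage report as CSV
#'
#' Columns `label`, `thickest_cm`, `thinnest_cm`, `sum_cm`, `half_run_cm`,
#' `area_cm2`, mirroring the per-path area table of the method.
#'
#' @param report A `coverage_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_coverage_csv <- function(report, path) {
  r <- report$rows
  out <- data.frame(label = r$label, thickest_cm = r$thickest_cm,
                    thinnest_cm = r$thinnest_cm,
                    sum_cm = r$thickest_cm + r$thinnest_cm,
                    half_run_cm = r$half_run_cm, area_cm2 = r$area_cm2)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

svg_num <- function(x) sprintf("%.6f", x)

#' Render an exam record as SVG
#'
#' Draws the result the examiner sees: dashed trajectory polylines, a
#' fixation cross, red off dots and green on dots connected by grey
#' scotoma segments, and (when the ground-truth field is supplied) the
#' blind-spot ellipse and scotoma outlines. Coordinates are visual-field
#' degrees scaled by `px_per_deg` with the y axis pointing up; the SVG is
#' deterministic for a given record, so exact coordinates can be parsed
#' back from the file.
#'
#' @param exam An `exam_record`.
#' @param path Output file path.
#' @param field Optional ground-truth [visual_field()] overlay.
#' @param px_per_deg Rendering scale.
#' @return `path`, invisibly.
#' @export
render_exam_svg <- function(exam, path, field = NULL, px_per_deg = 20) {
  ext <- lapply(exam$trajectory, function(p) rbind(p$start, p$end))
  ext <- do.call(rbind, ext)
  xr <- range(ext[, 1]) + c(-2, 2)
  yr <- range(ext[, 2]) + c(-2, 2)
  s <- px_per_deg
  tx <- function(x) (x - xr[1]) * s
  ty <- function(y) (yr[2] - y) * s
  w <- (xr[2] - xr[1]) * s; h <- (yr[2] - yr[1]) * s
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s" data-px-per-deg="%s" data-x-min-deg="%s" data-y-max-deg="%s">',
    svg_num(w), svg_num(h), svg_num(w), svg_num(h), svg_num(s),
    svg_num(xr[1]), svg_num(yr[2])),
    sprintf('<rect width="%s" height="%s" fill="black"/>', svg_num(w), svg_num(h)))
  if (!is.null(field)) {
    regions <- field_regions(field)
    for (i in seq_along(regions)) {
      poly <- region_boundary(regions[[i]], 0.05)
      pts <- paste(svg_num(tx(poly[, 1])), svg_num(ty(poly[, 2])),
                   sep = ",", collapse = " ")
      cls <- if (i == 1) "blind-spot" else "region"
      col <- if (regions[[i]]$depth == "absolute") "#666666" else "#444444"
      lines <- c(lines, sprintf(
        '<polygon class="%s" points="%s" fill="none" stroke="%s" stroke-width="1"/>',
        cls, pts, col))
    }
  }
  for (p in exam$trajectory) {
    lines <- c(lines, sprintf(
      '<line class="trajectory" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#cccccc" stroke-width="0.5" stroke-dasharray="4,3"/>',
      svg_num(tx(p$start[1])), svg_num(ty(p$start[2])),
      svg_num(tx(p$end[1])), svg_num(ty(p$end[2]))))
  }
  fx <- tx(0); fy <- ty(0); fr <- exam$stimulus$fixation_diameter_deg / 2 * s
  lines <- c(lines, sprintf(
    '<line class="fixation" x1="%s" y1="%s" x2="%s" y2="%s" stroke="white" stroke-width="1"/>',
    svg_num(fx - fr), svg_num(fy), svg_num(fx + fr), svg_num(fy)),
    sprintf(
    '<line class="fixation" x1="%s" y1="%s" x2="%s" y2="%s" stroke="white" stroke-width="1"/>',
    svg_num(fx), svg_num(fy - fr), svg_num(fx), svg_num(fy + fr)))
  segs <- exam$segments
  for (i in seq_len(nrow(segs))) {
    g <- segs[i, ]
    lines <- c(lines, sprintf(
      '<line class="segment" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#999999" stroke-width="2"/>',
      svg_num(tx(g$x_off_deg)), svg_num(ty(g$y_off_deg)),
      svg_num(tx(g$x_on_deg)), svg_num(ty(g$y_on_deg))))
  }
  for (i in seq_len(nrow(segs))) {
    g <- segs[i, ]
    lines <- c(lines, sprintf(
      '<circle class="off" cx="%s" cy="%s" r="3" fill="red"/>',
      svg_num(tx(g$x_off_deg)), svg_num(ty(g$y_off_deg))),
      sprintf(
      '<circle class="on" cx="%s" cy="%s" r="3" fill="green"/>',
      svg_num(tx(g$x_on_deg)), svg_num(ty(g$y_on_deg))))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic fixture bundle for testing
#'
#' One fixture per field preset, each carrying the ground-truth field, a
#' noise-free observer, the default trajectory and its own oracle: the
#' analytic path-region containment segments from [analytic_segments()],
#' against which engine output can be checked. Identical seeds give
#' identical bundles.
#'
#' @param seed Integer seed recorded in the bundle and used for the
#'   observers' RNG streams.
#' @return A named list of fixtures with class `fixture_suite`.
#' @export
fixture_suite <- function(seed = 0) {
  geom <- screen_geometry()
  spec <- stimulus_spec()
  traj <- build_screening_trajectory(geom)
  presets <- c("clean", "narrow_arcuate_035", "superior_arcuate",
               "inferior_arcuate", "quadrant_superior")
  fixtures <- lapply(presets, function(ps) {
    field <- make_preset_field(ps)
    list(preset = ps, field = field,
         observer = observer_params(rng_seed = seed),
         trajectory = traj, geometry = geom, stimulus = spec,
         expected_segments = analytic_segments(field, traj, spec, geom))
  })
  names(fixtures) <- presets
  structure(list(seed = as.integer(seed), fixtures = fixtures),
            class = "fixture_suite")
}
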