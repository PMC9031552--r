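# Synthetic ground-truth visual fields: the physiological blind spot plus
# parametric scotomas with absolute or relative depth.

DEPTHS <- c("normal", "relative", "absolute")

check_depth <- function(depth, attenuation_db) {
  depth <- match.arg(depth, c("absolute", "relative"))
  if (depth == "relative") {
    if (is.null(attenuation_db) || !is.finite(attenuation_db) ||
        attenuation_db <= 0) {
      stop("a relative scotoma requires a positive attenuation_db")
    }
  } else if (!is.null(attenuation_db)) {
    stop("attenuation_db only applies to relative scotomas")
  }
  depth
}

#' The physiological blind spot
#'
#' Modelled as an elliptical absolute scotoma at the optic-nerve head,
#' about 15 degrees temporal and slightly below the horizontal meridian.
#' Coordinates follow the temporal-positive-x convention of the tested eye.
#'
#' @param center Centre `c(x_deg, y_deg)`; `x` must lie between 10 and 20
#'   degrees temporal.
#' @param semi_axes_deg Horizontal and vertical semi-axes in degrees.
#' @return A `blind_spot` region.
#' @export
blind_spot <- function(center = c(15, -1.5), semi_axes_deg = c(2.75, 3.75)) {
  center <- as.numeric(center)
  if (center[1] < 10 || center[1] > 20) {
    stop("the blind spot centre must lie between 10 and 20 degrees temporal")
  }
  if (any(semi_axes_deg <= 0)) stop("semi-axes must be positive")
  structure(list(center = center, semi_axes_deg = as.numeric(semi_axes_deg),
                 depth = "absolute", attenuation_db = NULL),
            class = c("blind_spot", "field_region"))
}

#' Arcuate (nerve-fibre-bundle) scotoma
#'
#' A band of constant width around a circular arc, the geometric idealisation
#' of a Bjerrum-area defect: glaucomatous damage to one retinal nerve-fibre
#' bundle silences an arc running from the blind spot around fixation. A
#' point lies in the band when its distance from `arc_center` is within
#' `width_deg/2` of `arc_radius_deg` and its polar angle about `arc_center`
#' falls inside `angular_span_deg`.
#'
#' @param arc_center Centre of the generating arc, `c(x_deg, y_deg)`.
#' @param arc_radius_deg Radius of the generating arc in degrees.
#' @param angular_span_deg Arc extent `c(start, end)` in degrees
#'   (counter-clockwise from the +x direction; span below 360).
#' @param width_deg Band width, measured perpendicular to the arc.
#' @param depth `"absolute"` or `"relative"`.
#' @param attenuation_db Sensitivity loss in dB; required iff relative.
#' @return An `arcuate_scotoma` region.
#' @export
arcuate_scotoma <- function(arc_center, arc_radius_deg, angular_span_deg,
                            width_deg, depth = "absolute",
                            attenuation_db = NULL) {
  depth <- check_depth(depth, attenuation_db)
  if (width_deg <= 0) stop("width_deg must be positive")
  if (arc_radius_deg <= width_deg / 2) {
    stop("arc_radius_deg must exceed half the band width")
  }
  span <- as.numeric(angular_span_deg)
  if (length(span) != 2 || span[2] <= span[1] || span[2] - span[1] >= 360) {
    stop("angular_span_deg must be an increasing pair spanning less than 360")
  }
  structure(list(arc_center = as.numeric(arc_center),
                 arc_radius_deg = arc_radius_deg,
                 angular_span_deg = span, width_deg = width_deg,
                 depth = depth, attenuation_db = attenuation_db),
            class = c("arcuate_scotoma", "field_region"))
}

#' Wedge (quadrant) scotoma
#'
#' An annular sector: points whose distance from `apex` lies in
#' `radial_deg` and whose polar angle about `apex` lies in `sector_deg`.
#'
#' @param apex Sector apex `c(x_deg, y_deg)`.
#' @param sector_deg Angular sector `c(start, end)` in degrees.
#' @param radial_deg Radial extent `c(inner, outer)`, `outer > inner >= 0`.
#' @inheritParams arcuate_scotoma
#' @return A `wedge_scotoma` region.
#' @export
wedge_scotoma <- function(apex = c(0, 0), sector_deg = c(0, 90),
                          radial_deg = c(1, 12), depth = "absolute",
                          attenuation_db = NULL) {
  depth <- check_depth(depth, attenuation_db)
  radial <- as.numeric(radial_deg)
  if (radial[1] < 0 || radial[2] <= radial[1]) {
    stop("radial_deg must satisfy outer > inner >= 0")
  }
  sector <- as.numeric(sector_deg)
  if (sector[2] <= sector[1] || sector[2] - sector[1] >= 360) {
    stop("sector_deg must be an increasing pair spanning less than 360")
  }
  structure(list(apex = as.numeric(apex), sector_deg = sector,
                 radial_deg = radial, depth = depth,
                 attenuation_db = attenuation_db),
            class = c("wedge_scotoma", "field_region"))
}

#' Synthetic ground-truth visual field
#'
#' A blind spot plus an ordered list of scotoma regions on an otherwise
#' normal background. Classification is total and order-independent: every
#' point receives exactly one depth class, with the deepest class winning
#' on overlap (absolute > relative > normal).
#'
#' @param eye `"OD"` or `"OS"` (metadata; coordinates are always stored
#'   temporal-positive).
#' @param blind_spot A [blind_spot()] region; defaults to the standard one.
#' @param scotomas List of [arcuate_scotoma()] / [wedge_scotoma()] regions.
#' @return An object of class `visual_field`.
#' @export
visual_field <- function(eye = c("OD", "OS"), blind_spot = NULL,
                         scotomas = list()) {
  eye <- match.arg(eye)
  if (is.null(blind_spot)) blind_spot <- default_blind_spot()
  if (!inherits(blind_spot, "blind_spot")) {
    stop("blind_spot must be a blind_spot region")
  }
  if (!all(vapply(scotomas, inherits, logical(1), "field_region"))) {
    stop("scotomas must be field_region objects")
  }
  structure(list(eye = eye, blind_spot = blind_spot, scotomas = scotomas),
            class = "visual_field")
}

default_blind_spot <- function() blind_spot()

#' @export
print.visual_field <- function(x, ...) {
  cat(sprintf("Synthetic visual field (%s): blind spot at (%.1f, %.1f) deg",
              x$eye, x$blind_spot$center[1], x$blind_spot$center[2]))
  cat(sprintf(", %d scotoma(s)\n", length(x$scotomas)))
  for (s in x$scotomas) {
    cat(sprintf("  %s (%s)\n", class(s)[1], s$depth))
  }
  invisible(x)
}

#' All regions of a field, blind spot first
#'
#' @param field A [visual_field()].
#' @return A list of regions; index 1 is the blind spot.
#' @export
field_regions <- function(field) {
  c(list(field$blind_spot), field$scotomas)
}

#' Point-in-region test
#'
#' @param region A field region.
#' @param x_deg,y_deg Coordinate vectors in degrees.
#' @return Logical vector.
#' @export
region_contains <- function(region, x_deg, y_deg) {
  UseMethod("region_contains")
}

#' @export
region_contains.blind_spot <- function(region, x_deg, y_deg) {
  ((x_deg - region$center[1]) / region$semi_axes_deg[1])^2 +
    ((y_deg - region$center[2]) / region$semi_axes_deg[2])^2 <= 1
}

in_angular_span <- function(ang_deg, span) {
  ((ang_deg - span[1]) %% 360) <= (span[2] - span[1])
}

#' @export
region_contains.arcuate_scotoma <- function(region, x_deg, y_deg) {
  dx <- x_deg - region$arc_center[1]
  dy <- y_deg - region$arc_center[2]
  r <- sqrt(dx^2 + dy^2)
  ok_r <- abs(r - region$arc_radius_deg) <= region$width_deg / 2
  ang <- atan2(dy, dx) * 180 / pi
  ok_r & in_angular_span(ang, region$angular_span_deg)
}

#' @export
region_contains.wedge_scotoma <- function(region, x_deg, y_deg) {
  dx <- x_deg - region$apex[1]
  dy <- y_deg - region$apex[2]
  r <- sqrt(dx^2 + dy^2)
  ok_r <- r >= region$radial_deg[1] & r <= region$radial_deg[2]
  ang <- atan2(dy, dx) * 180 / pi
  ok_r & in_angular_span(ang, region$sector_deg)
}

#' Classify field points by depth
#'
#' @param field A [visual_field()].
#' @param x_deg,y_deg Coordinate vectors in degrees.
#' @return Character vector: `"normal"`, `"relative"` or `"absolute"`.
#' @export
classify_points <- function(field, x_deg, y_deg) {
  n <- length(x_deg)
  in_abs <- logical(n); in_rel <- logical(n)
  for (rg in field_regions(field)) {
    inside <- region_contains(rg, x_deg, y_deg)
    if (rg$depth == "absolute") in_abs <- in_abs | inside
    else in_rel <- in_rel | inside
  }
  ifelse(in_abs, "absolute", ifelse(in_rel, "relative", "normal"))
}

#' Classify a single field point (or point matrix)
#'
#' Ground-truth lookup with deepest-wins overlap resolution.
#'
#' @param field A [visual_field()].
#' @inheritParams deg_to_cm
#' @return Character vector of depth classes.
#' @examples
#' classify_point(make_preset_field("clean"), c(15, -1.5)) # "absolute"
#' @export
classify_point <- function(field, p) {
  p <- as_field_points(p)
  classify_points(field, p[, 1], p[, 2])
}

# Deterministic polar sampling offsets on the unit disc: centre plus
# n_rings equal-area rings of n_spokes each. Cached after first use.
disc_sample_offsets <- local({
  cache <- list()
  function(n_rings = 16, n_spokes = 32) {
    key <- paste(n_rings, n_spokes)
    if (is.null(cache[[key]])) {
      radii <- sqrt((seq_len(n_rings) - 0.5) / n_rings)
      ang <- 2 * pi * (seq_len(n_spokes) - 1) / n_spokes
      cache[[key]] <<- rbind(c(0, 0),
                             cbind(rep(radii, each = n_spokes) *
                                     cos(rep(ang, n_rings)),
                                   rep(radii, each = n_spokes) *
                                     sin(rep(ang, n_rings))))
    }
    cache[[key]]
  }
})

#' Fraction of a test disc lying inside a depth class
#'
#' Fraction of the disc's area classified at least as deep as
#' `target_class`, computed on a fixed deterministic polar grid (16
#' equal-area rings of 32 spokes plus the centre, 513 samples), so all
#' downstream tests are seed-free. The fraction equals 1 exactly when
#' every sample is at least as deep as the target; for a disc of diameter
#' `d` centred in a straight absolute band of width `w` this reproduces
#' the containment law: fraction 1 iff `d <= w` (to sampler resolution,
#' about 1.6 percent of the radius).
#'
#' @param field A [visual_field()].
#' @param center Disc centre `c(x_deg, y_deg)`.
#' @param diameter_deg Disc diameter in degrees.
#' @param target_class `"absolute"` or `"relative"` (relative counts
#'   absolute as deeper).
#' @param n_rings,n_spokes Sampler resolution.
#' @return Fraction in `[0, 1]`.
#' @export
disc_coverage_fraction <- function(field, center, diameter_deg,
                                   target_class = "absolute",
                                   n_rings = 16, n_spokes = 32) {
  center <- as_field_points(center)
  disc_coverage_fractions(field, center[, 1], center[, 2], diameter_deg,
                          target_class, n_rings, n_spokes)
}

# Vectorised over many disc centres (and diameters). Internal workhorse of
# the observer and the static-grid simulator.
disc_coverage_fractions <- function(field, x_deg, y_deg, diameter_deg,
                                    target_class = "absolute",
                                    n_rings = 16, n_spokes = 32) {
  target_class <- match.arg(target_class, c("absolute", "relative"))
  if (any(diameter_deg <= 0)) stop("diameter must be positive")
  offs <- disc_sample_offsets(n_rings, n_spokes)
  m <- nrow(offs)
  n <- length(x_deg)
  r <- rep_len(diameter_deg / 2, n)
  X <- rep(x_deg, each = m) + rep(r, each = m) * offs[, 1]
  Y <- rep(y_deg, each = m) + rep(r, each = m) * offs[, 2]
  cls <- classify_points(field, X, Y)
  deep <- if (target_class == "absolute") cls == "absolute" else cls != "normal"
  colMeans(matrix(deep, nrow = m))
}

# Arc through the blind-spot centre with its own centre on the vertical
# meridian, reaching the given apex eccentricity on that meridian. Returns
# centre (0, -c) and radius c + apex for the superior hemifield.
nerve_fiber_arc <- function(bs_center = c(15, -1.5), apex_ecc_deg = 8) {
  bx <- bs_center[1]; by <- bs_center[2]
  if (apex_ecc_deg <= by) stop("apex eccentricity must exceed the blind-spot height")
  cc <- (bx^2 + by^2 - apex_ecc_deg^2) / (2 * (apex_ecc_deg - by))
  list(center = c(0, -cc), radius = cc + apex_ecc_deg,
       anchor_angle_deg = atan2(by + cc, bx) * 180 / pi)
}

#' Preset synthetic visual fields
#'
#' Named ground-truth fields emulating characteristic glaucomatous defects:
#' \describe{
#'   \item{`clean`}{Blind spot only.}
#'   \item{`narrow_arcuate_035`}{A 0.35-degree-wide absolute arcuate band
#'     following the nerve-fibre course: a circular arc anchored at the
#'     blind-spot centre whose apex crosses the superior Bjerrum region 8
#'     degrees above fixation. The band is wider than the kinetic test dot
#'     but narrower than a 0.43-degree static stimulus, the geometry behind
#'     the two methods' discordant depth classification.}
#'   \item{`superior_arcuate` / `inferior_arcuate`}{The same nerve-fibre
#'     arc with a configurable (default 2 degree) width, in the superior or
#'     inferior hemifield.}
#'   \item{`quadrant_superior`}{An absolute wedge over the superior
#'     temporal quadrant.}
#' }
#'
#' @param preset Preset name.
#' @param params Optional overrides: `width_deg`, `apex_ecc_deg`,
#'   `span_end_deg`, `depth`, `attenuation_db`, and for the wedge
#'   `sector_deg` / `radial_deg`.
#' @param eye `"OD"` or `"OS"`.
#' @return A [visual_field()].
#' @examples
#' make_preset_field("narrow_arcuate_035")
#' @export
make_preset_field <- function(preset = c("clean", "narrow_arcuate_035",
                                         "superior_arcuate",
                                         "inferior_arcuate",
                                         "quadrant_superior"),
                              params = list(), eye = "OD") {
  if (!is.character(preset) || length(preset) != 1 ||
      !preset %in% c("clean", "narrow_arcuate_035", "superior_arcuate",
                     "inferior_arcuate", "quadrant_superior")) {
    stop("unknown preset; see ?make_preset_field for the available names")
  }
  bs <- blind_spot()
  depth <- params$depth %||% "absolute"
  att <- params$attenuation_db
  apex <- params$apex_ecc_deg %||% 8
  span_end <- params$span_end_deg %||% 130
  sup_arc <- function(width) {
    arc <- nerve_fiber_arc(bs$center, apex)
    arcuate_scotoma(arc$center, arc$radius,
                    c(arc$anchor_angle_deg, span_end), width,
                    depth = depth, attenuation_db = att)
  }
  scot <- switch(preset,
    clean = list(),
    narrow_arcuate_035 = list(sup_arc(params$width_deg %||% 0.35)),
    superior_arcuate = list(sup_arc(params$width_deg %||% 2)),
    inferior_arcuate = {
      arc <- nerve_fiber_arc(bs$center * c(1, -1), apex)
      list(arcuate_scotoma(arc$center * c(1, -1), arc$radius,
                           c(-span_end, -arc$anchor_angle_deg),
                           params$width_deg %||% 2,
                           depth = depth, attenuation_db = att))
    },
    quadrant_superior = list(wedge_scotoma(
      apex = c(0, 0),
      sector_deg = params$sector_deg %||% c(0, 90),
      radial_deg = params$radial_deg %||% c(1, 12),
      depth = depth, attenuation_db = att))
  )
  visual_field(eye = eye, blind_spot = bs, scotomas = scot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed boundary polyline of a field region
#'
#' Constructive outline of a region in degree coordinates, with vertices
#' spaced at most `resolution_deg` apart; the first vertex is repeated at
#' the end. Used as the ground-truth boundary against which delineation
#' accuracy is measured.
#'
#' @param field A [visual_field()].
#' @param region_index Index into [field_regions()] (1 = blind spot).
#' @param resolution_deg Maximum vertex spacing in degrees.
#' @return A closed two-column matrix of `x_deg`, `y_deg` vertices.
#' @export
region_boundary_polyline <- function(field, region_index,
                                     resolution_deg = 0.1) {
  regions <- field_regions(field)
  if (region_index < 1 || region_index > length(regions)) {
    stop("region_index out of range")
  }
  if (resolution_deg <= 0) stop("resolution must be positive")
  region_boundary(regions[[region_index]], resolution_deg)
}

region_boundary <- function(region, resolution_deg) {
  UseMethod("region_boundary")
}

arc_points <- function(center, radius, from_deg, to_deg, resolution_deg) {
  arc_len <- abs(to_deg - from_deg) * pi / 180 * radius
  n <- max(2L, ceiling(arc_len / resolution_deg) + 1L)
  a <- seq(from_deg, to_deg, length.out = n) * pi / 180
  cbind(center[1] + radius * cos(a), center[2] + radius * sin(a))
}

#' @export
region_boundary.blind_spot <- function(region, resolution_deg) {
  a <- region$semi_axes_deg[1]; b <- region$semi_axes_deg[2]
  # equal-angle parametrisation: local speed is at most max(a, b), so this
  # vertex count bounds every chord by the requested resolution
  n <- max(8L, ceiling(2 * pi * max(a, b) / resolution_deg) + 1L)
  t <- seq(0, 2 * pi, length.out = n)
  out <- cbind(region$center[1] + a * cos(t), region$center[2] + b * sin(t))
  colnames(out) <- c("x_deg", "y_deg")
  out
}

#' @export
region_boundary.arcuate_scotoma <- function(region, resolution_deg) {
  sp <- region$angular_span_deg
  ro <- region$arc_radius_deg + region$width_deg / 2
  ri <- region$arc_radius_deg - region$width_deg / 2
  out <- rbind(arc_points(region$arc_center, ro, sp[1], sp[2], resolution_deg),
               arc_points(region$arc_center, ri, sp[2], sp[1], resolution_deg))
  out <- rbind(out, out[1, ])
  colnames(out) <- c("x_deg", "y_deg")
  out
}

#' @export
region_boundary.wedge_scotoma <- function(region, resolution_deg) {
  sp <- region$sector_deg
  out <- rbind(arc_points(region$apex, region$radial_deg[2], sp[1], sp[2],
                          resolution_deg),
               arc_points(region$apex, max(region$radial_deg[1], 1e-9),
                          sp[2], sp[1], resolution_deg))
  out <- rbind(out, out[1, ])
  colnames(out) <- c("x_deg", "y_deg")
  out
}

# Minimum distance from points to a polyline (segment-wise), in the same
# units as the coordinates.
polyline_min_distance <- function(px, py, poly) {
  n <- length(px)
  best <- rep(Inf, n)
  for (i in seq_len(nrow(poly) - 1)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[i + 1, 1]; by <- poly[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
         else rep(0, n)
    d <- sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
    best <- pmin(best, d)
  }
  best
}
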