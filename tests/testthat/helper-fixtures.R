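# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

t_geom <- function() screen_geometry()
t_spec <- function() stimulus_spec()

# A nearly straight horizontal absolute band of the given width centred on
# y = y0: an arcuate region of radius 500 degrees, whose sagitta over a dot
# diameter is below 2e-5 degrees, so closed-form straight-band arithmetic
# applies to it.
straight_band_field <- function(y0 = 6, width = 0.35, depth = "absolute",
                                attenuation_db = NULL) {
  R <- 500
  visual_field(
    blind_spot = blind_spot(),
    scotomas = list(arcuate_scotoma(c(0, y0 - R), R, c(88, 92), width,
                                    depth = depth,
                                    attenuation_db = attenuation_db)))
}

central_paths <- function(traj) {
  traj[vapply(traj, function(p) p$label != "blind_spot_line", logical(1))]
}

# Maximum radial extent of the deterministic polar disc sampler, as a
# fraction of the disc radius (outermost equal-area ring).
sampler_extent <- function() sqrt(15.5 / 16)

dist_cm <- function(p, q, geom = t_geom()) {
  sqrt(sum((deg_to_cm(p, geom) - deg_to_cm(q, geom))^2))
}

# Worst screen-cm distance between each engine segment's endpoints and the
# best-matching oracle segment on the same path.
worst_segment_error_cm <- function(engine_segs, oracle_segs, geom = t_geom()) {
  stopifnot(nrow(engine_segs) > 0)
  worst <- 0
  for (i in seq_len(nrow(engine_segs))) {
    s <- engine_segs[i, ]
    cand <- oracle_segs[oracle_segs$path == s$path, , drop = FALSE]
    if (nrow(cand) == 0) return(Inf)
    d <- vapply(seq_len(nrow(cand)), function(j) {
      a <- cand[j, ]
      max(dist_cm(c(s$x_off_deg, s$y_off_deg), c(a$x_off_deg, a$y_off_deg), geom),
          dist_cm(c(s$x_on_deg, s$y_on_deg), c(a$x_on_deg, a$y_on_deg), geom))
    }, numeric(1))
    worst <- max(worst, min(d))
  }
  worst
}

# Distance of a point to polyline vertices (coarse but sufficient for
# spot checks at the vertex resolution used).
polyline_dist_helper <- function(x, y, poly) {
  sqrt((poly[, 1] - x)^2 + (poly[, 2] - y)^2)
}

# Printed size-ladder rows (distance from fixation, diameter in mm,
# angular diameter) used as frozen expectations.
size_ladder <- function() {
  data.frame(ecc = c(0, 1, 2.5, 5, 7.5, 10, 12.5, 15),
             mm = c(1.05, 1.16, 1.33, 1.61, 1.88, 2.17, 2.45, 2.72),
             deg = c(0.16, 0.17, 0.19, 0.23, 0.27, 0.31, 0.35, 0.39))
}
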