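test_that("classification is total with deepest-wins precedence", {
  f <- make_preset_field("clean")
  expect_equal(classify_point(f, f$blind_spot$center), "absolute")
  expect_equal(classify_point(f, c(0, 0)), "normal")
  # a relative band overlapped by an absolute band classifies absolute
  R <- 500
  f2 <- visual_field(scotomas = list(
    arcuate_scotoma(c(0, 6 - R), R, c(88, 92), 1, depth = "relative",
                    attenuation_db = 5),
    arcuate_scotoma(c(0, 6 - R), R, c(88, 92), 0.4, depth = "absolute")))
  expect_equal(classify_point(f2, c(2.5, 6)), "absolute")
  expect_equal(classify_point(f2, c(2.5, 6.4)), "relative")
  expect_equal(classify_point(f2, c(2.5, 8)), "normal")
})

test_that("classification is independent of scotoma order", {
  R <- 500
  a <- arcuate_scotoma(c(0, 6 - R), R, c(88, 92), 1, depth = "relative",
                       attenuation_db = 5)
  b <- arcuate_scotoma(c(0, 6 - R), R, c(88, 92), 0.4, depth = "absolute")
  w <- wedge_scotoma(c(0, 0), c(0, 90), c(1, 12), depth = "absolute")
  f1 <- visual_field(scotomas = list(a, b, w))
  f2 <- visual_field(scotomas = list(w, b, a))
  set.seed(7)
  x <- runif(500, -15, 20); y <- runif(500, -15, 15)
  expect_identical(classify_points(f1, x, y), classify_points(f2, x, y))
})

test_that("region constructors validate their invariants", {
  expect_error(blind_spot(center = c(5, 0)), "temporal")
  expect_error(arcuate_scotoma(c(0, 0), 1, c(0, 90), 3), "exceed")
  expect_error(arcuate_scotoma(c(0, 0), 10, c(0, 90), 1,
                               depth = "relative"), "attenuation")
  expect_error(arcuate_scotoma(c(0, 0), 10, c(0, 90), 1,
                               attenuation_db = 5), "relative")
  expect_error(wedge_scotoma(radial_deg = c(5, 2)), "outer > inner")
})

test_that("disc coverage obeys the containment law on a straight band", {
  w <- 0.35
  f <- straight_band_field(y0 = 6, width = w)
  ctr <- c(0, 6) # on the arc apex, where the band centreline is exactly y = 6
  # fully contained iff diameter <= width (to sampler resolution)
  expect_equal(disc_coverage_fraction(f, ctr, 0.31), 1)
  expect_equal(disc_coverage_fraction(f, ctr, w - 0.001), 1)
  expect_lt(disc_coverage_fraction(f, ctr, 0.43), 1)
  expect_lt(disc_coverage_fraction(f, ctr, w / sampler_extent() + 0.01), 1)
  # monotone non-increasing in diameter
  fr <- vapply(seq(0.1, 0.9, by = 0.05), function(d) {
    disc_coverage_fraction(f, ctr, d)
  }, numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
  # a disc deep inside a large scotoma is fully covered
  fq <- make_preset_field("quadrant_superior")
  expect_equal(disc_coverage_fraction(fq, c(4, 4), 0.43), 1)
  # area accuracy against the circular-segment formula: disc of radius 0.5
  # centred 0.2 below a straight scotoma edge
  fh <- straight_band_field(y0 = 6 + 50, width = 100) # lower edge at y = 6
  seg_frac <- (acos(0.4) - 0.4 * sqrt(1 - 0.16)) / pi
  expect_equal(disc_coverage_fraction(fh, c(0, 5.8), 1), seg_frac,
               tolerance = 0.02)
})

test_that("presets build the documented ground truths", {
  expect_length(make_preset_field("clean")$scotomas, 0)
  f <- make_preset_field("narrow_arcuate_035")
  rg <- f$scotomas[[1]]
  expect_equal(rg$width_deg, 0.35)
  expect_equal(rg$depth, "absolute")
  # band width is 0.35 at every sampled arc position
  angs <- seq(rg$angular_span_deg[1] + 1, rg$angular_span_deg[2] - 1,
              length.out = 25) * pi / 180
  for (a in angs) {
    u <- c(cos(a), sin(a))
    inside <- rg$arc_center + (rg$arc_radius_deg + 0.174) * u
    outside <- rg$arc_center + (rg$arc_radius_deg + 0.176) * u
    expect_true(region_contains(rg, inside[1], inside[2]))
    expect_false(region_contains(rg, outside[1], outside[2]))
  }
  # the arc apex crosses the Bjerrum region 8 degrees above fixation
  expect_true(region_contains(rg, 0, 8))
  expect_equal(eccentricity_deg(rg$arc_center) - rg$arc_radius_deg, -8,
               tolerance = 1e-9)
  # ... and anchors at the blind-spot centre
  expect_true(region_contains(rg, f$blind_spot$center[1],
                              f$blind_spot$center[2]))
  fi <- make_preset_field("inferior_arcuate")
  expect_true(region_contains(fi$scotomas[[1]], 0, -8))
  expect_error(make_preset_field("nope"), "unknown preset")
})

test_that("boundary polylines trace the regions at stated resolution", {
  f <- make_preset_field("quadrant_superior")
  res <- 0.05
  # blind-spot ellipse: vertices satisfy the ellipse equation; closed;
  # spacing below resolution
  poly <- region_boundary_polyline(f, 1, res)
  bs <- f$blind_spot
  q <- ((poly[, 1] - bs$center[1]) / bs$semi_axes_deg[1])^2 +
    ((poly[, 2] - bs$center[2]) / bs$semi_axes_deg[2])^2
  expect_lt(max(abs(q - 1)), 1e-9)
  expect_equal(poly[1, ], poly[nrow(poly), ])
  steps <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                           poly[-nrow(poly), , drop = FALSE])^2))
  expect_lte(max(steps), res * 1.01)
  # wedge outline: spot checks just inside and outside
  wpoly <- region_boundary_polyline(f, 2, res)
  expect_equal(wpoly[1, ], wpoly[nrow(wpoly), ])
  rg <- f$scotomas[[1]]
  expect_true(region_contains(rg, 4, 4))
  outer_mid <- 12 * c(cos(pi / 4), sin(pi / 4)) # outer rim at mid-sector
  expect_lt(min(polyline_dist_helper(outer_mid[1], outer_mid[2], wpoly)), 0.3)
  # band: inner and outer rims are one width apart
  fb <- make_preset_field("narrow_arcuate_035")
  bpoly <- region_boundary_polyline(fb, 2, res)
  rgb <- fb$scotomas[[1]]
  mid_ang <- mean(rgb$angular_span_deg) * pi / 180
  outer_pt <- rgb$arc_center +
    (rgb$arc_radius_deg + rgb$width_deg / 2) * c(cos(mid_ang), sin(mid_ang))
  inner_pt <- rgb$arc_center +
    (rgb$arc_radius_deg - rgb$width_deg / 2) * c(cos(mid_ang), sin(mid_ang))
  expect_equal(sqrt(sum((outer_pt - inner_pt)^2)), rgb$width_deg,
               tolerance = 1e-9)
  expect_lt(min(polyline_dist_helper(outer_pt[1], outer_pt[2], bpoly)), res)
  expect_error(region_boundary_polyline(fb, 5), "out of range")
})
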