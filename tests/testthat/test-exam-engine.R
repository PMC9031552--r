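test_that("a clean field yields exactly the blind-spot segment", {
  ex <- run_screening(make_preset_field("clean"), observer_params())
  expect_equal(nrow(ex$segments), 1)
  expect_equal(ex$segments$path, "blind_spot_line")
  expect_false(ex$segments$opened_at_start)
  expect_false(ex$segments$closed_at_end)
  # the segment straddles the blind-spot centre
  expect_lt(ex$segments$y_off_deg, -1.5)
  expect_gt(ex$segments$y_on_deg, -1.5)
})

test_that("screening detects the narrow 0.35-degree arcuate band", {
  ex <- run_screening(make_preset_field("narrow_arcuate_035"),
                      observer_params())
  segs <- ex$segments[ex$segments$path != "blind_spot_line", ]
  expect_gte(nrow(segs), 1)
  expect_true(any(grepl("^vertical_", segs$path)))
  expect_true(all(!segs$opened_at_start & !segs$closed_at_end))
})

test_that("screening durations meet the timing claims", {
  ex <- run_screening(make_preset_field("clean"), observer_params())
  expect_lt(ex$duration_central_s, 30)
  expect_lt(ex$duration_s, 60)
  geom <- t_geom(); spec <- t_spec()
  traj <- build_screening_trajectory(geom)
  expect_equal(ex$duration_s,
               sum(vapply(traj, path_length_cm, numeric(1), geom = geom)) /
                 spec$speed_cm_s,
               tolerance = 1e-9)
  # dot diameter is re-evaluated every frame from the current eccentricity
  fr <- ex$frames
  expect_equal(fr$diameter_mm,
               dot_diameter_mm(eccentricity_deg(cbind(fr$x_deg, fr$y_deg)),
                               spec))
})

test_that("segments match analytic path-region intersections within one frame step", {
  geom <- t_geom(); spec <- t_spec()
  traj <- build_screening_trajectory(geom)
  frame_step_cm <- spec$speed_cm_s / geom$frame_rate_hz
  for (preset in c("clean", "narrow_arcuate_035", "superior_arcuate",
                   "quadrant_superior")) {
    f <- make_preset_field(preset)
    ex <- run_screening(f, observer_params(), traj, geom, spec)
    oracle <- analytic_segments(f, traj, spec, geom)
    err <- worst_segment_error_cm(ex$segments, oracle, geom)
    expect_lte(err, frame_step_cm + 1e-9)
  }
})

test_that("the analytic oracle matches the closed-form straight-band law", {
  geom <- t_geom(); spec <- t_spec()
  y0 <- 6; w <- 0.35
  f <- straight_band_field(y0 = y0, width = w)
  # probe through the arc apex (x = 0), where the band centreline is y0
  p <- path_spec("probe", c(0, 0), c(0, 10))
  traj <- structure(list(p), class = "trajectory")
  an <- analytic_segments(f, traj, spec, geom)
  expect_equal(nrow(an), 1)
  # containment begins when the deepest sampler point clears the band edge:
  # y_off = y0 - w/2 + f*r, y_on = y0 + w/2 - f*r (fixed point in r)
  fex <- sampler_extent()
  r <- dot_diameter_deg(eccentricity_deg(c(0, y0)), spec, geom) / 2
  for (i in 1:3) {
    y_off <- y0 - w / 2 + fex * r
    r <- dot_diameter_deg(eccentricity_deg(c(0, y_off)), spec, geom) / 2
  }
  expect_equal(an$y_off_deg, y0 - w / 2 + fex * r, tolerance = 5e-3)
  expect_equal(an$y_on_deg, y0 + w / 2 - fex * r, tolerance = 5e-3)
})

test_that("event pairing applies the boundary-closure rules", {
  geom <- t_geom(); spec <- t_spec()
  p <- path_spec("probe", c(5, -10), c(5, 10))
  traj <- structure(list(p), class = "trajectory")
  mk_ev <- function(frames, events) {
    data.frame(path = rep("probe", length(frames)), frame = frames,
               event = events, t_s = (frames - 1) / 60,
               latency_s = rep(0, length(frames)),
               x_deg = rep(5, length(frames)), y_deg = rep(0, length(frames)),
               s_cm = frames * 0.05, stringsAsFactors = FALSE)
  }
  one <- pair_events(mk_ev(c(10, 20), c("off", "on")), traj, geom, spec)
  expect_equal(nrow(one), 1)
  expect_false(one$opened_at_start); expect_false(one$closed_at_end)
  none <- pair_events(mk_ev(integer(0), character(0)), traj, geom, spec)
  expect_equal(nrow(none), 0)
  # an unresolved off closes at the path endpoint
  tail_off <- pair_events(mk_ev(10, "off"), traj, geom, spec)
  expect_true(tail_off$closed_at_end)
  expect_equal(c(tail_off$x_on_deg, tail_off$y_on_deg), c(5, 10))
  # an unmatched on opens at the path start
  head_on <- pair_events(mk_ev(10, "on"), traj, geom, spec)
  expect_true(head_on$opened_at_start)
  expect_equal(c(head_on$x_off_deg, head_on$y_off_deg), c(5, -10))
  expect_error(pair_events(mk_ev(c(10, 20), c("off", "off")), traj,
                           geom, spec), "malformed")
})

test_that("a region reaching beyond the path end closes at the endpoint", {
  # the superior wedge spans past y = 10 at x = 2.5, so the vertical path
  # ends while the dot is still invisible
  f <- make_preset_field("quadrant_superior")
  ex <- run_screening(f, observer_params())
  v3 <- ex$segments[ex$segments$path == "vertical_3", ]
  expect_equal(nrow(v3), 1)
  expect_true(v3$closed_at_end)
  expect_equal(v3$y_on_deg, 10)
  # conservation: every off event has exactly one resolution
  expect_equal(sum(ex$events$event == "off"),
               nrow(ex$segments) - sum(ex$segments$opened_at_start))
})

test_that("identical configuration and seed give identical records", {
  f <- make_preset_field("narrow_arcuate_035")
  expect_identical(run_screening(f, observer_params()),
                   run_screening(f, observer_params()))
  obs <- observer_params(latency_sd_s = 0.05, lapse_rate = 0.2, rng_seed = 3)
  expect_identical(run_screening(f, obs), run_screening(f, obs))
})

test_that("eye bookkeeping between field and trajectory is enforced", {
  f <- make_preset_field("clean", eye = "OS")
  expect_error(run_screening(f, observer_params()), "different eyes")
  traj <- build_screening_trajectory(t_geom(), eye = "OS")
  expect_silent(ex <- run_screening(f, observer_params(), traj))
  expect_equal(nrow(ex$segments), 1)
})
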