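test_that("visibility follows the containment rule", {
  obs <- observer_params()
  f <- straight_band_field(y0 = 6, width = 0.35)
  # a 0.31-degree dot vanishes in the 0.35-degree band; 0.43 does not
  expect_false(stimulus_visible(f, obs, c(2.5, 6), 0.31))
  expect_true(stimulus_visible(f, obs, c(2.5, 6), 0.43))
  expect_true(stimulus_visible(f, obs, c(-5, -5), 0.31))
  # relative regions never extinguish the dot
  fr <- straight_band_field(y0 = 6, width = 2, depth = "relative",
                            attenuation_db = 10)
  expect_true(stimulus_visible(fr, obs, c(2.5, 6), 0.31))
})

test_that("respond is an exact change-point detector at zero noise", {
  obs <- observer_params()
  t <- (0:9) / 60
  expect_equal(nrow(respond(rep(TRUE, 10), t, obs)), 0)
  vis <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  ev <- respond(vis, t, obs)
  expect_equal(ev$event, c("off", "on"))
  expect_equal(ev$frame, c(3, 6))
  expect_equal(ev$t_response_s, t[c(3, 6)])
  # initially invisible timeline opens with an off at frame 1
  ev2 <- respond(c(FALSE, FALSE, TRUE), (0:2) / 60, obs)
  expect_equal(ev2$event, c("off", "on"))
  expect_equal(ev2$frame, c(1, 3))
})

test_that("event count equals twice the invisible-interval count", {
  obs <- observer_params()
  set.seed(99)
  for (i in 1:20) {
    vis <- runif(200) > 0.3
    vis[c(1, 200)] <- TRUE # close all intervals inside the timeline
    ev <- respond(vis, (0:199) / 60, obs)
    r <- rle(vis)
    n_int <- sum(!r$values)
    expect_equal(nrow(ev), 2 * n_int)
    expect_equal(sum(ev$event == "off"), n_int)
  }
})

test_that("latency displaces events in time and along the path", {
  obs <- observer_params(latency_mean_s = 0.2)
  vis <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 5))
  t <- (0:14) / 60
  ev <- respond(vis, t, obs)
  expect_equal(ev$t_response_s - t[ev$frame], rep(0.2, 2))
  # engine-level: at 3 cm/s a 0.2 s latency displaces the recorded event
  # exactly 0.6 cm along the path
  f <- straight_band_field(y0 = 6, width = 2)
  geom <- t_geom()
  traj <- build_screening_trajectory(geom)
  v3 <- traj[vapply(traj, function(p) p$label == "vertical_3", logical(1))]
  ex0 <- run_screening(f, observer_params(), structure(v3, class = "trajectory"),
                       geom)
  ex1 <- run_screening(f, obs, structure(v3, class = "trajectory"), geom)
  s0 <- ex0$events$s_cm[ex0$events$event == "off"][1]
  s1 <- ex1$events$s_cm[ex1$events$event == "off"][1]
  expect_equal(s1 - s0, 0.6, tolerance = 1e-9)
})

test_that("stochastic observers are reproducible from their seed", {
  f <- make_preset_field("superior_arcuate")
  obs <- observer_params(latency_mean_s = 0.15, latency_sd_s = 0.05,
                         lapse_rate = 0.3, rng_seed = 11)
  ex1 <- run_screening(f, obs)
  ex2 <- run_screening(f, obs)
  expect_identical(ex1, ex2)
  # lapses elide off/on pairs together: streams stay well-formed per path
  for (s in 1:5) {
    obs2 <- observer_params(lapse_rate = 0.7, rng_seed = s)
    ex <- run_screening(f, obs2)
    for (p in unique(ex$events$path)) {
      evp <- ex$events[ex$events$path == p, ]
      evp <- evp[order(evp$frame), ]
      expect_true(all(evp$event == rep(c("off", "on"),
                                       length.out = nrow(evp))))
    }
  }
})

test_that("observer parameter validation rejects bad values", {
  expect_error(observer_params(containment_threshold = 0), "\\(0, 1\\]")
  expect_error(observer_params(containment_threshold = 1.2), "\\(0, 1\\]")
  expect_error(observer_params(lapse_rate = 1), "rates")
  expect_error(observer_params(latency_mean_s = -0.1), "non-negative")
})
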