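test_that("the 10-2 grid has exactly 68 points under the radius rule", {
  g <- grid_10_2()
  pts <- g$points
  expect_equal(nrow(pts), 68)
  # odd lattice, 2-degree spacing, 1 degree off both meridians
  expect_true(all(pts$x_deg %% 2 == 1 | pts$x_deg %% 2 == -1))
  expect_true(all(abs(pts$x_deg) >= 1 & abs(pts$x_deg) <= 9))
  expect_true(all(pts$x_deg^2 + pts$y_deg^2 <= 82))
  # the radius rule keeps (9,1) and drops (9,3)
  expect_true(any(pts$x_deg == 9 & pts$y_deg == 1))
  expect_false(any(pts$x_deg == 9 & pts$y_deg == 3))
  # 4-fold mirror symmetry
  key <- function(x, y) paste(x, y)
  k <- key(pts$x_deg, pts$y_deg)
  expect_true(all(key(-pts$x_deg, pts$y_deg) %in% k))
  expect_true(all(key(pts$x_deg, -pts$y_deg) %in% k))
  expect_identical(g$points, grid_10_2()$points)
  expect_equal(g$stimulus_diameter_deg, 0.43)
})

test_that("static exam classifies by stimulus containment", {
  # clean field: nothing in the central 10 degrees
  res <- simulate_static_exam(make_preset_field("clean"))
  expect_equal(unname(res$counts["normal"]), 68)
  # narrow band: the 0.43-degree stimulus cannot fit in 0.35 degrees, so
  # no point is an absolute defect
  resn <- simulate_static_exam(make_preset_field("narrow_arcuate_035"))
  expect_equal(unname(resn$counts["absolute_defect"]), 0)
  # a large wedge swallows grid points whole
  resq <- simulate_static_exam(make_preset_field("quadrant_superior"))
  expect_gte(unname(resq$counts["absolute_defect"]), 1)
  # relative regions mark relative defects at the point centre
  fr <- straight_band_field(y0 = 7, width = 2, depth = "relative",
                            attenuation_db = 10)
  resr <- simulate_static_exam(fr)
  expect_gte(unname(resr$counts["relative_defect"]), 1)
  expect_equal(unname(resr$counts["absolute_defect"]), 0)
})

test_that("classification is monotone in stimulus size", {
  # a band crossing the y = 7 grid row: invisible to 0.43 but fully
  # containing a 0.31-degree stimulus
  f <- straight_band_field(y0 = 7, width = 0.35)
  abs43 <- simulate_static_exam(f, grid_10_2(0.43))$points
  abs31 <- simulate_static_exam(f, grid_10_2(0.31))$points
  a43 <- abs43$classification == "absolute_defect"
  a31 <- abs31$classification == "absolute_defect"
  expect_equal(sum(a43), 0)
  expect_gte(sum(a31), 1)
  # shrinking the stimulus never loses an absolute point
  expect_true(all(!a43 | a31))
})

test_that("the discordance window spans widths between 0.31 and 0.43 degrees", {
  # w = 0.35: no static absolute point; w = 0.6 over a grid row: at least one
  expect_equal(unname(
    simulate_static_exam(straight_band_field(7, 0.35))$counts["absolute_defect"]),
    0)
  expect_gte(unname(
    simulate_static_exam(straight_band_field(7, 0.6))$counts["absolute_defect"]),
    1)
})

test_that("compare_methods reports the discordance pattern", {
  obs <- observer_params()
  # narrow band: kinetic absolute, static at most relative
  fn <- make_preset_field("narrow_arcuate_035")
  cmp <- compare_methods(run_screening(fn, obs), simulate_static_exam(fn), fn)
  expect_true(cmp$regions$campimetry_absolute)
  expect_false(cmp$regions$static_absolute)
  expect_true(cmp$regions$discordant)
  expect_true(cmp$any_discordant)
  # clean field: both negative
  fc <- make_preset_field("clean")
  cmpc <- compare_methods(run_screening(fc, obs), simulate_static_exam(fc), fc)
  expect_false(cmpc$campimetry_positive)
  expect_false(cmpc$static_positive)
  # wide absolute arcuate: both methods positive and concordant
  fw <- make_preset_field("superior_arcuate")
  cmpw <- compare_methods(run_screening(fw, obs), simulate_static_exam(fw), fw)
  expect_true(cmpw$regions$campimetry_absolute)
  expect_true(cmpw$regions$static_absolute)
  expect_false(cmpw$regions$discordant)
  # provenance mismatch is an error
  expect_error(compare_methods(run_screening(fn, obs),
                               simulate_static_exam(fw), fw),
               "derive from")
})
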