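test_that("uniform-tube resistance matches the closed Poiseuille form", {
  blood <- blood_properties()
  seg <- segment("s", 0.01, 0.003, 0.003)
  r <- segment_resistance(seg, blood)
  expect_equal(r, 1.7605288e7, tolerance = 1e-6)
  expect_equal(r, 128 * blood$viscosity * 0.01 / (pi * 0.003^4),
               tolerance = 1e-12)
  # two-point mean-area form for a tapered tube
  tap <- segment("t", 0.01, 0.004, 0.002)
  expect_equal(segment_resistance(tap, blood),
               8 * pi * blood$viscosity * 0.01 / segment_mean_area(tap)^2,
               tolerance = 1e-12)
})

test_that("resistance scales linearly in length, as d^-4 in diameter", {
  r1 <- segment_resistance(segment("s", 0.01, 0.003, 0.003))
  r2 <- segment_resistance(segment("s", 0.02, 0.003, 0.003))
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
  rhalf <- segment_resistance(segment("s", 0.01, 0.0015, 0.0015))
  expect_equal(rhalf, 16 * r1, tolerance = 1e-12)
})

test_that("a flat profile reproduces the closed form exactly", {
  seg <- segment("s", 0.02, 0.003, 0.003,
                 profile = data.frame(pos = c(0, 0.007, 0.013, 0.02),
                                      diameter = rep(0.003, 4)))
  expect_equal(segment_resistance(seg),
               segment_resistance(segment("s", 0.02, 0.003, 0.003)),
               tolerance = 1e-12)
})

test_that("stenosis-modified resistance matches the piecewise closed form", {
  blood <- blood_properties()
  seg <- segment("s", 0.02, 0.003, 0.003)
  st <- stenosis("s", 0.0075, 0.005, 0.5, 0.003)
  got <- stenosis_effective_resistance(seg, st, blood)
  # independent arithmetic: healthy 15 mm at 3 mm, lesion 5 mm at 1.5 mm
  expected <- 128 * blood$viscosity * 0.015 / (pi * 0.003^4) +
    128 * blood$viscosity * 0.005 / (pi * 0.0015^4)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(got, 1.6725023e8, tolerance = 1e-6)
})

test_that("severity 0-limit and Q->0 nonlinear limit recover the healthy / linear values", {
  seg <- segment("s", 0.02, 0.003, 0.003)
  healthy <- segment_resistance(seg)
  tiny <- stenosis_effective_resistance(
    seg, stenosis("s", 0.005, 0.005, 1e-9, 0.003))
  expect_equal(tiny, healthy, tolerance = 1e-6)
  expect_equal(stenosis_effective_resistance(seg, NULL), healthy)

  st <- stenosis("s", 0.0075, 0.005, 0.5, 0.003)
  lin <- stenosis_effective_resistance(seg, st)
  for (q in c(1e-6, 1e-9, 1e-12))
    expect_equal(stenosis_effective_resistance(seg, st, Q = q) - lin,
                 1.52 * 1050 / (2 * (pi * 0.003^2 / 4)^2) * (4 - 1)^2 * q,
                 tolerance = 1e-9)
  expect_gt(stenosis_effective_resistance(seg, st, Q = 1e-6), lin)
})

test_that("resistance grows with severity and shrinks with diameter", {
  seg <- segment("s", 0.02, 0.003, 0.003)
  sev <- seq(0.1, 0.9, by = 0.1)
  r <- vapply(sev, function(s)
    stenosis_effective_resistance(seg, stenosis("s", 0.005, 0.008, s,
                                                0.003)),
    numeric(1))
  expect_true(all(diff(r) > 0))
  expect_error(stenosis_effective_resistance(
    seg, stenosis("s", 0.005, 0.008, 1 - 1e-18, 0.003)), "singular")
})

test_that("single-path calibration follows the stepwise Ohm walk", {
  blood <- blood_properties()
  tr <- single_vessel(L = 0.03, d = 0.003)
  q <- mLs_to_m3s(1)
  resting <- distribute_flow(tr, q)
  p_mbp <- 280 / 3
  rmap <- calibrate_microcirculation(tr, p_mbp, resting, blood)
  drop_pa <- segment_resistance(tr$segments$v, blood) * q
  p_i_expected <- mmHg_to_Pa(p_mbp) - drop_pa
  expect_equal(unname(rmap$p_outlet_rest["v"]), p_i_expected,
               tolerance = 1e-12)
  expect_equal(unname(rmap$micro_rest["v"]), p_i_expected / q,
               tolerance = 1e-12)
})

test_that("negligible epicardial resistance gives P_i = P_MBP, R_i = P/Q", {
  # vanishing length ~ zero epicardial drop
  tr <- single_vessel(L = 1e-12, d = 0.003)
  q <- 2e-6
  rmap <- calibrate_microcirculation(tr, 90, distribute_flow(tr, q))
  expect_equal(unname(rmap$p_outlet_rest["v"]), mmHg_to_Pa(90),
               tolerance = 1e-9)
  expect_equal(unname(rmap$micro_rest["v"]), mmHg_to_Pa(90) / q,
               tolerance = 1e-9)
})

test_that("symmetric bifurcation calibrates equal outlet resistances", {
  tr <- bifurcation_tree()
  rmap <- calibrate_microcirculation(tr, 95, distribute_flow(tr, 2.8e-6))
  expect_equal(unname(rmap$micro_rest["a"]), unname(rmap$micro_rest["b"]),
               tolerance = 1e-12)
})

test_that("calibration uses healthy geometry, ignoring stenoses", {
  healthy <- bifurcation_tree()
  sick <- coronary_tree(unname(healthy$segments),
                        stenoses = stenosis("a", 0.005, 0.008, 0.7, 0.003))
  f1 <- distribute_flow(healthy, 2.8e-6)
  f2 <- distribute_flow(sick, 2.8e-6)
  expect_equal(f1$outflows, f2$outflows)
  r1 <- calibrate_microcirculation(healthy, 95, f1)
  r2 <- calibrate_microcirculation(sick, 95, f2)
  expect_equal(r1$micro_rest, r2$micro_rest)
})

test_that("calibration names the outlet when pressure is exhausted", {
  # absurdly narrow long vessel: epicardial drop exceeds P_MBP
  tr <- single_vessel(L = 0.5, d = 0.0005)
  expect_error(
    calibrate_microcirculation(tr, 90, distribute_flow(tr, 2.8e-6)),
    "nonpositive microcirculation inlet pressure.*v")
})

test_that("resting solve with calibrated resistances inverts calibration", {
  # round trip on several fixtures: calibration is the inverse of the
  # resting network solve
  fixtures <- list(single_vessel(), bifurcation_tree(d1 = 0.003,
                                                     d2 = 0.002),
                   three_level_tree(),
                   generate_tree(11, cohort_spec(depth_range = c(4L, 4L))))
  for (tr in fixtures) {
    resting <- distribute_flow(tr, 2.8e-6)
    rmap <- calibrate_microcirculation(tr, 95, resting)
    back <- direct_solve_linear(tr, mmHg_to_Pa(95), rmap$micro_rest)
    expect_equal(back$outflows[tr$outlets], resting$outflows[tr$outlets],
                 tolerance = 1e-10)
  }
})
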