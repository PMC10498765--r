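test_that("forward pressure solve obeys Ohm drops along paths", {
  blood <- blood_properties()
  tr <- single_vessel(L = 0.03, d = 0.003)
  q <- c(v = 2e-6)
  p0 <- mmHg_to_Pa(82)
  st <- network_pressures(tr, q, p0, blood)
  r <- segment_resistance(tr$segments$v, blood)
  expect_equal(unname(st$p_node["v"]), p0 - r * 2e-6, tolerance = 1e-12)

  # vanishing resistance: all node pressures equal the inlet pressure
  tiny <- single_vessel(L = 1e-14)
  st2 <- network_pressures(tiny, c(v = 2e-6), p0)
  expect_equal(unname(st2$p_node["v"]), p0, tolerance = 1e-6)
})

test_that("pressures never increase from root to leaf for positive flows", {
  prob <- random_hyperemic_problem(3)
  st <- network_pressures(prob$tree, prob$resting$outflows, prob$p0)
  for (o in prob$tree$outlets) {
    path <- path_to_root(prob$tree, o)
    p <- c(st$p_in, st$p_node[path])
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("arc pressure interpolates the drop and hits nodal endpoints", {
  tr <- single_vessel(L = 0.03, d = 0.003)
  q <- c(v = 2e-6)
  p0 <- mmHg_to_Pa(82)
  st <- network_pressures(tr, q, p0)
  expect_equal(arc_pressure(tr, st, "v", 0), p0)
  expect_equal(arc_pressure(tr, st, "v", 0.03), unname(st$p_node["v"]),
               tolerance = 1e-12)
  # uniform tube: linear decline, so midpoint = mean of ends
  expect_equal(arc_pressure(tr, st, "v", 0.015),
               (p0 + st$p_node[["v"]]) / 2, tolerance = 1e-12)
  expect_error(arc_pressure(tr, st, "v", 0.05), "out of range")
})

test_that("single-outlet fixed point matches the series closed form", {
  # Q* = P0 / (R_e + R_j); outlet pressure P0 - Q* R_e
  blood <- blood_properties()
  tr <- single_vessel(L = 0.03, d = 0.003)
  r_e <- segment_resistance(tr$segments$v, blood)
  r_j <- c(v = 4.5 * r_e)  # mimics the 4:18 series ratio
  p0 <- mmHg_to_Pa(88)
  sol <- identify_hyperemic_flows(tr, p0, r_j,
                                  solver_settings(tol = 1e-12))
  q_star <- p0 / (r_e + r_j[["v"]])
  expect_equal(unname(sol$flows$outflows["v"]), q_star, tolerance = 1e-9)
  expect_equal(unname(sol$state$p_node["v"]), p0 - q_star * r_e,
               tolerance = 1e-9)
  expect_true(sol$report$converged)
  # FFR at the outlet of this series circuit: R_j/(R_e+R_j) = 4.5/5.5
  expect_equal(unname(sol$state$p_node["v"]) / p0, 4.5 / 5.5,
               tolerance = 1e-9)
})

test_that("zero epicardial resistance solves in one relaxed step to P0/R_j", {
  tr <- single_vessel(L = 1e-14)
  p0 <- mmHg_to_Pa(82)
  r_j <- c(v = 5e9)
  sol <- identify_hyperemic_flows(
    tr, p0, r_j, solver_settings(alpha = 1, tol = 1e-12, init = "series"))
  expect_equal(unname(sol$flows$outflows["v"]), p0 / 5e9, tolerance = 1e-9)
  expect_lte(sol$report$iterations, 2L)
})

test_that("symmetric bifurcation with identical R_j yields identical flows", {
  tr <- bifurcation_tree()
  p0 <- mmHg_to_Pa(82)
  r_j <- c(a = 6e9, b = 6e9)
  sol <- identify_hyperemic_flows(tr, p0, r_j, solver_settings(tol = 1e-10),
                                  init_flows = c(a = 1e-6, b = 1e-6))
  expect_equal(unname(sol$flows$outflows["a"]),
               unname(sol$flows$outflows["b"]), tolerance = 1e-12)
})

test_that("fixed point matches the direct linear solve on random trees", {
  # oracle equivalence over seeded random stenosed trees
  for (seed in 1:25) {
    prob <- random_hyperemic_problem(seed)
    sol <- identify_hyperemic_flows(
      prob$tree, prob$p0, prob$r_j, solver_settings(tol = 1e-10),
      init_flows = prob$resting$outflows)
    oracle <- direct_solve_linear(prob$tree, prob$p0, prob$r_j)
    expect_true(sol$report$converged)
    expect_equal(sol$flows$outflows[prob$tree$outlets],
                 oracle$outflows[prob$tree$outlets], tolerance = 1e-6)
  }
})

test_that("fixed-point certificate holds at the default tolerance", {
  for (seed in c(2, 9, 17)) {
    prob <- random_hyperemic_problem(seed)
    sol <- identify_hyperemic_flows(prob$tree, prob$p0, prob$r_j,
                                    init_flows = prob$resting$outflows)
    q <- sol$flows$outflows
    # per outlet: |P0 - (sum path drops + Q_j R_j)| / P0 <= tol
    st <- sol$state
    for (o in prob$tree$outlets) {
      drops <- st$p_in - st$p_node[[o]]
      expect_lte(abs(prob$p0 - (drops + q[[o]] * prob$r_j[[o]])) / prob$p0,
                 1e-4)
    }
  }
})

test_that("residual decays monotonically after burn-in at alpha 0.3", {
  prob <- random_hyperemic_problem(5)
  sol <- identify_hyperemic_flows(
    prob$tree, prob$p0, prob$r_j,
    solver_settings(alpha = 0.3, tol = 1e-12, adaptive = FALSE),
    init_flows = prob$resting$outflows)
  h <- sol$report$history
  burn <- min(5L, length(h) - 1L)
  tail_h <- h[burn:length(h)]
  expect_true(all(diff(tail_h) <= 1e-13))
})

test_that("non-convergence is reported, not raised", {
  prob <- random_hyperemic_problem(4)
  sol <- identify_hyperemic_flows(
    prob$tree, prob$p0, prob$r_j,
    solver_settings(tol = 1e-14, max_iter = 5L),
    init_flows = prob$resting$outflows)
  expect_false(sol$report$converged)
  expect_identical(sol$report$iterations, 5L)
  expect_length(sol$report$history, 5L)
})

test_that("literal printed pressure update drifts to an inconsistent fixed point", {
  # the literal relaxation's stationary pressure is P0 + Q R_j, not the
  # network pressure; kept behind a flag for comparison
  tr <- single_vessel(L = 0.03, d = 0.003)
  r_e <- segment_resistance(tr$segments$v)
  p0 <- mmHg_to_Pa(88)
  r_j <- c(v = 4.5 * r_e)
  lit <- identify_hyperemic_flows(
    tr, p0, r_j, solver_settings(literal_relaxation = TRUE, max_iter = 2000L),
    init_flows = c(v = p0 / (r_e + r_j[["v"]])))
  ref <- p0 / (r_e + r_j[["v"]])
  # does not stay at the true solution it was started from
  expect_gt(abs(lit$flows$outflows[["v"]] - ref) / ref, 0.01)
})

test_that("direct solve handles the 1x1 system and singular geometry", {
  tr <- single_vessel(L = 0.03, d = 0.003)
  r_e <- segment_resistance(tr$segments$v)
  p0 <- mmHg_to_Pa(88)
  out <- direct_solve_linear(tr, p0, c(v = 4.5 * r_e))
  expect_equal(unname(out$outflows["v"]), p0 / (5.5 * r_e),
               tolerance = 1e-12)
})

test_that("healthy-tree hyperemic/resting flow ratio approaches 0.88/0.23", {
  # when epicardial resistance is negligible next to the microcirculation,
  # scaling pressure by 0.88 and resistance by 0.23 multiplies flow by
  # 0.88/0.23
  tr <- bifurcation_tree(L = 1e-9)  # near-zero epicardial resistance
  resting <- distribute_flow(tr, 2.8e-6)
  rmap <- calibrate_microcirculation(tr, 95, resting)
  p0 <- mmHg_to_Pa(hyperemia_pressure(95))
  r_j <- hyperemia_resistance(rmap$micro_rest)
  hyper <- direct_solve_linear(tr, p0, r_j)
  expect_equal(hyper$q_total / resting$q_total, 0.88 / 0.23,
               tolerance = 1e-6)

  # any stenosis strictly reduces the hyperemic gain
  sick <- coronary_tree(unname(tr$segments),
                        stenoses = stenosis("a", 2e-10, 4e-10, 0.6, 0.003))
  hyper_sick <- direct_solve_linear(sick, p0, r_j)
  expect_lt(hyper_sick$q_total, hyper$q_total)
})

test_that("increasing severity never raises pressures downstream of the lesion", {
  # pressures in the stenosed subtree fall monotonically with severity
  # (the sibling branch, by contrast, is allowed to recover pressure as
  # the shared-path flow drops)
  tr0 <- three_level_tree()
  resting <- distribute_flow(tr0, 2.8e-6)
  rmap <- calibrate_microcirculation(tr0, 95, resting)
  p0 <- mmHg_to_Pa(hyperemia_pressure(95))
  r_j <- hyperemia_resistance(rmap$micro_rest)
  downstream <- c("rL", descendant_outlets(tr0, "rL"))
  sib <- "rR"
  prev <- NULL
  d_lesion <- tr0$segments$rL$d_prox
  for (sev in seq(0.1, 0.9, by = 0.2)) {
    tr <- coronary_tree(unname(tr0$segments),
                        stenoses = stenosis("rL", 0.005, 0.008, sev,
                                            d_lesion))
    fl <- direct_solve_linear(tr, p0, r_j)
    st <- network_pressures(tr, fl$outflows, p0)
    if (!is.null(prev)) {
      expect_true(all(st$p_node[downstream] <= prev[downstream] + 1e-9))
      expect_gte(st$p_node[[sib]], prev[[sib]] - 1e-9)
    }
    prev <- st$p_node
  }
})
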