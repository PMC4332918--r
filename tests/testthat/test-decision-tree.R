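test_that("node costs add the components the pathway incurs", {
  expect_equal(node_cost(2.00, 0.78, 0), 2.78)
  expect_equal(node_cost(1.50, 0.35, 0), 1.85)
  expect_equal(node_cost(0, 0, 0), 0)
  expect_error(node_cost(-1, 0, 0), class = "cea_invalid_parameter")
})

test_that("any-ORS-Z coverage is the total-probability combination", {
  expect_equal(any_orsz_coverage(arm_probabilities(1.0, 0.5, 0.9)), 0.5)
  expect_equal(any_orsz_coverage(arm_probabilities(0.0, 0.5, 0.2)), 0.2)
  expect_equal(any_orsz_coverage(arm_probabilities(0.48, 0.16, 0.27)),
               0.2172)
  # equals node mass A + C, and the branch decomposition inverts exactly
  set.seed(11)
  for (i in 1:25) {
    p <- arm_probabilities(runif(1), runif(1), runif(1))
    np <- node_probabilities(p)
    expect_equal(sum(np), 1)
    expect_equal(any_orsz_coverage(p), np[["A"]] + np[["C"]])
    back <- branch_from_node_probabilities(np)
    expect_equal(back$p_seek, p$p_seek)
    expect_equal(any_orsz_coverage(back), any_orsz_coverage(p))
  }
})

test_that("calibrated probabilities satisfy every published constraint", {
  for (tab in list(table2_intervention, table2_control)) {
    p <- calibrate_node_probabilities(tab$per_event, tab$per_diarrhea)
    # independent feasibility check, constraint by constraint
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0 & p <= 1))
    ratio <- tab$per_diarrhea / tab$per_event
    expect_true(all(abs(p - ratio) <= 0.005 / tab$per_event + 1e-12))
    expect_equal(round(p * tab$per_event, 2), tab$per_diarrhea,
                 ignore_attr = TRUE)
  }
  # ratios already summing to one are returned unchanged
  ev <- c(A = 2, B = 4, C = 1, D = 2)
  pd <- c(A = 0.50, B = 1.00, C = 0.25, D = 0.50)  # ratios .25 .25 .25 .25
  expect_equal(calibrate_node_probabilities(ev, pd),
               c(A = 0.25, B = 0.25, C = 0.25, D = 0.25))
  # infeasible cells signal a calibration failure with the residual
  expect_error(
    calibrate_node_probabilities(c(1, 1), c(0.10, 0.20)),
    class = "cea_calibration_failure"
  )
})

test_that("fold-back equals brute-force enumeration on random trees", {
  set.seed(23)
  for (i in 1:50) {
    consult <- runif(1, 0.5, 5)
    orsz <- runif(1, 0.1, 2)
    penalty <- runif(1, 0.1, 3)
    p <- arm_probabilities(runif(1), runif(1), runif(1))
    arm <- arm_model("intervention", consult, orsz, penalty, p)
    expect_equal(
      expected_cost_per_case(arm, method = "exact"),
      enumerate_expected_cost(consult, orsz, penalty, p)
    )
  }
  # point mass on the cheapest node
  arm_d <- arm_model("control", 2, 0.78, 1.35,
                     probabilities = c(A = 0, B = 0, C = 0, D = 1))
  expect_equal(expected_cost_per_case(arm_d, method = "exact"), 1.35)
})

test_that("expected cost rises with node costs and costliest-node mass", {
  p0 <- arm_probabilities(0.5, 0.4, 0.3)
  base <- arm_model("intervention", 2.0, 0.8, 1.2, p0)
  e0 <- expected_cost_per_case(base, "exact")
  # raise each component in turn
  expect_gt(expected_cost_per_case(
    arm_model("intervention", 2.5, 0.8, 1.2, p0), "exact"), e0)
  expect_gt(expected_cost_per_case(
    arm_model("intervention", 2.0, 1.0, 1.2, p0), "exact"), e0)
  expect_gt(expected_cost_per_case(
    arm_model("intervention", 2.0, 0.8, 1.5, p0), "exact"), e0)
  # shift mass from the cheapest node (C) to the costliest (B)
  np <- base$node_probabilities
  shift <- np[["C"]] / 2
  np2 <- np + c(A = 0, B = shift, C = -shift, D = 0)
  expect_gt(expected_cost_per_case(
    arm_model("intervention", 2.0, 0.8, 1.2, probabilities = np2), "exact"),
    e0)
})

test_that("calibrated arms reproduce the published cost table", {
  m <- orasel_model()
  tab_i <- arm_table(m$arms$intervention)
  tab_c <- arm_table(m$arms$control)
  expect_equal(tab_i$cost_per_event, c(2.78, 3.35, 0.78, 1.35))
  expect_equal(tab_i$cost_per_diarrhea, c(0.21, 1.34, 0.11, 0.50))
  expect_equal(tab_c$cost_per_event, c(1.85, 2.78, 0.35, 1.28))
  expect_equal(tab_c$cost_per_diarrhea, c(0.05, 1.09, 0.01, 0.68))
  # tree-implied coverage (mass of A + C) within calibration slack of the
  # Bayes'-rule combination of the back-derived branch probabilities
  for (arm in m$arms) {
    bp <- branch_from_node_probabilities(arm$node_probabilities)
    expect_equal(any_orsz_coverage(bp),
                 sum(arm$node_probabilities[c("A", "C")]))
  }
})

test_that("population scaling and incremental cost behave linearly", {
  frame <- population_frame()
  expect_equal(frame$under5_count, 81000)
  expect_equal(scale_to_population(0, frame), 0)
  expect_equal(scale_to_population(1.00, frame), 48373)

  m <- orasel_model()
  same <- incremental_cost(m$arms$intervention, m$arms$intervention, frame)
  expect_equal(same$per_case, 0)
  expect_equal(same$total, 0)

  a2 <- arm_model("intervention", 0, 2, 0,
                  probabilities = c(A = 0, B = 0, C = 1, D = 0))
  a1 <- arm_model("control", 0, 1, 0,
                  probabilities = c(A = 0, B = 0, C = 1, D = 0))
  inc <- incremental_cost(a2, a1, population_frame(annual_cases = 10))
  expect_equal(inc$per_case, 1.00)
  expect_equal(inc$total, 10.00)
})

test_that("unnormalized node probabilities are rejected", {
  expect_error(
    arm_model("control", 1, 1, 1,
              probabilities = c(A = 0.3, B = 0.3, C = 0.3, D = 0.3)),
    class = "cea_invalid_model"
  )
})
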