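test_that("parameter sampling honors distribution contracts", {
  m <- orasel_model()
  # point distributions reproduce base values exactly
  pts <- lapply(default_psa_specs(m), function(s) dist_spec("point", s$base))
  cfg <- psa_config(n_iterations = 3, seed = 7, specs = pts)
  draw <- sample_parameters(cfg, 1)
  expect_equal(draw, vapply(pts, function(s) s$base, numeric(1)))

  # triangular(0.8, 1, 1.2) sample mean converges to the base value
  set.seed(101)
  x <- franchiseCEA:::rtriangular(1e5, 0.8, 1.0, 1.2)
  se <- (0.2 / sqrt(6)) / sqrt(1e5)
  expect_lt(abs(mean(x) - 1.0), 3 * se)
  expect_true(all(x >= 0.8 & x <= 1.2))

  # heavy truncation keeps every draw inside the bounds
  set.seed(102)
  y <- franchiseCEA:::rtnorm(2000, 0.5, 10, 0, 1)
  expect_true(all(y >= 0 & y <= 1))

  # deterministic given (seed, iteration); different iterations differ
  cfg2 <- psa_config(n_iterations = 5, seed = 11,
                     specs = default_psa_specs(m))
  expect_identical(sample_parameters(cfg2, 3), sample_parameters(cfg2, 3))
  expect_false(identical(sample_parameters(cfg2, 3),
                         sample_parameters(cfg2, 4)))
})

test_that("PSA runs are reproducible and degenerate runs hit the base case", {
  m <- orasel_model()
  cfg <- psa_config(n_iterations = 50, seed = 5,
                    specs = default_psa_specs(m))
  a <- run_psa(m, cfg)
  b <- run_psa(m, cfg)
  expect_identical(a$draws, b$draws)
  expect_identical(a$iterations, b$iterations)

  # all point distributions: every iteration equals the exact-arithmetic
  # deterministic base case
  pts <- lapply(default_psa_specs(m, mode = "deterministic"),
                function(s) dist_spec("point", s$base))
  deg <- run_psa(m, psa_config(n_iterations = 3, seed = 1, specs = pts))
  bc <- base_case(m, method = "exact")
  expect_equal(unique(deg$iterations$delta_cost), bc$delta_cost)
  expect_equal(unique(deg$iterations$total_cost_intervention),
               unname(bc$total_cost[["intervention"]]))
  expect_equal(unique(deg$iterations$icer_per_daly), bc$icer_per_daly)

  # single-iteration summary equals that iteration
  one <- run_psa(m, psa_config(n_iterations = 1, seed = 9,
                               specs = default_psa_specs(m)))
  s <- one$summary$stats
  expect_equal(s[s$quantity == "delta_cost", "mean"],
               one$iterations$delta_cost)
  expect_equal(s[s$quantity == "delta_cost", "median"],
               one$iterations$delta_cost)
  expect_equal(s[s$quantity == "delta_cost", "sd"], 0)
})

test_that("per-iteration ICER identity and perspective difference hold", {
  m <- orasel_model()
  psa <- run_psa(m, psa_config(n_iterations = 200, seed = 3,
                               specs = default_psa_specs(m)))
  it <- psa$iterations_societal
  expect_equal(it$dalys_averted,
               it$deaths_averted * m$daly$dalys_per_death)
  expect_equal(it$icer_per_daly, it$delta_cost / it$dalys_averted)

  # common random numbers: medical minus societal incremental cost equals
  # that draw's caregiver-time savings on untreated-episode mass
  med <- psa$iterations_medical
  p_no_int <- with(as.data.frame(psa$draws),
    p_seek_intervention * (1 - p_orsz_seek_intervention) +
      (1 - p_seek_intervention) * (1 - p_orsz_noseek_intervention))
  p_no_ctrl <- with(as.data.frame(psa$draws),
    p_seek_control * (1 - p_orsz_seek_control) +
      (1 - p_seek_control) * (1 - p_orsz_noseek_control))
  savings <- psa$draws[, "cost_caregiver_time"] * (p_no_ctrl - p_no_int) *
    m$frame$annual_cases
  expect_equal(med$delta_cost - it$delta_cost, savings)

  # triangular cost parameters average back to their base values
  specs <- psa$config$specs
  for (nm in c("cost_factory", "cost_consult_intervention")) {
    se <- (0.4 * specs[[nm]]$base / sqrt(6)) / sqrt(nrow(psa$draws))
    expect_lt(abs(mean(psa$draws[, nm]) - specs[[nm]]$base), 4 * se)
  }
})

test_that("ICER flags separate ratios, dominance and non-informative draws", {
  expect_equal(icer(15963, 65.63)$value, 243, tolerance = 1e-2)
  expect_equal(icer(15963, 65.63)$flag, "ratio")
  expect_equal(icer(0, 2)$value, 0)
  expect_equal(icer(-100, 2)$flag, "cost-saving")
  expect_equal(icer(100, 0)$flag, "non-informative")
  expect_true(is.na(icer(100, -1)$value))
})

test_that("summaries use n-1 SD, interpolated quartiles, ordered", {
  it <- data.frame(
    iteration = 1:2, total_cost_intervention = c(10, 10),
    total_cost_control = c(5, 5), delta_cost = c(1, 3),
    deaths_averted = c(1, 1), dalys_averted = c(27.06, 27.06),
    icer_per_death = c(1, 3), icer_per_daly = c(1, 3) / 27.06,
    icer_flag = "ratio", stringsAsFactors = FALSE
  )
  s <- summarize_psa(it)$stats
  dc <- s[s$quantity == "delta_cost", ]
  expect_equal(dc$median, 2)
  expect_equal(dc$sd, sd(c(1, 3)))
  # constant input: mean = median = constant, sd 0
  cst <- it; cst$delta_cost <- c(4, 4); cst$icer_per_death <- c(4, 4)
  sc <- summarize_psa(cst)$stats
  expect_equal(sc[sc$quantity == "delta_cost", "mean"], 4)
  expect_equal(sc[sc$quantity == "delta_cost", "median"], 4)
  expect_equal(sc[sc$quantity == "delta_cost", "sd"], 0)

  m <- orasel_model()
  psa <- run_psa(m, psa_config(n_iterations = 300, seed = 17,
                               specs = default_psa_specs(m)))
  st <- psa$summary$stats
  expect_true(all(st$q25 <= st$median & st$median <= st$q75))
  expect_error(summarize_psa(it[0, ]), class = "cea_invalid_parameter")
})

test_that("cost-saving fraction counts negative incremental cost", {
  it <- data.frame(delta_cost = c(1, 2, 3))
  expect_equal(cost_saving_fraction(it), 0)
  expect_equal(cost_saving_fraction(data.frame(delta_cost = -(1:4))), 1)
  expect_equal(cost_saving_fraction(data.frame(delta_cost = c(-1, 1))), 0.5)
})

test_that("tornado recovers known coefficients and handles degeneracy", {
  set.seed(31)
  n <- 400
  x <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 2 * x[, "x1"] + 0.3 * x[, "x2"] + rnorm(n, sd = 0.1)
  res <- tornado(x, y, k = 3)
  expect_equal(res$parameter[1], "x1")
  expect_equal(res$coefficient[1], 2, tolerance = 0.05)
  expect_equal(res$rank, 1:3)
  expect_true(all(diff(abs(res$coefficient)) <= 0))

  # output independent of all inputs: coefficients near zero
  y0 <- rnorm(n)
  res0 <- tornado(x, y0, k = 3)
  expect_true(all(abs(res0$coefficient) < 0.2))

  # collinear column is dropped and flagged
  xc <- cbind(x, x4 = x[, "x1"])
  resc <- tornado(xc, y, k = 4)
  expect_true("x4" %in% attr(resc, "dropped") ||
                "x1" %in% attr(resc, "dropped"))
})

test_that("GDP threshold classification uses strict inequalities", {
  expect_equal(threshold_classification(214, 876.2), "highly cost-effective")
  expect_equal(threshold_classification(876.2, 876.2), "cost-effective")
  expect_equal(threshold_classification(3000, 876.2), "not cost-effective")
  expect_equal(threshold_classification(3 * 876.2, 876.2),
               "not cost-effective")
  expect_error(threshold_classification(-1, 876.2),
               class = "cea_invalid_parameter")
})
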