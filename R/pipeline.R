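#' Run the full analysis pipeline and write report tables
#'
#' End-to-end run over the calibrated model: unit costs, node costs and
#' calibrated probabilities, the deterministic base case, the Monte Carlo
#' uncertainty analysis under the chosen perspective, the tornado
#' regression, and the cost-effectiveness-plane iteration data, written
#' as plain CSV tables (monetary columns tagged USD 2010) together with a
#' JSON run log recording the seed, RNG, iteration count and headline
#' results. Two runs with identical configuration and seed produce
#' byte-identical outputs.
#'
#' @param out_dir Output directory (created if missing).
#' @param model A `cea_model`, or a path to a YAML model configuration.
#' @param seed Integer seed for the Monte Carlo stage.
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param perspective `"societal"` or `"medical"`.
#' @param effect Coverage-increment estimator recorded in the run log:
#'   `"prepost"` (the headline 7.6-point pre-post difference) or `"did"`
#'   (difference-in-differences).
#' @param verbose Print progress messages.
#' @return Invisibly, a list with the written `paths`, the `base_case`
#'   list, the `psa` object and the coverage `increment` used.
#' @export
run_pipeline <- function(out_dir, model = orasel_model(), seed = 1,
                         n_iterations = 1000,
                         perspective = c("societal", "medical"),
                         effect = c("prepost", "did"), verbose = FALSE) {
  perspective <- match.arg(perspective)
  effect <- match.arg(effect)
  if (is.character(model)) model <- read_model_config(model)
  stopifnot(inherits(model, "cea_model"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  # -- table 1: unit costs -------------------------------------------------
  say("writing unit costs")
  ledger <- subsidy_ledger(model$chain)
  uc <- model$unit_costs
  table1 <- data.frame(
    item = c(names(uc), "subtotal_program_per_user",
             "subtotal_household_penalty", "retail_price", "subsidy"),
    unit_cost_usd2010 = c(
      unlist(uc, use.names = FALSE),
      unit_social_cost(model$chain),
      uc$hospitalization + uc$caregiver_time,
      model$chain$retail_price, model$chain$subsidy
    ),
    stringsAsFactors = FALSE
  )
  p_table1 <- file.path(out_dir, "table1.csv")
  utils::write.csv(table1, p_table1, row.names = FALSE, quote = FALSE)

  # -- table 2: node costs, probabilities, base-case totals ----------------
  say("writing decision-tree table")
  t2 <- do.call(rbind, lapply(names(model$arms), function(a) {
    cbind(arm = a, arm_table(model$arms[[a]]))
  }))
  names(t2) <- c("arm", "node_label", "cost_per_event_usd2010",
                 "probability", "cost_per_diarrhea_usd2010")
  p_table2 <- file.path(out_dir, "table2.csv")
  utils::write.csv(t2, p_table2, row.names = FALSE, quote = FALSE)

  bc <- base_case(model, perspective = perspective)

  # -- effectiveness increment --------------------------------------------
  increment <- if (effect == "prepost") {
    prepost_increment(model$coverage$intervention)
  } else {
    did_increment(model$coverage$intervention, model$coverage$control)
  }

  # -- PSA -----------------------------------------------------------------
  say("running ", n_iterations, " Monte Carlo iterations")
  config <- psa_config(
    n_iterations = n_iterations, seed = seed, perspective = perspective,
    specs = default_psa_specs(model, mode = "stochastic")
  )
  psa <- run_psa(model, config)
  s <- psa$summary$stats
  grab <- function(q, col) as.numeric(s[s$quantity == q, col])
  table3 <- data.frame(
    row = c("mean_1000_iterations", "sd", "median", "lower_quartile",
            "upper_quartile", "base_case_from_tree"),
    total_cost_intervention_usd2010 = c(
      grab("total_cost_intervention", c("mean", "sd", "median", "q25",
                                        "q75")),
      bc$total_cost[["intervention"]]
    ),
    total_cost_control_usd2010 = c(
      grab("total_cost_control", c("mean", "sd", "median", "q25", "q75")),
      bc$total_cost[["control"]]
    ),
    dalys_averted = c(
      grab("dalys_averted", c("mean", "sd", "median", "q25", "q75")),
      bc$dalys_averted
    ),
    deaths_averted = c(
      grab("deaths_averted", c("mean", "sd", "median", "q25", "q75")),
      bc$deaths_averted
    ),
    incremental_cost_usd2010 = c(
      grab("delta_cost", c("mean", "sd", "median", "q25", "q75")),
      bc$delta_cost
    ),
    incremental_cost_per_daly_usd2010 = c(
      grab("icer_per_daly", c("mean", "sd", "median", "q25", "q75")),
      bc$icer_per_daly
    ),
    incremental_cost_per_death_usd2010 = c(
      grab("icer_per_death", c("mean", "sd", "median", "q25", "q75")),
      bc$icer_per_death
    ),
    stringsAsFactors = FALSE
  )
  p_table3 <- file.path(out_dir, "table3.csv")
  utils::write.csv(table3, p_table3, row.names = FALSE, quote = FALSE)

  p_iter <- file.path(out_dir, "iterations.csv")
  utils::write.csv(psa$iterations, p_iter, row.names = FALSE, quote = FALSE)

  say("tornado regression")
  torn <- if (nrow(psa$draws) > ncol(psa$draws) + 1L) {
    tornado(psa$draws, psa$iterations$icer_per_daly, k = 7)
  } else {
    # too few draws to regress on every parameter; emit an empty table
    data.frame(parameter = character(), coefficient = numeric(),
               rank = integer())
  }
  p_torn <- file.path(out_dir, "tornado.csv")
  utils::write.csv(torn, p_torn, row.names = FALSE, quote = FALSE)

  # -- run log -------------------------------------------------------------
  med_daly <- grab("icer_per_daly", "median")
  log <- list(
    seed = seed,
    n_iterations = n_iterations,
    perspective = perspective,
    effect_estimator = effect,
    coverage_increment_points = increment,
    rng = "Mersenne-Twister",
    package_version = as.character(utils::packageVersion("franchiseCEA")),
    base_case = list(
      delta_cost = bc$delta_cost,
      icer_per_daly = bc$icer_per_daly,
      icer_per_death = bc$icer_per_death
    ),
    psa = list(
      mean_delta_cost = grab("delta_cost", "mean"),
      median_icer_per_daly = med_daly,
      median_icer_per_death = grab("icer_per_death", "median"),
      fraction_cost_saving = psa$summary$fraction_cost_saving
    ),
    threshold = list(
      gdp_per_capita = model$gdp_per_capita,
      classification = threshold_classification(med_daly,
                                                model$gdp_per_capita)
    )
  )
  p_log <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, p_log, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(
    paths = c(table1 = p_table1, table2 = p_table2, table3 = p_table3,
              iterations = p_iter, tornado = p_torn, run_log = p_log),
    base_case = bc,
    psa = psa,
    increment = increment
  ))
}
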