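#' The ORASEL social-franchise cost-effectiveness model
#'
#' Assembles the full published parameter set: the per-kit value chain
#' (factory production $0.35, packaging $0.02, launch amortization $0.07,
#' administration overhead $0.09, franchise distribution $0.13, retail
#' service $0.12; retail price $0.35 against a $0.43 donor subsidy),
#' per-arm consultation costs ($2.00 treatment area, $1.50 control area),
#' the household penalty of an untreated episode (expected hospitalization
#' $0.07 plus a day of caregiver time $1.28), the per-event and
#' per-diarrhea node-cost columns from which node probabilities are
#' calibrated, the standard population frame, the DALY conversion, the
#' deaths-averted parameterization, the survey coverage proportions, and
#' the 2010 GDP per capita used for threshold classification.
#'
#' In the control arm ORS-Z carries only the factory cost (no franchise
#' chain) and the household penalty carries only the caregiver-time
#' component, matching the published node-cost footnotes.
#'
#' @return An object of class `cea_model`: a list with elements `chain`,
#'   `unit_costs`, `table2`, `arms` (calibrated [arm_model()]s), `frame`,
#'   `daly`, `mortality`, `coverage`, `survey_design`, `gdp_per_capita`.
#' @export
orasel_model <- function() {
  chain <- value_chain(
    rbind(
      cost_component("factory", 0.35, "donor", 1),
      cost_component("packaging", 0.02, "donor", 2),
      cost_component("launch", 0.07, "donor", 3),
      cost_component("administration", 0.09, "donor", 4),
      cost_component("distribution", 0.13, "donor", 5),
      cost_component("retail", 0.12, "provider", 6)
    ),
    retail_price = 0.35,
    subsidy = 0.43
  )
  unit_costs <- list(
    factory = 0.35, packaging = 0.02, launch = 0.07,
    administration = 0.09, distribution = 0.13, retail = 0.12,
    hospitalization = 0.07, caregiver_time = 1.28,
    consult_intervention = 2.00, consult_control = 1.50
  )
  table2 <- list(
    intervention = list(
      per_event = c(A = 2.78, B = 3.35, C = 0.78, D = 1.35),
      per_diarrhea = c(A = 0.21, B = 1.34, C = 0.11, D = 0.50)
    ),
    control = list(
      per_event = c(A = 1.85, B = 2.78, C = 0.35, D = 1.28),
      per_diarrhea = c(A = 0.05, B = 1.09, C = 0.01, D = 0.68)
    )
  )
  p_int <- calibrate_node_probabilities(
    table2$intervention$per_event, table2$intervention$per_diarrhea
  )
  p_ctrl <- calibrate_node_probabilities(
    table2$control$per_event, table2$control$per_diarrhea
  )
  orsz_int <- unit_social_cost(chain)           # 0.78, full chain
  orsz_ctrl <- unit_costs$factory               # 0.35, commodity only
  penalty_int <- unit_costs$hospitalization + unit_costs$caregiver_time
  penalty_ctrl <- unit_costs$caregiver_time
  arms <- list(
    intervention = arm_model(
      "intervention",
      consultation_cost = unit_costs$consult_intervention,
      orsz_unit_cost = orsz_int,
      household_penalty = penalty_int,
      probabilities = p_int
    ),
    control = arm_model(
      "control",
      consultation_cost = unit_costs$consult_control,
      orsz_unit_cost = orsz_ctrl,
      household_penalty = penalty_ctrl,
      probabilities = p_ctrl
    )
  )
  coverage <- list(
    intervention = coverage_change(
      "intervention",
      pre = coverage_estimate(0.061, 3200),
      post = coverage_estimate(0.137, 3200)
    ),
    control = coverage_change(
      "control",
      pre = coverage_estimate(0.048, 3382),
      post = coverage_estimate(0.018, 3382)
    )
  )
  structure(
    list(
      chain = chain,
      unit_costs = unit_costs,
      table2 = table2,
      arms = arms,
      frame = population_frame(),
      daly = daly_parameters(),
      mortality = mortality_effect(),
      coverage = coverage,
      survey_design = survey_design(),
      gdp_per_capita = 876.2
    ),
    class = "cea_model"
  )
}

#' Deterministic base case of the model
#'
#' Per-arm expected cost per episode, population totals, incremental cost,
#' deaths and DALYs averted, and the two ICERs, all without parameter
#' uncertainty. Deaths averted default to the deterministic base-case
#' parameterization. The arithmetic convention follows
#' [expected_cost_per_case()]: `"as-printed"` reproduces the published
#' base-case row to the printed rounding.
#'
#' @param model A [orasel_model()]-shaped `cea_model`.
#' @param method `"as-printed"` (default) or `"exact"`.
#' @param perspective `"societal"` (default) or `"medical"`.
#' @return A list with per-case costs, totals, `delta_cost`,
#'   `deaths_averted`, `dalys_averted`, `icer_per_death`, `icer_per_daly`.
#' @export
base_case <- function(model = orasel_model(),
                      method = c("as-printed", "exact"),
                      perspective = c("societal", "medical")) {
  method <- match.arg(method)
  perspective <- match.arg(perspective)
  arms <- model$arms
  if (perspective == "medical") {
    arms <- lapply(arms, strip_caregiver_time, model = model)
  }
  per_case <- vapply(arms, expected_cost_per_case, numeric(1),
                     method = method)
  totals <- vapply(per_case, scale_to_population, numeric(1),
                   frame = model$frame)
  delta <- totals[["intervention"]] - totals[["control"]]
  deaths <- model$mortality$deaths_averted_base
  dalys <- deaths_to_dalys(deaths, model$daly)
  list(
    perspective = perspective,
    method = method,
    cost_per_case = per_case,
    total_cost = totals,
    delta_cost = delta,
    deaths_averted = deaths,
    dalys_averted = dalys,
    icer_per_death = icer(delta, deaths)$value,
    icer_per_daly = icer(delta, dalys)$value
  )
}

# Rebuild an arm with the caregiver-time valuation removed from the
# household penalty (the medical-perspective costing scope).
strip_caregiver_time <- function(arm, model) {
  penalty <- arm$household_penalty - model$unit_costs$caregiver_time
  arm_model(
    arm$arm,
    consultation_cost = arm$consultation_cost,
    orsz_unit_cost = arm$orsz_unit_cost,
    household_penalty = max(penalty, 0),
    probabilities = arm$node_probabilities
  )
}

#' Write / read the model configuration as YAML
#'
#' Serializes the scalar parameter set (unit costs, node-cost columns,
#' population frame, DALY and mortality parameters, coverage proportions,
#' GDP per capita) so a run is reproducible from a plain-text config.
#' Reading rebuilds the calibrated model from those parameters.
#'
#' @param model A `cea_model`.
#' @param path YAML file path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a `cea_model`.
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    unit_costs = model$unit_costs,
    retail_price = model$chain$retail_price,
    subsidy = model$chain$subsidy,
    table2 = lapply(model$table2, function(a) lapply(a, as.list)),
    frame = list(
      total_population = model$frame$total_population,
      under5_fraction = model$frame$under5_fraction,
      annual_cases = model$frame$annual_cases,
      incidence = model$frame$incidence
    ),
    daly = list(dalys_per_death = model$daly$dalys_per_death,
                discount_rate = model$daly$discount_rate,
                life_expectancy = model$daly$life_expectancy),
    mortality = list(
      deaths_averted_base = model$mortality$deaths_averted_base,
      deaths_averted_mean = model$mortality$deaths_averted_mean,
      deaths_averted_sd = model$mortality$deaths_averted_sd
    ),
    coverage = lapply(model$coverage, function(ch) list(
      arm = ch$arm,
      pre = list(proportion = ch$pre$proportion, n = ch$pre$n),
      post = list(proportion = ch$post$proportion, n = ch$post$n)
    )),
    gdp_per_capita = model$gdp_per_capita
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    invalid_parameter(paste("model configuration file not found:", path))
  }
  cfg <- yaml::read_yaml(path)
  model <- orasel_model()
  uc <- utils::modifyList(model$unit_costs, cfg$unit_costs %||% list())
  t2 <- model$table2
  if (!is.null(cfg$table2)) {
    for (a in names(cfg$table2)) {
      for (col in names(cfg$table2[[a]])) {
        t2[[a]][[col]] <- stats::setNames(
          as.numeric(unlist(cfg$table2[[a]][[col]])),
          names(unlist(cfg$table2[[a]][[col]]))
        )
      }
    }
  }
  p_int <- calibrate_node_probabilities(t2$intervention$per_event,
                                        t2$intervention$per_diarrhea)
  p_ctrl <- calibrate_node_probabilities(t2$control$per_event,
                                         t2$control$per_diarrhea)
  orsz_int <- uc$factory + uc$packaging + uc$launch + uc$administration +
    uc$distribution + uc$retail
  model$unit_costs <- uc
  model$table2 <- t2
  model$arms <- list(
    intervention = arm_model("intervention", uc$consult_intervention,
                             orsz_int, uc$hospitalization + uc$caregiver_time,
                             p_int),
    control = arm_model("control", uc$consult_control, uc$factory,
                        uc$caregiver_time, p_ctrl)
  )
  if (!is.null(cfg$frame)) {
    model$frame <- population_frame(
      cfg$frame$total_population, cfg$frame$under5_fraction,
      cfg$frame$annual_cases, cfg$frame$incidence
    )
  }
  if (!is.null(cfg$daly)) {
    model$daly <- daly_parameters(
      dalys_per_death = cfg$daly$dalys_per_death,
      discount_rate = cfg$daly$discount_rate,
      life_expectancy = cfg$daly$life_expectancy
    )
  }
  if (!is.null(cfg$mortality)) {
    model$mortality <- mortality_effect(
      deaths_averted_base = cfg$mortality$deaths_averted_base,
      deaths_averted_mean = cfg$mortality$deaths_averted_mean,
      deaths_averted_sd = cfg$mortality$deaths_averted_sd
    )
  }
  if (!is.null(cfg$gdp_per_capita)) {
    model$gdp_per_capita <- cfg$gdp_per_capita
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
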