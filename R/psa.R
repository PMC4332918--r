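#' Distribution specification for one model parameter
#'
#' Cost parameters carry triangular distributions with minimum and maximum
#' at +/- 20% of the base value (the published sensitivity range);
#' probability parameters carry normal distributions centred on the
#' observed proportion, truncated to \[0, 1\] by rejection; `point` pins
#' the parameter at its base value (degenerate run).
#'
#' @param kind `"triangular"`, `"normal"`, or `"point"`.
#' @param base Base-case value (triangular mode; normal mean).
#' @param sd Standard deviation (normal only).
#' @param min,max Triangular bounds; default `0.8 * base` / `1.2 * base`.
#' @param truncation Length-2 `c(lo, hi)` truncation interval, or `NULL`.
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(kind = c("triangular", "normal", "point"), base,
                      sd = NULL, min = 0.8 * base, max = 1.2 * base,
                      truncation = NULL) {
  kind <- match.arg(kind)
  if (kind == "triangular" && !(min <= base && base <= max)) {
    invalid_parameter("triangular requires min <= mode <= max")
  }
  if (kind == "normal" && (is.null(sd) || sd < 0)) {
    invalid_parameter("normal spec requires a non-negative sd")
  }
  if (!is.null(truncation) &&
      (length(truncation) != 2L || truncation[1] > truncation[2])) {
    invalid_parameter("truncation bounds must be ordered c(lo, hi)")
  }
  structure(
    list(kind = kind, base = base, sd = sd, min = min, max = max,
         truncation = truncation),
    class = "dist_spec"
  )
}

# Inverse-CDF triangular sampler.
rtriangular <- function(n, min, mode, max) {
  if (max <= min) return(rep(mode, n))
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

# Rejection-sampled truncated normal.
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
    guard <- guard + 1L
    if (guard > 10000L) {
      invalid_parameter("truncated-normal rejection failed to converge")
    }
  }
  out[seq_len(n)]
}

# One draw from a dist_spec (assumes RNG state already set by caller).
draw_spec <- function(spec) {
  x <- switch(spec$kind,
    point = spec$base,
    triangular = rtriangular(1L, spec$min, spec$base, spec$max),
    normal = {
      tr <- spec$truncation %||% c(-Inf, Inf)
      rtnorm(1L, spec$base, spec$sd, tr[1], tr[2])
    }
  )
  if (spec$kind == "triangular" && !is.null(spec$truncation)) {
    x <- pmin(pmax(x, spec$truncation[1]), spec$truncation[2])
  }
  x
}

#' Default distribution specifications for the ORASEL model
#'
#' Every unit-cost parameter gets triangular(0.8 base, base, 1.2 base).
#' The six branch probabilities (care-seeking and the two conditional
#' ORS-Z receipt probabilities, per arm) get truncated normals centred on
#' the calibrated values with binomial standard errors whose denominators
#' are the expected episode counts implied by the household-survey design
#' (households x episodes per child-year, and the expected seek / no-seek
#' subsets for the conditional probabilities). Deaths averted is
#' Normal(mean, sd) truncated at zero in `"stochastic"` mode and a point
#' mass at the deterministic base value in `"deterministic"` mode.
#'
#' @param model A `cea_model`.
#' @param mode `"stochastic"` (default) or `"deterministic"` deaths.
#' @return Named list of [dist_spec()] objects.
#' @export
default_psa_specs <- function(model = orasel_model(),
                              mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  uc <- model$unit_costs
  specs <- lapply(uc, function(b) dist_spec("triangular", b))
  names(specs) <- paste0("cost_", names(uc))

  des <- model$survey_design
  p_episode <- des$incidence / 100
  n_ep <- c(intervention = des$n_intervention * p_episode,
            control = des$n_control * p_episode)
  for (arm in c("intervention", "control")) {
    bp <- branch_from_node_probabilities(
      model$arms[[arm]]$node_probabilities
    )
    n <- n_ep[[arm]]
    n_seek <- n * bp$p_seek
    n_noseek <- n * (1 - bp$p_seek)
    specs[[paste0("p_seek_", arm)]] <- dist_spec(
      "normal", bp$p_seek, sd = binomial_se(bp$p_seek, n),
      truncation = c(0, 1)
    )
    specs[[paste0("p_orsz_seek_", arm)]] <- dist_spec(
      "normal", bp$p_orsz_given_seek,
      sd = binomial_se(bp$p_orsz_given_seek, n_seek),
      truncation = c(0, 1)
    )
    specs[[paste0("p_orsz_noseek_", arm)]] <- dist_spec(
      "normal", bp$p_orsz_given_noseek,
      sd = binomial_se(bp$p_orsz_given_noseek, n_noseek),
      truncation = c(0, 1)
    )
  }
  specs$deaths_averted <- if (mode == "stochastic") {
    dist_spec("normal", model$mortality$deaths_averted_mean,
              sd = model$mortality$deaths_averted_sd,
              truncation = c(0, Inf))
  } else {
    dist_spec("point", model$mortality$deaths_averted_base)
  }
  specs
}

#' Configuration for a probabilistic sensitivity analysis run
#'
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param seed Integer seed; every source of randomness in the run derives
#'   from it.
#' @param perspective `"societal"` or `"medical"`.
#' @param specs Named list of [dist_spec()]s (default
#'   [default_psa_specs()]).
#' @return An object of class `psa_config`.
#' @export
psa_config <- function(n_iterations = 1000, seed = 1,
                       perspective = c("societal", "medical"),
                       specs = default_psa_specs()) {
  if (n_iterations < 1) invalid_parameter("n_iterations must be >= 1")
  perspective <- match.arg(perspective)
  if (!length(specs) || is.null(names(specs)) || any(names(specs) == "")) {
    invalid_parameter("specs must be a fully named list of dist_spec")
  }
  structure(
    list(n_iterations = as.integer(n_iterations), seed = as.integer(seed),
         perspective = perspective, specs = specs),
    class = "psa_config"
  )
}

# Deterministic per-iteration substream seed (kept below 2^31).
psa_iteration_seed <- function(seed, iteration_index) {
  as.integer((abs(as.numeric(seed)) + iteration_index * 2654435761) %%
               2147483647)
}

#' Draw one full parameter realization
#'
#' Deterministic given `(config$seed, iteration_index)`: each iteration
#' seeds its own Mersenne-Twister substream, and parameters are drawn in
#' the fixed order of `config$specs`.
#'
#' @param config A [psa_config()].
#' @param iteration_index Iteration number (1-based).
#' @return Named numeric vector, one value per parameter.
#' @export
sample_parameters <- function(config, iteration_index) {
  stopifnot(inherits(config, "psa_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  suppressWarnings(set.seed(psa_iteration_seed(config$seed, iteration_index),
                            kind = "Mersenne-Twister"))
  vapply(config$specs, draw_spec, numeric(1))
}

# Evaluate the decision-tree model on a matrix of parameter draws
# (rows = iterations) under one costing perspective. Exact fold-back
# arithmetic; common random numbers across arms and perspectives follow
# from reusing the same draw matrix.
evaluate_draws <- function(draws, model, perspective = "societal") {
  g <- function(nm) draws[, nm]
  orsz_int <- g("cost_factory") + g("cost_packaging") + g("cost_launch") +
    g("cost_administration") + g("cost_distribution") + g("cost_retail")
  orsz_ctrl <- g("cost_factory")
  if (perspective == "societal") {
    pen_int <- g("cost_hospitalization") + g("cost_caregiver_time")
    pen_ctrl <- g("cost_caregiver_time")
  } else {
    pen_int <- g("cost_hospitalization")
    pen_ctrl <- 0
  }
  per_case <- function(s, os, on, consult, orsz, pen) {
    s * (os * (consult + orsz) + (1 - os) * (consult + pen)) +
      (1 - s) * (on * orsz + (1 - on) * pen)
  }
  e_int <- per_case(g("p_seek_intervention"),
                    g("p_orsz_seek_intervention"),
                    g("p_orsz_noseek_intervention"),
                    g("cost_consult_intervention"), orsz_int, pen_int)
  e_ctrl <- per_case(g("p_seek_control"), g("p_orsz_seek_control"),
                     g("p_orsz_noseek_control"),
                     g("cost_consult_control"), orsz_ctrl, pen_ctrl)
  cases <- model$frame$annual_cases
  deaths <- g("deaths_averted")
  dalys <- deaths_to_dalys(deaths, model$daly)
  delta <- (e_int - e_ctrl) * cases
  data.frame(
    iteration = seq_len(nrow(draws)),
    total_cost_intervention = e_int * cases,
    total_cost_control = e_ctrl * cases,
    delta_cost = delta,
    deaths_averted = deaths,
    dalys_averted = dalys,
    icer_per_death = ifelse(deaths > 0, delta / deaths, NA_real_),
    icer_per_daly = ifelse(dalys > 0, delta / dalys, NA_real_),
    icer_flag = ifelse(dalys <= 0, "non-informative",
                       ifelse(delta < 0, "cost-saving", "ratio")),
    stringsAsFactors = FALSE
  )
}

#' Run the second-order Monte Carlo analysis
#'
#' Draws `n_iterations` full parameter realizations, folds back the
#' decision tree under each, and scales to the standard population. Both
#' costing perspectives are evaluated on the same draws (common random
#' numbers), so per-iteration perspective differences isolate the
#' caregiver-time component. Reproducible: identical `(seed, config)`
#' give identical results.
#'
#' @param model A `cea_model`.
#' @param config A [psa_config()].
#' @return An object of class `cea_psa`: list with `config`, `draws`
#'   (iterations x parameters matrix), `iterations` (the configured
#'   perspective), `iterations_medical`, `iterations_societal`, and
#'   `summary` ([summarize_psa()] of the configured perspective).
#' @export
run_psa <- function(model = orasel_model(),
                    config = psa_config(specs = default_psa_specs(model))) {
  stopifnot(inherits(config, "psa_config"))
  draws <- t(vapply(
    seq_len(config$n_iterations),
    function(i) sample_parameters(config, i),
    numeric(length(config$specs))
  ))
  colnames(draws) <- names(config$specs)
  soc <- evaluate_draws(draws, model, "societal")
  med <- evaluate_draws(draws, model, "medical")
  primary <- if (config$perspective == "societal") soc else med
  structure(
    list(
      config = config,
      draws = draws,
      iterations = primary,
      iterations_societal = soc,
      iterations_medical = med,
      summary = summarize_psa(primary)
    ),
    class = "cea_psa"
  )
}

#' Incremental cost-effectiveness ratio with dominance flags
#'
#' `delta_cost / delta_effect` when the effect gain is positive. A
#' positive effect bought at negative cost is flagged `"cost-saving"`
#' (dominant); a non-positive effect change makes the ratio
#' non-informative and is flagged and excluded from ratio summaries.
#'
#' @param delta_cost Incremental cost, USD.
#' @param delta_effect Incremental effect (deaths or DALYs averted).
#' @return List with `value` (the ratio, or `NA` when non-informative)
#'   and `flag` (`"ratio"`, `"cost-saving"`, `"non-informative"`).
#' @export
icer <- function(delta_cost, delta_effect) {
  if (delta_effect <= 0) {
    return(list(value = NA_real_, flag = "non-informative"))
  }
  list(value = delta_cost / delta_effect,
       flag = if (delta_cost < 0) "cost-saving" else "ratio")
}

#' Summary statistics over PSA iterations
#'
#' Mean, SD (denominator n-1), median and quartiles (linear interpolation
#' between order statistics) for each monitored quantity. ICER rows are
#' computed over the iterations with positive effect gain only
#' (non-informative iterations are counted separately); the
#' ratio-of-means ICERs (mean incremental cost over mean incremental
#' effect, the published "Avg"-row arithmetic) are also reported.
#'
#' @param iterations An iteration `data.frame` from [run_psa()].
#' @return An object of class `psa_summary`: list with `stats` (one row
#'   per quantity), `fraction_cost_saving`, `n_non_informative`, and
#'   `icer_of_means` (per death and per DALY).
#' @export
summarize_psa <- function(iterations) {
  if (is.null(iterations) || nrow(iterations) < 1L) {
    invalid_parameter("summarize_psa needs at least one iteration")
  }
  quantities <- c("total_cost_intervention", "total_cost_control",
                  "delta_cost", "deaths_averted", "dalys_averted",
                  "icer_per_death", "icer_per_daly")
  informative <- iterations$icer_flag != "non-informative"
  one <- function(q) {
    x <- iterations[[q]]
    if (startsWith(q, "icer_")) x <- x[informative]
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(
      quantity = q, mean = mean(x),
      sd = if (length(x) > 1L) stats::sd(x) else 0,
      q25 = qs[1], median = qs[2], q75 = qs[3],
      stringsAsFactors = FALSE
    )
  }
  stats_df <- do.call(rbind, lapply(quantities, one))
  mean_dc <- mean(iterations$delta_cost)
  structure(
    list(
      stats = stats_df,
      fraction_cost_saving = mean(iterations$delta_cost < 0),
      n_non_informative = sum(!informative),
      icer_of_means = c(
        per_death = mean_dc / mean(iterations$deaths_averted),
        per_daly = mean_dc / mean(iterations$dalys_averted)
      )
    ),
    class = "psa_summary"
  )
}

#' Tornado sensitivity regression
#'
#' Ordinary least squares of the output (per-iteration ICER) on the
#' z-standardized parameter draws; parameters are ranked by the absolute
#' value of their standardized coefficients and the top `k` returned.
#' Zero-variance and collinear (aliased) columns are dropped and reported.
#'
#' @param inputs Draws-by-parameters numeric matrix.
#' @param output Numeric vector, one model output per draw.
#' @param k Number of leading parameters to return (default 7).
#' @return A `data.frame` with `parameter`, `coefficient`, `rank`
#'   (ordered by descending `|coefficient|`, `rank` 1 first), carrying a
#'   `dropped` attribute naming excluded columns.
#' @export
tornado <- function(inputs, output, k = 7) {
  stopifnot(is.matrix(inputs) || is.data.frame(inputs))
  inputs <- as.matrix(inputs)
  keep <- !is.na(output)
  inputs <- inputs[keep, , drop = FALSE]
  output <- output[keep]
  if (nrow(inputs) < ncol(inputs) + 1L) {
    invalid_parameter("tornado needs at least parameters + 1 draws")
  }
  sds <- apply(inputs, 2, stats::sd)
  dropped <- colnames(inputs)[sds == 0]
  use <- inputs[, sds > 0, drop = FALSE]
  z <- scale(use)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, z), output)
  coefs <- fit$coefficients[-1]
  aliased <- names(coefs)[is.na(coefs)]
  dropped <- c(dropped, aliased)
  coefs <- coefs[!is.na(coefs)]
  ord <- order(abs(coefs), decreasing = TRUE)
  coefs <- coefs[ord]
  out <- data.frame(
    parameter = names(coefs),
    coefficient = unname(coefs),
    rank = seq_along(coefs),
    stringsAsFactors = FALSE
  )[seq_len(min(k, length(coefs))), ]
  attr(out, "dropped") <- dropped
  rownames(out) <- NULL
  out
}

#' Fraction of iterations in which the intervention is cost saving
#'
#' @param iterations An iteration `data.frame` from [run_psa()].
#' @return Proportion of iterations with negative incremental cost.
#' @export
cost_saving_fraction <- function(iterations) {
  if (nrow(iterations) < 1L) invalid_parameter("needs >= 1 iteration")
  mean(iterations$delta_cost < 0)
}

#' Classify an ICER against GDP-per-capita thresholds
#'
#' The Commission on Macroeconomics and Health convention: strictly below
#' one GDP per capita per DALY averted is highly cost-effective, strictly
#' below three times is cost-effective, otherwise not cost-effective.
#'
#' @param icer_per_daly ICER, USD per DALY averted.
#' @param gdp_per_capita GDP per capita, USD.
#' @return One of `"highly cost-effective"`, `"cost-effective"`,
#'   `"not cost-effective"`.
#' @export
threshold_classification <- function(icer_per_daly, gdp_per_capita) {
  if (icer_per_daly <= 0 || gdp_per_capita <= 0) {
    invalid_parameter("ICER and GDP per capita must be positive")
  }
  if (icer_per_daly < gdp_per_capita) return("highly cost-effective")
  if (icer_per_daly < 3 * gdp_per_capita) return("cost-effective")
  "not cost-effective"
}
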