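#' Terminal-node cost for a diarrhea episode pathway
#'
#' A pathway through the episode decision tree incurs the consultation cost
#' if formal care was sought, the commodity (ORS-Z) cost if the child
#' received it, and the household penalty (expected hospitalization plus
#' caregiver time lost to the extra day of illness) if it did not.
#'
#' @param consultation Consultation cost, USD (0 if no care sought).
#' @param orsz ORS-Z unit cost, USD (0 if not received).
#' @param household_penalty Household cost of an untreated episode, USD
#'   (0 if ORS-Z received).
#' @return Node cost per event, USD.
#' @export
node_cost <- function(consultation, orsz, household_penalty) {
  if (any(c(consultation, orsz, household_penalty) < 0)) {
    invalid_parameter("node cost components must be non-negative")
  }
  consultation + orsz + household_penalty
}

#' Branch probabilities for one study arm
#'
#' The tree first splits on whether formal care is sought, then on whether
#' the child receives ORS-Z conditional on that choice, yielding four
#' terminal nodes: A (seek, ORS-Z), B (seek, none), C (no-seek, ORS-Z),
#' D (no-seek, none).
#'
#' @param p_seek Probability of seeking formal care.
#' @param p_orsz_given_seek Probability of receiving ORS-Z if seen.
#' @param p_orsz_given_noseek Probability of receiving ORS-Z if not seen.
#' @return An object of class `arm_probabilities`.
#' @export
arm_probabilities <- function(p_seek, p_orsz_given_seek,
                              p_orsz_given_noseek) {
  p <- c(p_seek, p_orsz_given_seek, p_orsz_given_noseek)
  if (any(p < 0 | p > 1)) {
    invalid_parameter("branch probabilities must lie in [0, 1]")
  }
  structure(
    list(
      p_seek = p_seek,
      p_orsz_given_seek = p_orsz_given_seek,
      p_orsz_given_noseek = p_orsz_given_noseek
    ),
    class = "arm_probabilities"
  )
}

#' Marginal probability of receiving any ORS-Z
#'
#' Total-probability (Bayes'-rule) combination of the two conditional
#' receipt probabilities: `p_seek * p(ORS-Z | seen) + (1 - p_seek) *
#' p(ORS-Z | not seen)`; equals the probability mass of terminal nodes
#' A and C.
#'
#' @param p An [arm_probabilities()].
#' @return Marginal ORS-Z coverage among episodes, in \[0, 1\].
#' @export
any_orsz_coverage <- function(p) {
  stopifnot(inherits(p, "arm_probabilities"))
  p$p_seek * p$p_orsz_given_seek +
    (1 - p$p_seek) * p$p_orsz_given_noseek
}

#' Terminal-node probabilities implied by branch probabilities
#'
#' @param p An [arm_probabilities()].
#' @return Named numeric vector over nodes `A`, `B`, `C`, `D`, summing
#'   to 1.
#' @export
node_probabilities <- function(p) {
  stopifnot(inherits(p, "arm_probabilities"))
  s <- p$p_seek
  c(
    A = s * p$p_orsz_given_seek,
    B = s * (1 - p$p_orsz_given_seek),
    C = (1 - s) * p$p_orsz_given_noseek,
    D = (1 - s) * (1 - p$p_orsz_given_noseek)
  )
}

#' Back out branch probabilities from terminal-node probabilities
#'
#' Inverse of [node_probabilities()]; exact for any node distribution with
#' positive mass on both the seek and no-seek branches.
#'
#' @param node_p Named numeric vector over `A`, `B`, `C`, `D`.
#' @return An [arm_probabilities()].
#' @export
branch_from_node_probabilities <- function(node_p) {
  s <- node_p[["A"]] + node_p[["B"]]
  arm_probabilities(
    p_seek = s,
    p_orsz_given_seek = if (s > 0) node_p[["A"]] / s else 0,
    p_orsz_given_noseek = if (s < 1) node_p[["C"]] / (1 - s) else 0
  )
}

#' Calibrate terminal-node probabilities from printed cost columns
#'
#' The study tables print, per terminal node, the cost per event `c_i` and
#' the probability-weighted cost per diarrhea `r_i = p_i * c_i` rounded to
#' the cent — but not the probabilities themselves. This back-derives a
#' probability vector that (a) sums to one exactly and (b) keeps every
#' `p_i * c_i` within the half-cent rounding slack of the printed cell,
#' i.e. `|p_i - r_i/c_i| <= 0.005 / c_i`. The naive ratios typically sum
#' to slightly less than one (the rounding losses); the shortfall is
#' distributed across nodes in proportion to each node's slack width,
#' which stays inside every box constraint whenever the constraint set is
#' feasible at all.
#'
#' @param per_event_costs Numeric vector of per-event node costs `c_i`
#'   (USD), strictly positive where the per-diarrhea cost is positive.
#' @param per_diarrhea_costs Numeric vector of printed per-diarrhea costs
#'   `r_i` (USD, cent precision).
#' @return Named numeric vector of node probabilities (names taken from
#'   `per_event_costs` or `A`,`B`,... by position), summing to 1.
#' @export
calibrate_node_probabilities <- function(per_event_costs,
                                         per_diarrhea_costs) {
  stopifnot(length(per_event_costs) == length(per_diarrhea_costs))
  if (any(per_event_costs <= 0 & per_diarrhea_costs > 0)) {
    invalid_parameter(
      "per-event cost must be positive wherever per-diarrhea cost is"
    )
  }
  ratio <- ifelse(per_event_costs > 0,
                  per_diarrhea_costs / per_event_costs, 0)
  slack <- ifelse(per_event_costs > 0, 0.005 / per_event_costs, 0)
  gap <- 1 - sum(ratio)
  if (abs(gap) > sum(slack) + 1e-12) {
    calibration_failure(sprintf(
      "probabilities cannot sum to 1 within rounding slack (residual %.6f)",
      abs(gap) - sum(slack)
    ))
  }
  p <- ratio + gap * slack / sum(slack)
  if (any(p < -1e-12 | p > 1 + 1e-12)) {
    calibration_failure("calibrated probability outside [0, 1]")
  }
  p <- pmin(pmax(p, 0), 1)
  # verify the round-trip: probabilities must reproduce the printed cents
  cells <- round(p * per_event_costs, 2)
  bad <- which(abs(cells - round(per_diarrhea_costs, 2)) > 1e-9)
  if (length(bad)) {
    calibration_failure(sprintf(
      "calibrated probabilities fail to reproduce printed cell(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  names(p) <- if (!is.null(names(per_event_costs))) {
    names(per_event_costs)
  } else {
    LETTERS[seq_along(p)]
  }
  p
}

#' Construct one arm of the episode decision tree
#'
#' @param arm `"intervention"` or `"control"`.
#' @param consultation_cost Consultation cost per visit, USD.
#' @param orsz_unit_cost Societal unit cost of ORS-Z in this arm, USD (the
#'   full value-chain cost where the franchise distributes it, the factory
#'   cost where it does not).
#' @param household_penalty Household cost when ORS-Z is not received, USD.
#' @param probabilities An [arm_probabilities()], or a named node
#'   probability vector over `A`..`D`.
#' @return An object of class `arm_model` with per-event node costs and
#'   node probabilities.
#' @export
arm_model <- function(arm = c("intervention", "control"),
                      consultation_cost, orsz_unit_cost,
                      household_penalty, probabilities) {
  arm <- match.arg(arm)
  node_p <- if (inherits(probabilities, "arm_probabilities")) {
    node_probabilities(probabilities)
  } else {
    stopifnot(all(c("A", "B", "C", "D") %in% names(probabilities)))
    probabilities[c("A", "B", "C", "D")]
  }
  if (abs(sum(node_p) - 1) > 1e-9) {
    invalid_model("node probabilities must sum to 1 within 1e-9")
  }
  costs <- c(
    A = node_cost(consultation_cost, orsz_unit_cost, 0),
    B = node_cost(consultation_cost, 0, household_penalty),
    C = node_cost(0, orsz_unit_cost, 0),
    D = node_cost(0, 0, household_penalty)
  )
  structure(
    list(
      arm = arm,
      consultation_cost = consultation_cost,
      orsz_unit_cost = orsz_unit_cost,
      household_penalty = household_penalty,
      node_costs = costs,
      node_probabilities = node_p
    ),
    class = "arm_model"
  )
}

#' Expected societal cost per diarrhea episode (tree fold-back)
#'
#' Folds the decision tree back to the root: the probability-weighted sum
#' of terminal-node costs. Two arithmetic conventions are provided.
#' `"exact"` computes `sum(p_i * c_i)` at full precision — the
#' mathematically consistent expectation, used throughout the Monte Carlo
#' analysis. `"as-printed"` first rounds each node's per-diarrhea subtotal
#' `p_i * c_i` to the cent and then sums, reproducing the published
#' table arithmetic (whose per-case totals were formed from cent-rounded
#' cells); this is the default for the deterministic base case so that
#' headline figures match the source tables to the cent.
#'
#' @param arm An [arm_model()].
#' @param method `"as-printed"` (default) or `"exact"`.
#' @return Expected cost per episode, USD.
#' @export
expected_cost_per_case <- function(arm,
                                   method = c("as-printed", "exact")) {
  stopifnot(inherits(arm, "arm_model"))
  method <- match.arg(method)
  p <- arm$node_probabilities
  if (abs(sum(p) - 1) > 1e-9) {
    invalid_model("node probabilities must sum to 1 within 1e-9")
  }
  cells <- p * arm$node_costs
  if (method == "as-printed") sum(round(cells, 2)) else sum(cells)
}

#' Standard-population frame
#'
#' The reference community for population scaling: 1 million total
#' population, of whom 8.1% are children under 5, generating 48,373
#' diarrhea episodes per year (59.7 episodes per 100 child-years). The
#' episode count is pinned to the published figure rather than recomputed
#' from the incidence (which would give 48,357) so that scaled totals
#' match printed values.
#'
#' @param total_population Community size (persons).
#' @param under5_fraction Fraction of the population under 5 years.
#' @param annual_cases Diarrhea episodes per year in the community.
#' @param incidence Episodes per 100 child-years (kept for survey
#'   simulation; not used to derive `annual_cases`).
#' @return An object of class `population_frame`.
#' @export
population_frame <- function(total_population = 1e6,
                             under5_fraction = 0.081,
                             annual_cases = 48373,
                             incidence = 59.7) {
  if (annual_cases <= 0) invalid_parameter("annual_cases must be positive")
  structure(
    list(
      total_population = total_population,
      under5_fraction = under5_fraction,
      under5_count = total_population * under5_fraction,
      annual_cases = annual_cases,
      incidence = incidence
    ),
    class = "population_frame"
  )
}

#' Scale a per-case cost to the standard population
#'
#' @param cost_per_case Expected cost per episode, USD (unrounded).
#' @param frame A [population_frame()].
#' @return Annual cost for the community, USD.
#' @export
scale_to_population <- function(cost_per_case, frame = population_frame()) {
  stopifnot(inherits(frame, "population_frame"))
  cost_per_case * frame$annual_cases
}

#' Incremental cost of the intervention arm over the control arm
#'
#' @param intervention,control Calibrated [arm_model()] objects.
#' @param frame A [population_frame()].
#' @param method Arithmetic convention passed to
#'   [expected_cost_per_case()].
#' @return A list with `per_case` (USD per episode) and `total` (USD per
#'   year for the standard population).
#' @export
incremental_cost <- function(intervention, control,
                             frame = population_frame(),
                             method = c("as-printed", "exact")) {
  method <- match.arg(method)
  per_case <- expected_cost_per_case(intervention, method) -
    expected_cost_per_case(control, method)
  list(per_case = per_case, total = scale_to_population(per_case, frame))
}

#' Table of node costs and probabilities for one arm
#'
#' The published-table shape: one row per terminal node with the cost per
#' event, calibrated probability, and per-diarrhea subtotal.
#'
#' @param arm An [arm_model()].
#' @return A `data.frame` with columns `node_label`, `cost_per_event`,
#'   `probability`, `cost_per_diarrhea`.
#' @export
arm_table <- function(arm) {
  stopifnot(inherits(arm, "arm_model"))
  data.frame(
    node_label = names(arm$node_costs),
    cost_per_event = unname(arm$node_costs),
    probability = unname(arm$node_probabilities),
    cost_per_diarrhea = unname(round(
      arm$node_costs * arm$node_probabilities, 2
    )),
    stringsAsFactors = FALSE
  )
}
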