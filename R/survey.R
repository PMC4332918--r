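# Printed node-cost columns shared by the model constructor and the
# survey-design defaults (kept internal; the public surface is
# orasel_model()).
orasel_table2 <- function() {
  list(
    intervention = list(
      per_event = c(A = 2.78, B = 3.35, C = 0.78, D = 1.35),
      per_diarrhea = c(A = 0.21, B = 1.34, C = 0.11, D = 0.50)
    ),
    control = list(
      per_event = c(A = 1.85, B = 2.78, C = 0.35, D = 1.28),
      per_diarrhea = c(A = 0.05, B = 1.09, C = 0.01, D = 0.68)
    )
  )
}

#' Design of the synthetic two-arm, two-period household survey
#'
#' Emulates the study's survey frame: 3,200 intervention and 3,382
#' control households, each with one child under 5 observed in a pre and
#' a post round, with diarrhea episodes at 59.7 per 100 child-years
#' (converted to a per-child, per-round episode probability of 0.597
#' under a one-year recall window). True care-seeking and conditional
#' ORS-Z receipt probabilities default, in the post period, to the
#' calibrated decision-tree values; pre-period conditional receipt
#' probabilities are the post values scaled by the ratio of the surveyed
#' pre to post any-ORS-Z coverage in that arm (care-seeking held
#' constant across periods). True out-of-pocket pathway cost means
#' default to the per-event node costs; observed costs carry
#' mean-preserving multiplicative lognormal noise.
#'
#' @param n_intervention,n_control Households per arm.
#' @param incidence Episodes per 100 child-years.
#' @param probabilities Nested list `[[arm]][[period]]` of
#'   [arm_probabilities()]; built from the calibrated tree when `NULL`.
#' @param pathway_costs Nested list `[[arm]]` of named vectors over nodes
#'   `A`..`D`; per-event node costs when `NULL`.
#' @param oop_sdlog Lognormal sigma of the cost noise (0 = noiseless).
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(n_intervention = 3200, n_control = 3382,
                          incidence = 59.7, probabilities = NULL,
                          pathway_costs = NULL, oop_sdlog = 0.5) {
  if (n_intervention <= 0 || n_control <= 0) {
    invalid_parameter("sample sizes must be positive")
  }
  if (incidence < 0) invalid_parameter("incidence must be non-negative")
  t2 <- orasel_table2()
  if (is.null(probabilities)) {
    cov_ratio <- c(intervention = 0.061 / 0.137, control = 0.048 / 0.018)
    probabilities <- lapply(
      stats::setNames(nm = c("intervention", "control")),
      function(arm) {
        post <- branch_from_node_probabilities(
          calibrate_node_probabilities(t2[[arm]]$per_event,
                                       t2[[arm]]$per_diarrhea)
        )
        pre <- arm_probabilities(
          post$p_seek,
          min(post$p_orsz_given_seek * cov_ratio[[arm]], 1),
          min(post$p_orsz_given_noseek * cov_ratio[[arm]], 1)
        )
        list(pre = pre, post = post)
      }
    )
  }
  if (is.null(pathway_costs)) {
    pathway_costs <- lapply(t2, `[[`, "per_event")
  }
  structure(
    list(
      n_intervention = n_intervention, n_control = n_control,
      incidence = incidence, probabilities = probabilities,
      pathway_costs = pathway_costs, oop_sdlog = oop_sdlog
    ),
    class = "survey_design"
  )
}

#' Generate a synthetic household survey
#'
#' One record per household per round. Episodes are Bernoulli with the
#' incidence-derived per-child probability; among episodes, care-seeking
#' and conditional ORS-Z receipt are Bernoulli with the design's true
#' probabilities for that arm and period; out-of-pocket cost is the true
#' pathway mean times mean-one lognormal noise. Care-seeking, receipt and
#' cost fields are `NA` for rounds without an episode.
#'
#' @param design A [survey_design()].
#' @param seed Integer seed for reproducibility.
#' @return A `data.frame` with columns `household_id`, `arm`, `period`,
#'   `episode`, `sought_care`, `got_orsz`, `oop_cost`.
#' @export
generate_survey <- function(design = survey_design(), seed = 1) {
  stopifnot(inherits(design, "survey_design"))
  suppressWarnings(set.seed(as.integer(seed), kind = "Mersenne-Twister"))
  p_episode <- min(design$incidence / 100, 1)
  blocks <- list()
  for (arm in c("intervention", "control")) {
    n <- if (arm == "intervention") design$n_intervention else
      design$n_control
    for (period in c("pre", "post")) {
      p <- design$probabilities[[arm]][[period]]
      episode <- stats::rbinom(n, 1L, p_episode) == 1L
      sought <- rep(NA, n)
      got <- rep(NA, n)
      oop <- rep(NA_real_, n)
      ne <- sum(episode)
      if (ne > 0) {
        s <- stats::rbinom(ne, 1L, p$p_seek) == 1L
        g <- logical(ne)
        g[s] <- stats::rbinom(sum(s), 1L, p$p_orsz_given_seek) == 1L
        g[!s] <- stats::rbinom(sum(!s), 1L, p$p_orsz_given_noseek) == 1L
        node <- ifelse(s, ifelse(g, "A", "B"), ifelse(g, "C", "D"))
        mu <- design$pathway_costs[[arm]][node]
        noise <- if (design$oop_sdlog > 0) {
          stats::rlnorm(ne, meanlog = -design$oop_sdlog^2 / 2,
                        sdlog = design$oop_sdlog)
        } else {
          rep(1, ne)
        }
        sought[episode] <- s
        got[episode] <- g
        oop[episode] <- pmax(mu * noise, 0)
      }
      blocks[[paste(arm, period)]] <- data.frame(
        household_id = paste0(substr(arm, 1, 1), seq_len(n)),
        arm = arm, period = period, episode = episode,
        sought_care = sought, got_orsz = got, oop_cost = oop,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Estimate decision-tree probabilities from survey records
#'
#' Pooled individual-level frequencies (never village means): per arm and
#' period, the proportion of episodes with formal care sought, and the
#' conditional proportions receiving ORS-Z among seekers and
#' non-seekers, each with its binomial standard error. Cells with no
#' observations are returned as `NA` and flagged.
#'
#' @param records A survey `data.frame` from [generate_survey()] (or the
#'   same schema read from file).
#' @return A `data.frame` with columns `arm`, `period`, `parameter`,
#'   `estimate`, `se`, `n`, `flag`.
#' @export
estimate_probabilities <- function(records) {
  cell <- function(x) {
    n <- length(x)
    if (n == 0L) {
      return(c(estimate = NA_real_, se = NA_real_, n = 0))
    }
    p <- mean(x)
    c(estimate = p, se = binomial_se(p, n), n = n)
  }
  rows <- list()
  for (arm in unique(records$arm)) {
    for (period in unique(records$period)) {
      d <- records[records$arm == arm & records$period == period &
                     records$episode, , drop = FALSE]
      cells <- list(
        p_seek = cell(d$sought_care),
        p_orsz_given_seek = cell(d$got_orsz[d$sought_care]),
        p_orsz_given_noseek = cell(d$got_orsz[!d$sought_care])
      )
      for (nm in names(cells)) {
        v <- cells[[nm]]
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, period = period, parameter = nm,
          estimate = v[["estimate"]], se = v[["se"]], n = v[["n"]],
          flag = if (v[["n"]] == 0) "empty-cell" else
            if (v[["n"]] < 10) "sparse" else "ok",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate mean out-of-pocket costs per care pathway
#'
#' Arithmetic means (with standard errors) of observed out-of-pocket
#' costs keyed by arm and pathway `(sought_care, got_orsz)`, pooled over
#' survey rounds. Pathways with no observations are flagged absent.
#'
#' @param records A survey `data.frame`.
#' @return A `data.frame` with columns `arm`, `node_label`,
#'   `sought_care`, `got_orsz`, `mean_cost`, `se`, `n`, `flag`.
#' @export
estimate_costs <- function(records) {
  d <- records[records$episode, , drop = FALSE]
  paths <- expand.grid(sought_care = c(TRUE, FALSE),
                       got_orsz = c(TRUE, FALSE))
  paths$node_label <- ifelse(paths$sought_care,
                             ifelse(paths$got_orsz, "A", "B"),
                             ifelse(paths$got_orsz, "C", "D"))
  rows <- list()
  for (arm in unique(d$arm)) {
    for (i in seq_len(nrow(paths))) {
      x <- d$oop_cost[d$arm == arm &
                        d$sought_care == paths$sought_care[i] &
                        d$got_orsz == paths$got_orsz[i]]
      n <- length(x)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, node_label = paths$node_label[i],
        sought_care = paths$sought_care[i], got_orsz = paths$got_orsz[i],
        mean_cost = if (n) mean(x) else NA_real_,
        se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
        n = n,
        flag = if (n == 0) "absent" else "ok",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$arm, out$node_label), ]
  rownames(out) <- NULL
  out
}

#' Read / write survey records as CSV
#'
#' @param records A survey `data.frame` (for writing).
#' @param path File path.
#' @return `read_survey()` returns the records `data.frame`;
#'   `write_survey()` returns `path` invisibly.
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("household_id", "arm", "period", "episode", "sought_care",
            "got_orsz", "oop_cost")
  if (!all(need %in% names(df))) {
    invalid_parameter(
      paste("survey CSV must have columns:", paste(need, collapse = ", "))
    )
  }
  for (col in c("episode", "sought_care", "got_orsz")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' @rdname read_survey
#' @export
write_survey <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
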