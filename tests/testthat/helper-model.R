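# Shared fixtures and independent oracles.

# A random two-branch tree (branch probabilities + cost components),
# for property-style checks of the fold-back.
random_arm <- function() {
  p <- arm_probabilities(runif(1), runif(1), runif(1))
  arm_model(
    sample(c("intervention", "control"), 1),
    consultation_cost = runif(1, 0.5, 5),
    orsz_unit_cost = runif(1, 0.1, 2),
    household_penalty = runif(1, 0.1, 3),
    probabilities = p
  )
}

# Brute-force enumeration oracle for the expected cost per episode:
# walks every root-to-leaf path, multiplying branch probabilities and
# summing the cost components incurred along the way. Independent of the
# node-cost / fold-back arithmetic in arm_model().
enumerate_expected_cost <- function(consult, orsz, penalty, p) {
  paths <- expand.grid(seek = c(TRUE, FALSE), got = c(TRUE, FALSE))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    seek <- paths$seek[i]
    got <- paths$got[i]
    pr <- (if (seek) p$p_seek else 1 - p$p_seek) *
      (if (seek) {
        if (got) p$p_orsz_given_seek else 1 - p$p_orsz_given_seek
      } else {
        if (got) p$p_orsz_given_noseek else 1 - p$p_orsz_given_noseek
      })
    cost <- (if (seek) consult else 0) + (if (got) orsz else penalty)
    total <- total + pr * cost
  }
  total
}

# Printed node-cost columns (per-event / per-diarrhea) used across tests.
table2_intervention <- list(
  per_event = c(A = 2.78, B = 3.35, C = 0.78, D = 1.35),
  per_diarrhea = c(A = 0.21, B = 1.34, C = 0.11, D = 0.50)
)
table2_control <- list(
  per_event = c(A = 1.85, B = 2.78, C = 0.35, D = 1.28),
  per_diarrhea = c(A = 0.05, B = 1.09, C = 0.01, D = 0.68)
)
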