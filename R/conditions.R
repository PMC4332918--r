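#' @keywords internal
#' @noRd
cea_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cea_error")))
}

# Invalid user-supplied parameter (negative cost, share outside [0,1], ...)
invalid_parameter <- function(msg) cea_stop(msg, "cea_invalid_parameter")

# Model state inconsistent with the requested computation
invalid_model <- function(msg) cea_stop(msg, "cea_invalid_model")

# Probability calibration could not satisfy its constraints
calibration_failure <- function(msg) cea_stop(msg, "cea_calibration_failure")
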