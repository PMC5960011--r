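# Structured conditions: every error the package raises carries a specific
# class (plus "bellcog_error") so callers can branch on failure modes.

bellcog_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "bellcog_error")))
}

abort_normalization <- function(measurement, sum, tol) {
  bellcog_error(
    "normalization_error",
    sprintf("block %s sums to %.12g (|sum - 1| > tol = %g)", measurement, sum, tol),
    measurement = measurement, sum = sum, tol = tol
  )
}

abort_negative_probability <- function(measurement, i, j, value) {
  bellcog_error(
    "negative_probability_error",
    sprintf("cell (%s, %d, %d) is negative: %.12g", measurement, i, j, value),
    measurement = measurement, i = i, j = j, value = value
  )
}

abort_mapping <- function(msg) bellcog_error("mapping_error", msg)

abort_infeasible <- function(msg, residual = NA_real_) {
  bellcog_error("infeasible_target_error", msg, residual = residual)
}

abort_assumption <- function(msg) bellcog_error("assumption_error", msg)

abort_parse <- function(msg, ...) bellcog_error("parse_error", msg, ...)

abort_schema <- function(msg, ...) bellcog_error("schema_error", msg, ...)
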