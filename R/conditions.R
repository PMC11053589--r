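## Classed error conditions so callers can distinguish recoverable
## domain failures from programming errors.

stop_not_stationary <- function(msg, check) {
  stop(errorCondition(msg, check = check,
                      class = c("gaitfusion_not_stationary", "gaitfusion_error")))
}

stop_alignment_unreliable <- function(msg, best_correlation) {
  stop(errorCondition(msg, best_correlation = best_correlation,
                      class = c("gaitfusion_alignment_unreliable", "gaitfusion_error")))
}

stop_unsupported_operator <- function(msg) {
  stop(errorCondition(msg,
                      class = c("gaitfusion_unsupported_operator", "gaitfusion_error")))
}
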