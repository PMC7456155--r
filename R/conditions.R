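# Classed conditions so callers (and the CLI exit-code mapping) can tell
# bad arguments apart from bad data and failed fits.

stop_arg <- function(...) {
  stop(errorCondition(paste0(...), class = c("woodonset_arg_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("woodonset_data_error", "error")))
}

stop_fit <- function(...) {
  stop(errorCondition(paste0(...), class = c("woodonset_fit_error", "error")))
}
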