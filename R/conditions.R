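# Structured conditions: every validation failure signals a classed error so
# callers (and tests) can distinguish e.g. a depth-error from a format-error.

cryodiv_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("cryodiv_", class), "cryodiv_error")))
}

cryodiv_warn <- function(msg) {
  warning(warningCondition(msg, class = "cryodiv_warning"), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
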