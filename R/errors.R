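# Typed error helpers. Every validation failure raises a classed condition so
# callers (and tests) can dispatch on the error kind rather than match text.

sq_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "simsquant_error")))
}

sq_warn <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "simsquant_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
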