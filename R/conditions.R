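# Classed conditions so callers can distinguish contract violations
# (invalid_parameter / invalid_input), file-format problems (format_error),
# filesystem failures (io_error) and model/metric misuse.

abort_class <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "peachsae_error"), call = call))
}

invalid_parameter <- function(msg) abort_class(msg, "invalid_parameter")
invalid_input     <- function(msg) abort_class(msg, "invalid_input")
format_error      <- function(msg) abort_class(msg, "format_error")
io_error          <- function(msg) abort_class(msg, "io_error")
degenerate_reference <- function(msg) abort_class(msg, "degenerate_reference")
undefined_metric  <- function(msg) abort_class(msg, "undefined_metric")
incompatible_model <- function(msg) abort_class(msg, "incompatible_model")

`%||%` <- function(a, b) if (is.null(a)) b else a
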