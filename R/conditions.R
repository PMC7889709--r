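# Classed conditions so callers (and the CLI) can map failures to exit codes.
# schema/config errors -> exit 2, estimation errors -> exit 3.

sirs_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "picusirs_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

abort_schema     <- function(msg, ...) sirs_abort(msg, "picusirs_schema_error", ...)
abort_integrity  <- function(msg, ...) sirs_abort(msg, "picusirs_integrity_error", ...)
abort_config     <- function(msg, ...) sirs_abort(msg, "picusirs_config_error", ...)
abort_parameter  <- function(msg, ...) sirs_abort(msg, "picusirs_parameter_error", ...)
abort_invariant  <- function(msg, ...) sirs_abort(msg, "picusirs_invariant_error", ...)
abort_estimation <- function(msg, ...) sirs_abort(msg, "picusirs_estimation_error", ...)
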