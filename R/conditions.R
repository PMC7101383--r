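# Typed error conditions used across the package. Every user-facing error
# carries a subclass so callers (and the CLI) can map failures to exit codes
# without parsing messages.

abort_plastisize <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message,
    class = c(class, "plastisize_error"),
    call = call
  ))
}

invalid_parameter <- function(message) {
  abort_plastisize(message, "plastisize_invalid_parameter", call = sys.call(-1))
}

insufficient_data <- function(message) {
  abort_plastisize(message, "plastisize_insufficient_data", call = sys.call(-1))
}

invalid_record <- function(message) {
  abort_plastisize(message, "plastisize_invalid_record", call = sys.call(-1))
}

invalid_grid <- function(message) {
  abort_plastisize(message, "plastisize_invalid_grid", call = sys.call(-1))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    invalid_parameter(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
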