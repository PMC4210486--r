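# Condition helpers. Every user-facing failure carries a class so callers
# (and the CLI) can map it to an exit status without parsing messages.

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = c("atyp_validation_error", "atyp_error"), ...)
}

abort_parameter <- function(msg, ...) {
  rlang::abort(msg, class = c("atyp_parameter_error", "atyp_validation_error", "atyp_error"), ...)
}

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = c("atyp_io_error", "atyp_error"), ...)
}

abort_unencodable <- function(msg, ...) {
  rlang::abort(msg, class = c("atyp_unencodable_error", "atyp_validation_error", "atyp_error"), ...)
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = c("atyp_degenerate_fit", "atyp_error"), ...)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
# All stochastic operations in the package funnel through this.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!rlang::is_scalar_integerish(seed)) {
    abort_parameter("`seed` must be a single integer or NULL.")
  }
  withr::with_seed(as.integer(seed), force(code))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
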