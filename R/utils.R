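#' @importFrom rlang abort warn %||%
#' @importFrom stats rbeta rlnorm setNames
#' @importFrom utils head
NULL

# internal: stop with a classed validation error listing offending rows
validation_error <- function(msg, details = character()) {
  if (length(details) > 0) {
    msg <- paste0(msg, "\n", paste0("  - ", head(details, 20), collapse = "\n"))
    if (length(details) > 20) {
      msg <- paste0(msg, "\n  ... and ", length(details) - 20, " more")
    }
  }
  abort(msg, class = "evworkload_validation_error")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}
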