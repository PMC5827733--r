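`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signalling helpers
#'
#' All package errors carry the condition class `dmoma_error` plus a
#' specific subclass, so callers can distinguish e.g. validation failures
#' from infeasible optimization steps.
#' @noRd
dmoma_stop <- function(subclass, message, ...) {
  cond <- structure(
    class = c(subclass, "dmoma_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

dmoma_warn <- function(message) warning(message, call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
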