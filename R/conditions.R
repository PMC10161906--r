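#' Classed errors
#'
#' All failure modes that callers are expected to branch on are signalled as
#' classed conditions (subclass of `dscqc_error`), so tests and the feature
#' extractor can distinguish, e.g., a missing bolus from a degenerate baseline.
#'
#' @param msg human-readable message
#' @param class condition subclass, e.g. "dscqc_no_bolus"
#' @param ... fields attached to the condition
#' @keywords internal
#' @noRd
qc_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "dscqc_error", "error")))
}

#' @noRd
qc_reason <- function(cond) {
  cls <- setdiff(class(cond), c("dscqc_error", "error", "condition"))
  if (length(cls)) cls[[1L]] else "error"
}
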