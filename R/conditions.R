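# Classed conditions used across the package. Every user-facing failure is a
# condition inheriting from "mirdose_error" so pipelines can branch on the
# failure class rather than on message text.

mird_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "mirdose_error", "error", "condition")))
}

mird_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "mirdose_warning", "warning", "condition")))
}

#' @keywords internal
assert_scalar_number <- function(x, name, positive = FALSE, nonnegative = FALSE,
                                 finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    mird_stop(sprintf("`%s` must be a single non-missing number", name),
              "mirdose_invalid_argument")
  }
  if (finite && !is.finite(x)) {
    mird_stop(sprintf("`%s` must be finite", name), "mirdose_invalid_argument")
  }
  if (positive && x <= 0) {
    mird_stop(sprintf("`%s` must be > 0 (got %g)", name, x),
              "mirdose_invalid_argument")
  }
  if (nonnegative && x < 0) {
    mird_stop(sprintf("`%s` must be >= 0 (got %g)", name, x),
              "mirdose_invalid_argument")
  }
  invisible(x)
}
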