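# Structured conditions used across the package.
#
# Error classes:
#   membrafluor_invalid     - precondition violation on user input
#   membrafluor_degenerate  - input is formally valid but the quantity is undefined
#   membrafluor_stage_error - a pipeline stage failed; carries the stage name
# Warning classes:
#   membrafluor_anomaly      - physically suspicious value (e.g. Q > 1), kept
#   membrafluor_plausibility - value outside the empirical envelope for the probe
#   membrafluor_clipped      - result clipped into its mathematical range

mf_stop <- function(msg, class = "membrafluor_invalid", ..., call. = sys.call(-1)) {
  cnd <- structure(
    class = c(class, "membrafluor_error", "error", "condition"),
    list(message = msg, call = call., ...)
  )
  stop(cnd)
}

mf_stage_stop <- function(stage, msg, ...) {
  cnd <- structure(
    class = c("membrafluor_stage_error", "membrafluor_error", "error", "condition"),
    list(message = sprintf("stage '%s' failed: %s", stage, msg),
         call = sys.call(-1), stage = stage, ...)
  )
  stop(cnd)
}

mf_warn <- function(msg, class = "membrafluor_anomaly") {
  cnd <- structure(
    class = c(class, "membrafluor_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  warning(cnd)
}

check_numeric <- function(x, name, non_negative = FALSE, positive = FALSE,
                          finite = TRUE, scalar = FALSE) {
  if (!is.numeric(x) || length(x) == 0) {
    mf_stop(sprintf("'%s' must be numeric and non-empty", name))
  }
  if (scalar && length(x) != 1L) {
    mf_stop(sprintf("'%s' must be a single number", name))
  }
  if (anyNA(x)) mf_stop(sprintf("'%s' contains missing values", name))
  if (finite && any(!is.finite(x))) {
    mf_stop(sprintf("'%s' contains non-finite values", name))
  }
  if (positive && any(x <= 0)) {
    mf_stop(sprintf("'%s' must be strictly positive", name))
  }
  if (non_negative && any(x < 0)) {
    mf_stop(sprintf("'%s' must be non-negative", name))
  }
  invisible(x)
}
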