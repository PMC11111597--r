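# Classed error conditions used throughout the package so callers (and the
# command-line wrapper) can distinguish user/validation errors from internal
# failures.

vs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "voicescreen_error"),
                      call = call))
}

vs_not_found   <- function(msg) vs_stop(msg, "vs_not_found_error")
vs_format      <- function(msg) vs_stop(msg, "vs_format_error")
vs_degenerate  <- function(msg) vs_stop(msg, "vs_degenerate_error")
vs_too_short   <- function(msg) vs_stop(msg, "vs_too_short_error")
vs_invalid     <- function(msg) vs_stop(msg, "vs_invalid_error")
vs_config      <- function(msg) vs_stop(msg, "vs_config_error")
vs_dimension   <- function(msg) vs_stop(msg, "vs_dimension_error")
vs_exclusion   <- function(msg) vs_stop(msg, "vs_exclusion_error")
vs_validation  <- function(msg) vs_stop(msg, "vs_validation_error")
vs_compat      <- function(msg) vs_stop(msg, "vs_compatibility_error")
vs_budget      <- function(msg) vs_stop(msg, "vs_budget_error")
vs_transcription <- function(msg) vs_stop(msg, "vs_transcription_error")

#' @keywords internal
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
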