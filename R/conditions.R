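#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish structured failures
# (malformed records, empty bands, zero-energy segments, ...) from
# ordinary argument errors.
stop_edafreq <- function(subclass, message, ...) {
  stop(errorCondition(
    message,
    ...,
    class = c(paste0("edafreq_", subclass), "edafreq_error", "error")
  ))
}

#' Affective-state codes used throughout the package
#'
#' Every label leaving the I/O layer is one of these four strings.
#' `"other"` marks samples excluded from all experiments (transients,
#' meditation, mixed resampling blocks).
#'
#' @return Character vector of the four state codes.
#' @export
eda_states <- function() c("baseline", "stress", "amusement", "other")
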