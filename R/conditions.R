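#' @keywords internal
"_PACKAGE"

# Classed conditions shared across the package. Exit-code mapping used by the
# CLI: invalid parameter / usage -> 2, format -> 3, analysis -> 4.

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("epimapr_invalid_parameter", "epimapr_error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("epimapr_format_error", "epimapr_error")))
}

stop_analysis <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("epimapr_analysis_error", "epimapr_error")))
}

warn_epimapr <- function(msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = "epimapr_warning"))
}

# stderr logging; machine outputs are never written here
log_msg <- function(level, msg, ...) {
  cat(sprintf("[%s] %s\n", level, sprintf(msg, ...)), file = stderr())
}
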