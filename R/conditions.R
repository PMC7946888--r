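# Classed conditions so callers (and the CLI) can map failures to exit codes.
# Classes used:
#   mprheo_invalid_parameter, mprheo_domain_error   -> bad arguments
#   mprheo_format_error                             -> malformed files/frames
#   mprheo_degenerate_data                          -> constant images, zero
#                                                      variance, empty masks
#   mprheo_calibration_error                        -> calibration fit failed
#   mprheo_insufficient_data                        -> too few samples/steps

mp_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mprheo_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

mp_check <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) mp_stop(class, msg, ...)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
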