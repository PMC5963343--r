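# Classed error conditions so callers can distinguish bad input from bad data.
# All inherit from "ctquant_error".

ct_abort <- function(message, class, ...) {
  abort(message, class = c(class, "ctquant_error"), ...)
}

abort_format <- function(message, ...) {
  ct_abort(message, "ctquant_format_error", ...)
}

abort_validation <- function(message, ...) {
  ct_abort(message, "ctquant_validation_error", ...)
}

abort_missing_assay <- function(message, ...) {
  ct_abort(message, "ctquant_missing_assay_error", ...)
}

abort_insufficient_data <- function(message, ...) {
  ct_abort(message, "ctquant_insufficient_data_error", ...)
}

abort_qc <- function(message, ...) {
  ct_abort(message, "ctquant_qc_error", ...)
}

abort_degenerate_design <- function(message, ...) {
  ct_abort(message, "ctquant_degenerate_design_error", ...)
}

abort_io <- function(message, ...) {
  ct_abort(message, "ctquant_io_error", ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
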