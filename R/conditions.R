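# Typed error conditions. Every rejection names the violated invariant so the
# CLI can map condition classes onto machine-readable exit codes
# (2 validation, 3 convergence, 4 design).

nccpv_stop <- function(class, message, ...) {
  stop(structure(
    class = c(class, "nccpv_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

stop_validation <- function(message, ...) {
  nccpv_stop("nccpv_validation_error", message, ...)
}

stop_invalid_design <- function(message, ...) {
  nccpv_stop(c("nccpv_invalid_design_error", "nccpv_validation_error"),
             message, ...)
}

stop_degenerate_table <- function(message, ...) {
  nccpv_stop(c("nccpv_degenerate_table_error", "nccpv_validation_error"),
             message, ...)
}

stop_boundary <- function(message, ...) {
  nccpv_stop(c("nccpv_boundary_error", "nccpv_validation_error"), message, ...)
}

stop_convergence <- function(message, ...) {
  nccpv_stop("nccpv_convergence_error", message, ...)
}

exit_code_for_condition <- function(cond) {
  if (inherits(cond, "nccpv_convergence_error")) return(3L)
  if (inherits(cond, "nccpv_invalid_design_error")) return(4L)
  if (inherits(cond, "nccpv_validation_error")) return(2L)
  2L
}
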