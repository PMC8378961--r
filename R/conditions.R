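#' @title Condition classes
#' @description All declared error families raised by mcrn carry a condition
#'   class so callers (and the CLI exit-code map) can dispatch on them:
#'   `mcrn_usage_error`, `mcrn_config_error`, `mcrn_param_error`,
#'   `mcrn_io_error`, `mcrn_format_error`, `mcrn_shape_error`.
#' @name mcrn-conditions
#' @keywords internal
NULL

mcrn_abort <- function(class, msg) {
  stop(structure(
    class = c(class, "mcrn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_usage  <- function(msg) mcrn_abort("mcrn_usage_error", msg)
abort_config <- function(msg) mcrn_abort("mcrn_config_error", msg)
abort_param  <- function(msg) mcrn_abort("mcrn_param_error", msg)
abort_io     <- function(msg) mcrn_abort("mcrn_io_error", msg)
abort_format <- function(msg) mcrn_abort("mcrn_format_error", msg)
abort_shape  <- function(msg) mcrn_abort("mcrn_shape_error", msg)

#' Exit-code map used by the command-line interface
#'
#' usage errors exit 2, configuration errors 3, I/O and format errors 4,
#' shape errors 5; any other error exits 1.
#'
#' @param cond a condition object
#' @return integer exit status
#' @keywords internal
exit_code_for <- function(cond) {
  if (inherits(cond, "mcrn_usage_error")) return(2L)
  if (inherits(cond, "mcrn_config_error") || inherits(cond, "mcrn_param_error")) return(3L)
  if (inherits(cond, "mcrn_io_error") || inherits(cond, "mcrn_format_error")) return(4L)
  if (inherits(cond, "mcrn_shape_error")) return(5L)
  1L
}
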