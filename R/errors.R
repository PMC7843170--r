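# Classed conditions so callers (and the CLI) can map failure kinds to
# distinct exit codes.  Class hierarchy:
#   mlcs_input_error      bad/missing input file, FASTA syntax, alphabet violations
#     mlcs_parse_error      malformed FASTA (carries a line number when known)
#     mlcs_cardinality_error  fewer than 2 records
#   mlcs_parameter_error  bad argument values at the function boundary
#   mlcs_config_error     inconsistent run configuration (e.g. dp2 with n > 2)
#   mlcs_integrity_error  malformed graph handed to backtracking
#   mlcs_resource_error   node/enumeration budget exceeded
#   mlcs_io_error         unwritable output path

mlcs_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "mlcs_error")))
}

#' Map an error condition to the CLI exit code
#'
#' Exit codes: 0 success, 2 input (file/format/alphabet), 3 parameter or
#' configuration, 4 graph integrity, 5 resource budget, 1 anything else.
#'
#' @param cond a condition object.
#' @return integer exit code.
#' @keywords internal
mlcs_exit_code <- function(cond) {
  if (inherits(cond, c("mlcs_input_error", "mlcs_io_error"))) return(2L)
  if (inherits(cond, c("mlcs_parameter_error", "mlcs_config_error"))) return(3L)
  if (inherits(cond, "mlcs_integrity_error")) return(4L)
  if (inherits(cond, "mlcs_resource_error")) return(5L)
  1L
}
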