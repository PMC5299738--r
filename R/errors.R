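# Classed error conditions; each class maps to a stable CLI exit code.

sp_error_codes <- c(
  sp_config_error     = 2L,
  sp_generation_error = 3L,
  sp_resolution_error = 4L,
  sp_transport_error  = 5L,
  sp_format_error     = 6L
)

sp_stop <- function(class, fmt, ..., data = NULL) {
  cond <- structure(
    class = c(class, "sparqlpipe_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL, data = data)
  )
  stop(cond)
}

#' Exit code for a sparqlpipe error condition
#'
#' Maps classed package errors to the stable exit codes used by the
#' command-line interface: configuration 2, query generation 3,
#' endpoint/template resolution 4, transport 5, data format 6.
#' Unclassed errors map to 1.
#'
#' @param cond A condition object.
#' @return Integer exit code.
#' @export
exit_code_for <- function(cond) {
  for (cl in class(cond)) {
    if (cl %in% names(sp_error_codes)) return(unname(sp_error_codes[[cl]]))
  }
  1L
}
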