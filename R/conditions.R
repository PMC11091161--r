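#' @title Error conditions
#' @description Classed conditions used across the package so that callers
#'   (and the CLI) can map failures to stable exit codes:
#'   `locohd_config_error` (2), `locohd_parse_error` (3),
#'   `locohd_domain_error` (4), `locohd_empty_error` (4).
#' @name locohd-conditions
#' @keywords internal
NULL

stop_locohd <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "locohd_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_config <- function(msg, ...) stop_locohd("locohd_config_error", msg, ...)
stop_parse  <- function(msg, ...) stop_locohd("locohd_parse_error", msg, ...)
stop_domain <- function(msg, ...) stop_locohd("locohd_domain_error", msg, ...)
stop_empty  <- function(msg, ...) {
  stop(structure(
    class = c("locohd_empty_error", "locohd_domain_error", "locohd_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
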