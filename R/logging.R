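# Minimal stderr logger. Verbosity is a package option so the CLI's
# --verbose flag and library use share one switch.

ft_verbose <- function() isTRUE(getOption("fragtrack.verbose", FALSE))

#' Enable or disable verbose logging
#'
#' Messages are written to stderr; off by default.
#'
#' @param on logical switch.
#' @return The previous setting, invisibly.
#' @export
ft_set_verbose <- function(on = TRUE) {
  old <- ft_verbose()
  options(fragtrack.verbose = isTRUE(on))
  invisible(old)
}

ft_log <- function(fmt, ...) {
  if (ft_verbose()) {
    message(sprintf(paste0("[fragtrack] ", fmt), ...))
  }
  invisible(NULL)
}

ft_warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

# Classed conditions so the CLI can map error kinds to exit codes.
ft_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "fragtrack_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

ft_input_error    <- function(fmt, ...) ft_stop("fragtrack_input_error", fmt, ...)
ft_format_error   <- function(fmt, ...) ft_stop("fragtrack_format_error", fmt, ...)
ft_config_error   <- function(fmt, ...) ft_stop("fragtrack_config_error", fmt, ...)
ft_contract_error <- function(fmt, ...) ft_stop("fragtrack_contract_error", fmt, ...)
ft_validation_error <- function(fmt, ...) ft_stop("fragtrack_validation_error", fmt, ...)
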