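# Classified conditions so callers (and the CLI) can map failures to exit codes.

stop_gosets <- function(class, ..., call. = FALSE) {
  msg <- paste0(...)
  cond <- structure(
    class = c(class, "gosets_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

config_error <- function(...) stop_gosets("gosets_config_error", ...)
parse_error <- function(...) stop_gosets("gosets_parse_error", ...)
io_error <- function(...) stop_gosets("gosets_io_error", ...)
validation_error <- function(...) stop_gosets("gosets_validation_error", ...)
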