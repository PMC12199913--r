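# Internal condition helpers: validation errors (bad input) and I/O errors are
# distinguishable classes so the CLI can map them to exit codes 1 and 2.

stop_validation <- function(fmt, ...) {
  stop(structure(
    class = c("nm_validation_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stop_io <- function(fmt, ...) {
  stop(structure(
    class = c("nm_io_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
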