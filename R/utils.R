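`%||%` <- function(a, b) if (is.null(a)) b else a

# one structured log line per event; suppress with suppressMessages()
dp_log <- function(fmt, ...) message("[dasypop] ", sprintf(fmt, ...))

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && x == round(x)

stop_if_missing_file <- function(path, what = "file") {
  if (!file.exists(path)) stop(what, " not found: ", path, call. = FALSE)
  invisible(path)
}
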