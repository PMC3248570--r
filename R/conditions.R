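#' @keywords internal
"_PACKAGE"

# Structured error helper: every user-facing failure carries a condition
# class of the form "agnc_<type>_error" so callers can branch on tryCatch().
agnc_stop <- function(message, type, call. = FALSE, ...) {
  cond <- structure(
    class = c(paste0("agnc_", type, "_error"), "agnc_error",
              "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

agnc_assert <- function(ok, message, type) {
  if (!isTRUE(ok)) agnc_stop(message, type)
  invisible(TRUE)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x == as.integer(x) && x >= min
}
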