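# Classed error conditions shared across the package.
#
# Every user-facing failure raises a condition with class
# c("arblink_<what>", <category>, "arblink_error", "error", "condition") where
# <category> is "arblink_validation" (bad input/content) or "arblink_io"
# (filesystem). The CLI maps categories to exit codes.

abort_arblink <- function(message, class, category = "arblink_validation",
                          call = NULL, ...) {
  cond <- structure(
    class = c(class, category, "arblink_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

# Small utilities used throughout --------------------------------------------

# strsplit() drops trailing empty fields; headers with empty trailing metadata
# cells must keep them, so pad to the delimiter count.
split_keep_empty <- function(x, delim = "\t") {
  parts <- strsplit(x, delim, fixed = TRUE)[[1]]
  n_cells <- nchar(x) - nchar(gsub(delim, "", x, fixed = TRUE)) + 1L
  c(parts, rep("", n_cells - length(parts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
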