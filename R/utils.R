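# Internal helpers shared across modules.

# Locale-independent sorting: reference databases and reports must be
# byte-identical across platforms, so never rely on the collation locale.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

# Collapse internal whitespace runs and strip the ends.
squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_proxitax <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "proxitax_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}
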