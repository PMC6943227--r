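#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Typed condition helper: every user-facing failure carries a condition class
## so callers (and tests) can distinguish parse / validation / usage errors.
fmt_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fmtengraft_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

fmt_assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) fmt_stop(class, msg, ...)
  invisible(TRUE)
}

is_fraction <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)

## Deterministic sub-seed derivation; keeps values within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * offset) %% 2147483647)
}
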