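# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators in the package are pure functions of
# (arguments, seed) via this helper.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_fraction <- function(x, name, open_low = TRUE, open_high = TRUE) {
  ok <- is_scalar_number(x) &&
    (if (open_low) x > 0 else x >= 0) &&
    (if (open_high) x < 1 else x <= 1)
  if (!ok) stop(sprintf("`%s` must be a fraction in %s0, 1%s, got %s",
                        name, if (open_low) "(" else "[",
                        if (open_high) ")" else "]",
                        format(x)), call. = FALSE)
  invisible(x)
}
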