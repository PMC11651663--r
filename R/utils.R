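# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic operations in the package go
# through this so that every result is a pure function of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible child seed from a parent seed and a stream label.
# Keeps results below 2^31 so they remain valid R integers.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 131 + ch) %% 2147483587L
  as.integer(h) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stopf("`%s` must be a positive finite scalar", name)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
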