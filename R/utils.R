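
# Run expr with a local RNG state seeded from `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed fan-out from one master seed, kept inside
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Fixed-width numeric formatting used by every writer so that reruns produce
# byte-identical tables.
format_num <- function(x, digits = 6L) {
  out <- formatC(x, digits = digits, format = "f")
  out[is.na(x)] <- "NA"
  out
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
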