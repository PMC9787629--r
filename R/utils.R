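# Internal helpers shared across modules.

# Run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# user's random stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible sub-seed from a base seed and one or more indices,
# kept inside the 32-bit signed range.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ks) s <- (s * 48271 + as.double(k) * 9973 + 1) %% 2147483647
  as.integer(s)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop_invalid("`%s` must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

assert_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min)
    stop_invalid("`%s` must be a single number >= %g", name, min)
  invisible(as.numeric(x))
}

# Format a numeric vector so it round-trips bit-exactly through text.
fmt_num <- function(x) sprintf("%.17g", x)
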