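# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`; with seed = NULL
# the global RNG stream is used (and advanced) as usual.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

check_seed <- function(seed, allow_null = TRUE) {
  if (is.null(seed)) {
    if (!allow_null) abort("`seed` must be a single integer.")
    return(invisible(NULL))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed) || abs(seed) > .Machine$integer.max) {
    abort("`seed` must be a single integer (or NULL).")
  }
  invisible(NULL)
}

# Deterministic seed derivation: mixes a master seed with integer labels so
# that scenario cells and replicates can be evaluated in any order and still
# see identical streams. Plain 32-bit multiplicative mixing, kept in
# [1, 2^31 - 2] so the result is always a valid R seed.
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(master %% m)
  for (k in as.double(c(...))) {
    h <- (h * 48271 + (k + 11) * 16807 + 104729) %% m
  }
  as.integer(h %% (m - 2)) + 1L
}

# Hash a character label into an integer for derive_seed().
label_code <- function(x) {
  u <- utf8ToInt(paste(format(x), collapse = "\r"))
  as.integer(sum(u * (seq_along(u) %% 97 + 1)) %% 2147483000)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single number %s %s.", name,
      if (strict) ">" else ">=", format(min)
    ))
  }
  as.numeric(x)
}
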