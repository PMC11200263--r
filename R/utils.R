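# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed for a (seed, key...) combination, always < 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(..., sep = "/")
  codes <- utf8ToInt(key)
  h <- sum(codes * seq_along(codes)) %% 2048L
  (as.integer(seed) %% 1000000L) * 2048L + as.integer(h)
}

# Row-wise softmax of a matrix of log-weights, numerically stable.
softmax_rows <- function(l) {
  m <- apply(l, 1L, max)
  w <- exp(l - m)
  w / rowSums(w)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
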