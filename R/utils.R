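# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream (generators must be bit-reproducible and side-effect free).
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if ((strict_lo && x <= lo) || (!strict_lo && x < lo) || x > hi)
    stopf("'%s' = %s is outside the allowed range %s%s, %s]",
          name, format(x), if (strict_lo) "(" else "[", format(lo), format(hi))
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stopf("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

# Counts-per-10k library-size normalization (genes x cells).
normalize_cp10k <- function(counts) {
  libs <- colSums(counts)
  libs[libs == 0] <- 1
  sweep(counts, 2L, libs / 1e4, "/")
}
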