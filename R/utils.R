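# Internal helpers: validation and named-stream RNG.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ca <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Deterministic 31-bit hash of a character stream name (FNV-1a style),
# folded with the master seed so every component of a run draws from its
# own reproducible substream.
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(name)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((abs(seed) + h) %% 2147483647)
}

# Evaluate expr with the RNG seeded from (seed, stream), restoring the
# caller's RNG state afterwards.
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, name))
  expr
}

# Weighted sampling of k items without replacement, probability proportional
# to w at each draw (Efraimidis-Spirakis exponential-key construction, which
# is equivalent to successive draws and vectorizes well).
sample_weighted <- function(n, k, w = NULL) {
  if (k == 0L) return(integer(0))
  if (is.null(w)) return(sample.int(n, k))
  if (k > n) stop_ca("cannot draw %d items from a pool of %d", k, n)
  keys <- rexp(n) / w
  order(keys)[seq_len(k)]
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
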