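# Internal numeric helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators are pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Centered moving average with shrinking (partial) windows at the edges.
# k is the full window length in points; even k is bumped to the next odd.
movavg <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  if (h == 0L) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered rolling min/max (morphological erosion/dilation) with edge-value
# padding; k as in movavg.
roll_extreme <- function(x, k, fun = pmin) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  out <- x
  for (s in seq_len(h)) {
    fwd <- c(x[-seq_len(s)], rep(x[n], s))
    bwd <- c(rep(x[1L], s), x[seq_len(n - s)])
    out <- fun(out, fwd, bwd)
  }
  out
}

# Trapezoidal integral of y over (possibly non-uniform) x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
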