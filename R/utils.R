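# Internal numerical helpers shared across modules.

# Truncated (edge-shrinking) box sum along matrix rows: for each row i,
# sum over rows max(1, i - w) .. min(n, i + w). w = 0 is the identity.
boxsum_rows <- function(m, w) {
  if (w <= 0) return(m)
  n <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  hi <- pmin(n, seq_len(n) + w)
  lo <- pmax(1, seq_len(n) - w)
  cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
}

# 2-D truncated box sum: half-width wx along rows, wz along columns.
boxsum2 <- function(m, wx, wz) {
  out <- boxsum_rows(m, wx)
  if (wz > 0) out <- t(boxsum_rows(t(out), wz))
  out
}

# Trailing running mean along a vector: mean of x[max(1, i-w+1) .. i].
trailing_mean <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(0L, seq_len(n) - w)
  (cs[seq_len(n) + 1L] - cs[lo + 1L]) / (seq_len(n) - lo)
}

# Centered truncated running mean along a vector (half-width w).
centered_mean <- function(x, w) {
  if (w <= 0) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  hi <- pmin(n, seq_len(n) + w)
  lo <- pmax(1L, seq_len(n) - w)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# NA-tolerant centered running mean; positions with no finite neighbours
# stay NA.
centered_mean_na <- function(x, w) {
  if (w <= 0) return(x)
  n <- length(x)
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xs)); cn <- c(0, cumsum(ok))
  hi <- pmin(n, seq_len(n) + w); lo <- pmax(1L, seq_len(n) - w)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

# x first so dim attributes survive (pmax takes attributes from its
# first argument)
clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Run expr with a private RNG stream seeded by `seed`; the caller's
# .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
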