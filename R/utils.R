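# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic 31-bit seed derived from a base seed and a stage label, so a
## single pipeline seed fans out to independently reproducible stages.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647L)
}

## Zero-phase moving average with window shrinking at the edges (so the output
## has the same length as the input and no phase lag).
moving_average <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(x)
  n <- length(x)
  half <- (window - 1L) / 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Otsu threshold (between-class variance maximization) on a numeric sample.
## Used to place state thresholds in the valley of a bimodal log-magnitude
## distribution. Returns a value on the scale of `x`.
otsu_threshold <- function(x, n_bins = 128) {
  x <- x[is.finite(x)]
  stopifnot(length(x) > 1)
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  crit <- ifelse(den > 0, num / den, 0)
  mids[which.max(crit)]
}

## Nearest rotation matrix by polar decomposition (SVD), used to
## re-orthonormalize the 3D body frame each integration step.
polar_orthonormalize <- function(m) {
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    s$u[, 3] <- -s$u[, 3]
    r <- s$u %*% t(s$v)
  }
  r
}

## Run-length segments of a logical vector: data.frame(start, end) of TRUE runs.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

## Evaluate with a locally-scoped RNG state when `seed` is not NULL.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
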