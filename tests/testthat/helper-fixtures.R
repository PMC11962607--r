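# Shared fixtures built in code.

# Straight-line track: constant velocity v along angle alpha, dt = 1 s.
make_line_track <- function(n = 20, v = 2, alpha = 0, dt = 1,
                            body_length = 10, id = "line") {
  t <- (seq_len(n) - 1) * dt
  pos <- cbind(v * t * cos(alpha), v * t * sin(alpha))
  dg_track(id, t, pos, theta = rep(alpha %% (2 * pi), n),
           body_length = body_length)
}

# Deterministic circular track of radius R at angular rate w (rad/s).
make_circle_track <- function(n = 100, R = 5, w = 0.2, dt = 1,
                              body_length = 10, id = "circle") {
  t <- (seq_len(n) - 1) * dt
  phi <- w * t
  pos <- cbind(R * cos(phi), R * sin(phi))
  dg_track(id, t, pos, theta = (phi + pi / 2) %% (2 * pi),
           body_length = body_length)
}

# Brute-force two-branch dynamic program: the orientation series (mod pi
# ambiguous) minimizing total absolute rotation. Independent oracle for
# unwrap_orientation.
dp_unwrap <- function(theta) {
  n <- length(theta)
  branch <- cbind(theta %% (2 * pi), (theta + pi) %% (2 * pi))
  cost <- matrix(Inf, n, 2)
  back <- matrix(NA_integer_, n, 2)
  cost[1, 1] <- 0
  cost[1, 2] <- Inf  # first value kept as reported
  rot <- function(a, b) {
    d <- abs(b - a) %% (2 * pi)
    min(d, 2 * pi - d)
  }
  for (i in 2:n) for (j in 1:2) for (p in 1:2) {
    cc <- cost[i - 1, p] + rot(branch[i - 1, p], branch[i, j])
    if (cc < cost[i, j]) { cost[i, j] <- cc; back[i, j] <- p }
  }
  path <- integer(n)
  path[n] <- which.min(cost[n, ])
  for (i in n:2) path[i - 1] <- back[i, path[i]]
  branch[cbind(seq_len(n), path)]
}

# Quantile of v in 1..length via manual linear interpolation (type-7 oracle).
type7_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# Circular difference mapped to (-pi, pi].
circ_diff_test <- function(th) {
  d <- diff(th) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

# State names in canonical order (local alias, not a package internal).
DG_STATES_test <- function() c("Glide", "Stop", "Pivot", "Reverse")

# Seeded evaluation that modifies variables in the caller's frame.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  res <- eval.parent(substitute(expr))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  invisible(res)
}
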