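track_positions <- function(tr) {
  if (inherits(tr, "dg_track")) tr$positions else as.matrix(tr)
}

#' Time- and ensemble-averaged mean squared displacement
#'
#' `MSD(tau) = < || r(t_i + tau) - r(t_i) ||^2 >` averaged over all start
#' times `t_i` (overlapping windows) and all tracks, with the 10th/90th
#' percentile band of the pooled squared displacements. Tracks shorter than
#' a requested lag simply contribute no pairs at that lag (the lag set is
#' silently limited to the longest track).
#'
#' @param tracks List of [dg_track()] objects (2D or 3D) or position
#'   matrices.
#' @param lags Integer lags in frames (default `1:max_lag`).
#' @param max_lag Maximum lag in frames (default: longest track - 1,
#'   capped at 600 when `lags` is not given).
#' @param full_duration_only Keep only tracks spanning the full (longest)
#'   recording, removing the survivorship bias of interrupted tracks.
#' @param dt Frame interval in seconds (default: from the first track).
#' @return A `dg_msd` data.frame with columns `lag`, `msd`, `p10`, `p90`,
#'   `n_pairs`; attributes `per_track` (track x lag matrix of per-track
#'   MSDs), `dim` (spatial dimension), `dt`.
#' @export
compute_msd <- function(tracks, lags = NULL, max_lag = NULL,
                        full_duration_only = FALSE, dt = NULL) {
  if (inherits(tracks, "dg_track") || is.matrix(tracks)) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1)
  dt <- dt %||% (if (inherits(tracks[[1]], "dg_track")) tracks[[1]]$dt else 1)
  pos <- lapply(tracks, track_positions)
  lens <- vapply(pos, nrow, integer(1))
  if (full_duration_only) {
    keep <- lens == max(lens)
    pos <- pos[keep]; lens <- lens[keep]
  }
  longest <- max(lens)
  if (is.null(lags)) {
    max_lag <- max_lag %||% min(longest - 1L, 600L)
    lags <- seq_len(min(max_lag, longest - 1L))
  }
  lags <- sort(unique(as.integer(lags)))
  lags <- lags[lags >= 1 & lags <= longest - 1L]
  d_spatial <- ncol(pos[[1]])
  n_tr <- length(pos)
  per_track <- matrix(NA_real_, n_tr, length(lags))
  n_pairs_tr <- matrix(0L, n_tr, length(lags))
  p10 <- p90 <- rep(NA_real_, length(lags))
  for (j in seq_along(lags)) {
    L <- lags[j]
    pooled <- vector("list", n_tr)
    for (i in seq_len(n_tr)) {
      n <- lens[i]
      if (n <= L) next
      dmat <- pos[[i]][(1 + L):n, , drop = FALSE] -
        pos[[i]][1:(n - L), , drop = FALSE]
      sq <- rowSums(dmat^2)
      per_track[i, j] <- mean(sq)
      n_pairs_tr[i, j] <- length(sq)
      pooled[[i]] <- sq
    }
    all_sq <- unlist(pooled, use.names = FALSE)
    if (length(all_sq) > 0) {
      qq <- stats::quantile(all_sq, c(0.1, 0.9), names = FALSE)
      p10[j] <- qq[1]; p90[j] <- qq[2]
    }
  }
  n_pairs <- colSums(n_pairs_tr)
  msd <- colSums(per_track * n_pairs_tr, na.rm = TRUE) / pmax(n_pairs, 1)
  out <- data.frame(lag = lags * dt, msd = msd, p10 = p10, p90 = p90,
                    n_pairs = n_pairs)
  out <- out[n_pairs > 0, , drop = FALSE]
  attr(out, "per_track") <- per_track[, n_pairs > 0, drop = FALSE]
  attr(out, "n_pairs_track") <- n_pairs_tr[, n_pairs > 0, drop = FALSE]
  attr(out, "spatial_dim") <- d_spatial
  attr(out, "dt") <- dt
  class(out) <- c("dg_msd", "data.frame")
  out
}

#' Normalized velocity autocorrelation function
#'
#' `VACF(tau) = < v(t) . v(t + tau) > / < |v|^2 >` with frame-wise
#' velocities, averaged over start times and tracks. For glide-reverse
#' (telegraph) motion the decay is approximately `exp(-2 lambda tau)` with
#' reversal rate `lambda`.
#'
#' @inheritParams compute_msd
#' @param max_lag Maximum lag in frames (default: half the longest track,
#'   capped at 300).
#' @return data.frame with columns `lag`, `vacf`, `n_pairs`;
#'   `vacf[lag == 0] == 1`.
#' @export
compute_vacf <- function(tracks, max_lag = NULL, dt = NULL) {
  if (inherits(tracks, "dg_track") || is.matrix(tracks)) tracks <- list(tracks)
  dt <- dt %||% (if (inherits(tracks[[1]], "dg_track")) tracks[[1]]$dt else 1)
  vel <- lapply(tracks, function(tr) diff(track_positions(tr)) / dt)
  lens <- vapply(vel, nrow, integer(1))
  if (max(lens) < 2) stop("need tracks with at least 3 frames")
  max_lag <- max_lag %||% min(floor(max(lens) / 2), 300L)
  lags <- 0:max_lag
  num <- den_pairs <- numeric(length(lags))
  for (j in seq_along(lags)) {
    L <- lags[j]
    for (i in seq_along(vel)) {
      n <- lens[i]
      if (n <= L) next
      a <- vel[[i]][1:(n - L), , drop = FALSE]
      b <- vel[[i]][(1 + L):n, , drop = FALSE]
      num[j] <- num[j] + sum(a * b)
      den_pairs[j] <- den_pairs[j] + (n - L)
    }
  }
  norm0 <- num[1] / den_pairs[1]  # < |v|^2 >
  data.frame(lag = lags * dt, vacf = (num / pmax(den_pairs, 1)) / norm0,
             n_pairs = den_pairs)
}

#' Local MSD scaling exponent
#'
#' `d log MSD / d log tau` by central finite differences of the log-log
#' curve, lightly smoothed with a 3-point moving average; labels the
#' regimes ballistic (>= 1.5, slope near 2), diffusive, and sublinear
#' (< 0.9).
#'
#' @param msd A `dg_msd` (needs >= 5 lags).
#' @return data.frame with columns `lag`, `exponent`, `regime`.
#' @export
local_exponent <- function(msd) {
  ok <- msd$msd > 0 & msd$lag > 0
  lt <- log(msd$lag[ok]); lm <- log(msd$msd[ok])
  if (length(lt) < 5) stop("need at least 5 positive lags")
  n <- length(lt)
  e <- numeric(n)
  e[2:(n - 1)] <- (lm[3:n] - lm[1:(n - 2)]) / (lt[3:n] - lt[1:(n - 2)])
  e[1] <- (lm[2] - lm[1]) / (lt[2] - lt[1])
  e[n] <- (lm[n] - lm[n - 1]) / (lt[n] - lt[n - 1])
  e <- moving_average(e, 3)
  regime <- cut(e, breaks = c(-Inf, 0.9, 1.5, Inf),
                labels = c("sublinear", "diffusive", "ballistic"))
  data.frame(lag = msd$lag[ok], exponent = e, regime = regime)
}

#' Long-time diffusivity from the MSD
#'
#' Fits `MSD = 2 d D tau + c` by weighted least squares (weights
#' proportional to the number of displacement pairs per lag) over a lag
#' window inside the diffusive regime, with a bootstrap confidence interval
#' over tracks. The convention is `MSD = 2 d D tau` with `d` the spatial
#' dimension (4 D tau in 2D, 6 D tau in 3D).
#'
#' @param msd A `dg_msd`.
#' @param fit_window Numeric `c(lo, hi)` lag window in seconds. Default:
#'   the last decade of available lags restricted to local exponent in
#'   `[0.9, 1.1]`.
#' @param n_boot Bootstrap replicates over tracks (default 200; 0 disables).
#' @param seed Optional RNG seed for the bootstrap.
#' @param dimension Spatial dimension for the `2 d D tau` convention;
#'   defaults to the track dimension. Pass 1 for motion confined to a line
#'   (e.g. pure run-and-reverse with rotation off).
#' @return List with `D` (um^2/s), `ci` (2.5/97.5 percentiles), `slope`,
#'   `window`, `local_exponent_in_window`, `warning` (NULL or text).
#' @export
estimate_diffusivity <- function(msd, fit_window = NULL, n_boot = 200,
                                 seed = NULL, dimension = NULL) {
  d_spatial <- dimension %||% attr(msd, "spatial_dim") %||% 2
  le <- local_exponent(msd)
  warn <- NULL
  if (is.null(fit_window)) {
    hi <- max(msd$lag)
    cand <- le$lag >= hi / 10 & le$exponent >= 0.9 & le$exponent <= 1.1
    if (!any(cand)) {
      warn <- sprintf(
        "no diffusive window found (median local exponent %.2f in last decade); using last decade",
        stats::median(le$exponent[le$lag >= hi / 10]))
      fit_window <- c(hi / 10, hi)
    } else fit_window <- range(le$lag[cand])
  }
  sel <- msd$lag >= fit_window[1] & msd$lag <= fit_window[2]
  if (sum(sel) < 2) stop("fit window contains fewer than 2 lags")
  exp_in <- le$exponent[le$lag >= fit_window[1] & le$lag <= fit_window[2]]
  if (is.null(warn) && (stats::median(exp_in) < 0.8 ||
                        stats::median(exp_in) > 1.2))
    warn <- sprintf("fit window not diffusive: median local exponent %.2f",
                    stats::median(exp_in))
  wfit <- function(m) {
    f <- stats::lm(m[sel] ~ msd$lag[sel], weights = msd$n_pairs[sel])
    unname(stats::coef(f)[2])
  }
  slope <- wfit(msd$msd)
  D <- slope / (2 * d_spatial)
  ci <- c(NA_real_, NA_real_)
  pt <- attr(msd, "per_track")
  npt <- attr(msd, "n_pairs_track")
  if (n_boot > 0 && !is.null(pt) && nrow(pt) > 1) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(pt), replace = TRUE)
      w <- colSums(npt[idx, , drop = FALSE])
      m <- colSums(pt[idx, , drop = FALSE] * npt[idx, , drop = FALSE],
                   na.rm = TRUE) / pmax(w, 1)
      wfit(m) / (2 * d_spatial)
    }, numeric(1)))
    ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  }
  if (!is.null(warn)) warning(warn)
  list(D = D, ci = ci, slope = slope, window = fit_window,
       local_exponent_in_window = stats::median(exp_in), warning = warn)
}
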