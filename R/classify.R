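#' Denoise the tangential velocity series
#'
#' Running-median filter followed by a zero-phase moving average (both with
#' odd windows, default 5). The median removes single-frame tracking spikes
#' without smearing edges; the average suppresses the remaining frame-to-
#' frame noise. Sign changes of sustained direction switches are preserved
#' to within about 2 frames at the default windows.
#'
#' @param v_par Signed tangential velocity series (um/s).
#' @param median_window,mean_window Odd filter windows (default 5).
#' @return Filtered series `v_tilde`, same length.
#' @export
preprocess_velocity <- function(v_par, median_window = 5, mean_window = 5) {
  n <- length(v_par)
  if (n < 5) stop("data error: series shorter than 5 frames")
  if (median_window > n || mean_window > n)
    stop("data error: filter window larger than the series")
  med <- stats::runmed(v_par, median_window, endrule = "keep")
  moving_average(as.numeric(med), mean_window)
}

#' Classify per-frame motility states
#'
#' Assigns one of the four stereotyped states to every kinematic frame from
#' the denoised tangential speed and the rotation rate:
#' * **Glide** -- `|v_tilde| >= v_stop` (persistent directed motion);
#' * **Stop** -- `|v_tilde| < v_stop` and `|omega| < omega_pivot`;
#' * **Pivot** -- `|v_tilde| < v_stop` and `|omega| >= omega_pivot`
#'   (rotation about one cell end without net translation);
#' * **Reverse** -- a sign flip of the tangential velocity between two
#'   directed runs of at least `persistence` frames each, separated by at
#'   most `max_gap` sub-threshold frames; the whole gap (bounded by
#'   `max_run`) is labelled Reverse. Sign flips inside stops are not
#'   reversals: a reversal re-establishes directed motion. Sign detection
#'   uses `v_sign` -- by default a lightly filtered (3-point running
#'   median) copy of the tangential velocity rather than the heavily
#'   smoothed `v_tilde`, because a reversal is a large-amplitude sign flip
#'   that needs temporal sharpness, not smoothing.
#'
#' Polarity `s(t)` starts at +1 and flips once per Reverse event.
#'
#' @param v_tilde Denoised tangential velocity (see [preprocess_velocity()]).
#' @param omega Rotation rate series (rad/s), same length.
#' @param v_stop Speed threshold (um/s).
#' @param omega_pivot Rotation threshold (rad/s).
#' @param v_sign Signal used for reversal sign detection (default
#'   `v_tilde`; [classify_dataset()] passes the median-3 filtered raw
#'   velocity).
#' @param persistence Minimum consistent-sign directed frames on each side
#'   of a reversal (default 1; the supra-threshold sign of the filtered
#'   velocity is already a high-confidence signal, and a larger value
#'   suppresses reversals flanked by short glides).
#' @param max_gap Maximum sub-threshold frames between the two glides of a
#'   reversal (default 4, matching the ramp width the sign filter
#'   introduces around an instantaneous reversal).
#' @param max_run Cap on the length of a labelled Reverse run (default 5).
#' @return A `dg_states` data.frame with columns `label` (factor with levels
#'   Glide, Stop, Pivot, Reverse), `polarity`, `v_tilde`.
#' @export
classify_states <- function(v_tilde, omega, v_stop, omega_pivot,
                            v_sign = v_tilde, persistence = 1, max_gap = 4,
                            max_run = 5) {
  n <- length(v_tilde)
  stopifnot(length(omega) == n, length(v_sign) == n)
  if (!all(is.finite(v_tilde)) || !all(is.finite(omega)))
    stop("data error: non-finite values in classifier input")
  lab <- ifelse(abs(v_tilde) >= v_stop, "Glide",
                ifelse(abs(omega) >= omega_pivot, "Pivot", "Stop"))
  # signed directed-motion indicator: +-1 when moving, 0 otherwise
  sgn <- ifelse(abs(v_sign) >= v_stop, sign(v_sign), 0)
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rev_at <- integer(0)
  k <- length(runs$values)
  for (i in seq_len(k)) {
    if (runs$values[i] == 0 || runs$lengths[i] < persistence) next
    # find next glide run with enough persistence
    j <- i + 1L
    gap <- 0L
    while (j <= k && (runs$values[j] == 0 ||
                      runs$lengths[j] < persistence)) {
      gap <- gap + runs$lengths[j]
      j <- j + 1L
    }
    if (j > k || gap > max_gap) next
    if (runs$values[j] == -runs$values[i]) {
      lo <- ends[i] + 1L
      hi <- starts[j] - 1L
      if (hi < lo) { # adjacent frames: mark the first frame of the new glide
        rev_frames <- starts[j]
      } else {
        if (hi - lo + 1L > max_run) { # clamp long gaps around the midpoint
          mid <- (lo + hi) %/% 2L
          lo <- max(lo, mid - (max_run - 1L) %/% 2L)
          hi <- min(hi, lo + max_run - 1L)
        }
        rev_frames <- lo:hi
      }
      lab[rev_frames] <- "Reverse"
      rev_at <- c(rev_at, rev_frames[1])
    }
  }
  polarity <- rep(1L, n)
  if (length(rev_at) > 0) {
    flips <- rep(0L, n)
    flips[rev_at] <- 1L
    polarity <- ifelse(cumsum(flips) %% 2 == 0, 1L, -1L)
  }
  out <- data.frame(
    label = factor(lab, levels = c("Glide", "Stop", "Pivot", "Reverse")),
    polarity = polarity, v_tilde = v_tilde)
  class(out) <- c("dg_states", "data.frame")
  out
}

#' Merge sub-resolution label runs into their neighbours
#'
#' Non-Reverse runs shorter than `min_run` frames are absorbed into the
#' preceding run (the following run at the sequence start), iterating until
#' stable. The frame classifier cannot resolve sojourns below the width of
#' its velocity filter, so such fragments are threshold-crossing noise, not
#' state visits; the transition-model estimators apply this before counting
#' and correct the resulting censoring of genuinely short sojourns.
#'
#' @param lab Character/factor label vector.
#' @param min_run Minimum run length in frames (default 3).
#' @return Character label vector.
#' @export
absorb_short_runs <- function(lab, min_run = 3) {
  lab <- as.character(lab)
  if (min_run <= 1) return(lab)
  repeat {
    r <- rle(lab)
    m <- length(r$values)
    if (m <= 1) break
    short <- r$lengths < min_run & r$values != "Reverse"
    if (!any(short)) break
    # single left-to-right pass: every short run takes the value of the
    # nearest preceding kept run (the first kept run's value at the start)
    first_kept <- which(!short)[1]
    if (is.na(first_kept)) break
    vals <- r$values
    carry <- NA_character_
    for (q in seq_len(m)) {
      if (short[q]) {
        vals[q] <- if (is.na(carry)) r$values[first_kept] else carry
      } else carry <- vals[q]
    }
    r$values <- vals
    lab <- inverse.rle(r)
  }
  lab
}

#' Derive per-species state thresholds from pooled kinematics
#'
#' The pooled magnitudes `|v_tilde|` are modelled as a two-component
#' mixture of a half-normal (the stationary states' fluctuations around
#' zero) and a normal centred at the glide speed; `v_stop` is placed at
#' the posterior crossover of the two fitted components. `omega_pivot` is
#' derived the same way from `|omega|` over slow frames not adjacent to
#' any glide frame (ramps into and out of glides carry glide-level
#' rotation noise and would otherwise form a spurious low mode). The
#' states occupy similar regions of `{|v_par|, |omega|}` space across
#' species but are shifted in absolute value, so thresholds are
#' data-driven per dataset and overridable.
#'
#' @param ks_list List of `dg_kinematics` (one per track).
#' @param guard Frames of dilation around glide frames excluded from the
#'   rotation pool (default 3).
#' @param omega_window Denoising windows applied to the rotation channel
#'   before thresholding (default 3; must match classification).
#' @return List with `v_stop` (um/s) and `omega_pivot` (rad/s).
#' @export
derive_state_thresholds <- function(ks_list, guard = 3L, omega_window = 3) {
  vt_list <- lapply(ks_list, function(k) preprocess_velocity(k$v_par))
  v <- abs(unlist(vt_list, use.names = FALSE))
  v_stop <- magnitude_split(v)
  w <- unlist(lapply(seq_along(ks_list), function(i) {
    fast <- abs(vt_list[[i]]) >= v_stop
    near_fast <- dilate_logical(fast, guard)
    ws <- preprocess_velocity(ks_list[[i]]$omega, omega_window, omega_window)
    abs(ws[!near_fast])
  }), use.names = FALSE)
  omega_pivot <- if (length(w) >= 50) magnitude_split(w)
  else 3 * stats::sd(unlist(lapply(ks_list, `[[`, "omega")), na.rm = TRUE)
  list(v_stop = v_stop, omega_pivot = omega_pivot)
}

## Logical dilation by k frames on both sides.
dilate_logical <- function(x, k) {
  if (k <= 0 || !any(x)) return(x)
  idx <- which(x)
  out <- logical(length(x))
  for (d in -k:k) {
    sh <- idx + d
    sh <- sh[sh >= 1 & sh <= length(x)]
    out[sh] <- TRUE
  }
  out
}

## Threshold between a half-normal noise component (scale sigma1, around
## zero) and a displaced normal component (mean mu2 > 0), fitted to
## positive magnitudes by EM. Returns the posterior crossover between the
## fitted components; falls back to 3 * sigma1 if the displaced component
## collapses.
magnitude_split <- function(x, max_iter = 300) {
  x <- x[is.finite(x) & x >= 0]
  # (near-)constant pool: a nonzero constant is directed motion, so the
  # threshold sits below it; an all-zero pool gets an epsilon threshold
  if (length(unique(x)) < 3) return(max(x) / 2 + 1e-12)
  s1 <- stats::median(x) / 0.6745   # robust half-normal scale if majority
  mu2 <- stats::quantile(x, 0.95, names = FALSE)
  s2 <- max(mu2 / 4, 1e-9)
  w1 <- 0.6
  for (i in seq_len(max_iter)) {
    f1 <- 2 * stats::dnorm(x, 0, s1)
    f2 <- stats::dnorm(x, mu2, s2) + stats::dnorm(x, -mu2, s2)
    g <- w1 * f1 / pmax(w1 * f1 + (1 - w1) * f2, 1e-300)
    w1_new <- mean(g)
    if (w1_new < 1e-3 || w1_new > 1 - 1e-3) break
    s1_new <- sqrt(sum(g * x^2) / sum(g))
    # responsibilities of the +/- branches within component 2
    dp <- stats::dnorm(x, mu2, s2); dm <- stats::dnorm(x, -mu2, s2)
    rp <- dp / pmax(dp + dm, 1e-300)
    g2 <- 1 - g
    mu2_new <- sum(g2 * x * (2 * rp - 1)) / sum(g2)
    s2_new <- sqrt(sum(g2 * (rp * (x - mu2_new)^2 +
                               (1 - rp) * (x + mu2_new)^2)) / sum(g2))
    conv <- max(abs(c(s1_new - s1, mu2_new - mu2, s2_new - s2,
                      w1_new - w1)))
    s1 <- max(s1_new, 1e-12); mu2 <- mu2_new
    s2 <- max(s2_new, 1e-12); w1 <- w1_new
    if (conv < 1e-9) break
  }
  if (w1 < 1e-3 || w1 > 1 - 1e-3 || mu2 < 2 * s1) {
    # unimodal pool: decide which single state dominates. A mode far from
    # zero (median >> MAD) is directed motion, so the threshold must sit
    # below it; otherwise everything is noise around zero.
    med <- stats::median(x)
    if (med > 3 * stats::mad(x)) return(med / 2)
    return(max(3 * s1, stats::quantile(x, 0.95, names = FALSE)))
  }
  grid <- seq(s1 / 2, mu2, length.out = 500)
  lhs <- w1 * 2 * stats::dnorm(grid, 0, s1)
  rhs <- (1 - w1) * (stats::dnorm(grid, mu2, s2) +
                       stats::dnorm(grid, -mu2, s2))
  cross <- which(lhs < rhs)
  thr <- if (length(cross) == 0) mean(c(3 * s1, mu2 - 2 * s2))
         else grid[cross[1]]
  # cap at half the displaced mode: a threshold close to the mode would
  # stretch the sub-threshold ramps around transitions beyond the reversal
  # detector's gap window
  min(thr, max(0.5 * mu2, 3 * s1))
}

#' Classify every track of a dataset
#'
#' Convenience wrapper: preprocesses each track's tangential velocity,
#' derives thresholds from the pool unless given, and classifies each track.
#'
#' The tangential channel is denoised with the default 5/5 windows; the
#' rotation channel with shorter 3/3 windows (pivots are briefer than
#' glides, and the raw per-frame rotation rate would fragment them at the
#' threshold).
#'
#' @param ks_list List of `dg_kinematics`.
#' @param thresholds Optional list(v_stop, omega_pivot); derived via
#'   [derive_state_thresholds()] when `NULL`.
#' @param omega_window Denoising windows for the rotation channel
#'   (default 3).
#' @param ... Passed to [classify_states()].
#' @return List with `states` (list of `dg_states`) and `thresholds`.
#' @export
classify_dataset <- function(ks_list, thresholds = NULL, omega_window = 3,
                             ...) {
  if (is.null(thresholds))
    thresholds <- derive_state_thresholds(ks_list,
                                          omega_window = omega_window)
  states <- lapply(ks_list, function(k) {
    classify_states(preprocess_velocity(k$v_par),
                    preprocess_velocity(k$omega, omega_window, omega_window),
                    thresholds$v_stop, thresholds$omega_pivot,
                    v_sign = as.numeric(stats::runmed(k$v_par, 3,
                                                      endrule = "keep")),
                    ...)
  })
  list(states = states, thresholds = thresholds)
}

#' Reconstruct polarity from Reverse frames
#'
#' @param labels Factor/character state labels.
#' @return Integer polarity series (+1/-1), flipping at the first frame of
#'   each Reverse run.
#' @export
polarity_from_labels <- function(labels) {
  is_rev <- labels == "Reverse"
  event_start <- is_rev & !c(FALSE, is_rev[-length(is_rev)])
  ifelse(cumsum(event_start) %% 2 == 0, 1L, -1L)
}

#' Time fraction spent in each state
#'
#' @param seqs List of `dg_states` or of label vectors (or a single one).
#' @return Named numeric vector over the four states, summing to 1.
#' @export
occupancy_fractions <- function(seqs) {
  if (is.data.frame(seqs) || is.atomic(seqs)) seqs <- list(seqs)
  if (length(seqs) == 0) stop("no state sequences supplied")
  labs <- unlist(lapply(seqs, function(s)
    if (is.data.frame(s)) as.character(s$label) else as.character(s)),
    use.names = FALSE)
  tab <- table(factor(labs, levels = c("Glide", "Stop", "Pivot", "Reverse")))
  fr <- as.numeric(tab) / sum(tab)
  names(fr) <- names(tab)
  fr
}

#' State regions in log-speed / log-rotation space
#'
#' For each state, pools `(log10(|v_par|+shift), log10(|omega|+shift))`
#' points across tracks, builds a smoothed bivariate histogram, and computes
#' the convex hull of the densest fraction of points (default 97.5%,
#' dropping the 2.5% of points in the lowest-density bins first).
#'
#' @param seqs List of `dg_states`.
#' @param ks_list Matching list of `dg_kinematics`.
#' @param shift Additive shift before logs (default 0.01).
#' @param n_bins Histogram bins per axis (default 40).
#' @param hull_fraction Fraction of points the hull must cover (default 0.975).
#' @param smooth_sd Gaussian smoothing SD in bins (default 1).
#' @param min_points Minimum pooled points required per state (default 20).
#' @return Named list per state: `histogram` (list x, y, z), `hull`
#'   (matrix of hull vertices, possibly degenerate), `n_points`.
#' @export
state_region_hull <- function(seqs, ks_list, shift = 0.01, n_bins = 40,
                              hull_fraction = 0.975, smooth_sd = 1,
                              min_points = 20) {
  labs <- unlist(lapply(seqs, function(s) as.character(s$label)))
  v <- unlist(lapply(ks_list, function(k) k$v_par))
  w <- unlist(lapply(ks_list, function(k) k$omega))
  x <- log10(abs(v) + shift)
  y <- log10(abs(w) + shift)
  out <- list()
  for (st in c("Glide", "Stop", "Pivot", "Reverse")) {
    sel <- labs == st & is.finite(x) & is.finite(y)
    if (sum(sel) < min_points)
      stop("data error: fewer than ", min_points, " points for state ", st)
    xs <- x[sel]; ys <- y[sel]
    xb <- seq(min(xs), max(xs), length.out = n_bins + 1)
    yb <- seq(min(ys), max(ys), length.out = n_bins + 1)
    ix <- findInterval(xs, xb, all.inside = TRUE)
    iy <- findInterval(ys, yb, all.inside = TRUE)
    z <- matrix(0, n_bins, n_bins)
    for (i in seq_along(ix)) z[ix[i], iy[i]] <- z[ix[i], iy[i]] + 1
    z <- gauss_smooth2d(z, smooth_sd)
    dens <- z[cbind(ix, iy)]
    ord <- order(dens, decreasing = TRUE)
    keep <- ord[seq_len(ceiling(hull_fraction * length(ord)))]
    px <- xs[keep]; py <- ys[keep]
    hull <- if (length(unique(paste(px, py))) < 3) {
      cbind(px, py)[!duplicated(cbind(px, py)), , drop = FALSE]
    } else {
      idx <- grDevices::chull(px, py)
      cbind(px[idx], py[idx])
    }
    out[[st]] <- list(
      histogram = list(x = (xb[-1] + xb[-length(xb)]) / 2,
                       y = (yb[-1] + yb[-length(yb)]) / 2, z = z),
      hull = hull, n_points = sum(sel))
  }
  out
}

## Separable Gaussian smoothing of a matrix (reflective edges).
gauss_smooth2d <- function(z, sd_bins) {
  if (sd_bins <= 0) return(z)
  r <- ceiling(3 * sd_bins)
  kern <- stats::dnorm(-r:r, sd = sd_bins)
  kern <- kern / sum(kern)
  smooth_vec <- function(v) {
    vp <- c(rev(v[seq_len(r)]), v, rev(v[(length(v) - r + 1):length(v)]))
    as.numeric(stats::filter(vp, kern, sides = 2))[(r + 1):(r + length(v))]
  }
  z <- apply(z, 2, smooth_vec)
  t(apply(t(z), 2, smooth_vec))
}
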