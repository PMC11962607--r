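#' Construct a polyline (track path or traced raphe)
#'
#' @param points Numeric matrix (n x 2) of ordered x,y coordinates in um.
#' @param kind `"track"` or `"raphe"`.
#' @return A `dg_polyline`.
#' @export
dg_polyline <- function(points, kind = c("track", "raphe")) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  if (nrow(points) < 3) stop("polyline needs at least 3 points")
  structure(list(points = unname(points), kind = kind), class = "dg_polyline")
}

polyline_points <- function(poly) {
  if (inherits(poly, "dg_polyline")) poly$points else as.matrix(poly)
}

arclength <- function(pts) c(0, cumsum(sqrt(rowSums(diff(pts)^2))))

#' Resample a polyline at uniform arclength spacing
#'
#' Linear interpolation along the polyline at equally spaced arclength
#' positions, so curvature estimates use the same spatial resolution across
#' raphes and tracks. Endpoints are preserved; the actual spacing is the
#' total arclength divided into `round(L/step)` equal pieces (closest uniform
#' spacing to `step`).
#'
#' @param poly A `dg_polyline` or point matrix.
#' @param step Target spacing in um (> 0).
#' @return A resampled `dg_polyline`.
#' @export
resample_polyline <- function(poly, step) {
  stopifnot(step > 0)
  pts <- polyline_points(poly)
  s <- arclength(pts)
  L <- s[length(s)]
  if (L < 2 * step) stop("data error: polyline arclength (", signif(L, 4),
                         " um) shorter than 2 steps")
  # drop zero-length segments so interpolation is well defined
  keep <- c(TRUE, diff(s) > 0)
  pts <- pts[keep, , drop = FALSE]
  s <- s[keep]
  n_seg <- max(2L, round(L / step))
  s_new <- seq(0, L, length.out = n_seg + 1L)
  out <- cbind(stats::approx(s, pts[, 1], xout = s_new)$y,
               stats::approx(s, pts[, 2], xout = s_new)$y)
  dg_polyline(out, kind = if (inherits(poly, "dg_polyline")) poly$kind else "track")
}

## Curvature (1/R) of the circle through three points; 0 when the triangle
## area is below `area_tol` (collinear, infinite radius).
circle3_curvature <- function(p1, p2, p3, area_tol = 1e-12) {
  a <- sqrt(sum((p2 - p1)^2))
  b <- sqrt(sum((p3 - p2)^2))
  cc <- sqrt(sum((p3 - p1)^2))
  area2 <- abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
               (p3[1] - p1[1]) * (p2[2] - p1[2]))  # 2 * triangle area
  if (area2 / 2 < area_tol) return(0)
  # kappa = 1/R = 4 * area / (a b c)
  2 * area2 / (a * b * cc)
}

#' Moving-window three-point circle-fit curvature
#'
#' Slides a window of `window_points` consecutive points along the polyline
#' and fits a circle through the first, middle, and last point of each
#' window; the unsigned curvature is the inverse circle radius. Collinear
#' triplets give curvature 0.
#'
#' @param poly A `dg_polyline`, typically resampled via [resample_polyline()].
#' @param window_points Odd window size in points (>= 3, default 5).
#' @return A `dg_curvature` list with `kappa` (length
#'   `n_points - window_points + 1`), `window_points`, and `resolution`
#'   (mean point spacing in um).
#' @export
curvature_profile <- function(poly, window_points = 5) {
  stopifnot(window_points >= 3, window_points %% 2 == 1)
  pts <- polyline_points(poly)
  n <- nrow(pts)
  if (n < window_points) stop("polyline shorter than the window")
  half <- (window_points - 1L) / 2L
  n_win <- n - window_points + 1L
  kappa <- vapply(seq_len(n_win), function(i) {
    circle3_curvature(pts[i, ], pts[i + half, ], pts[i + window_points - 1L, ])
  }, numeric(1))
  seg <- sqrt(rowSums(diff(pts)^2))
  structure(list(kappa = kappa, window_points = window_points,
                 resolution = mean(seg)),
            class = "dg_curvature")
}

#' Per-frame curvature of a track
#'
#' Three-point circle fits on the raw frame positions (window in frames),
#' aligned to frames for use in glide segmentation: entry `i` is the
#' curvature of the window centred on frame `i`; the first and last
#' `(window-1)/2` entries are `NA`.
#'
#' @param track A [dg_track()].
#' @param window_frames Odd window size in frames (default 5).
#' @return Numeric vector of length `n_frames(track)` with NA padding.
#' @export
track_curvature <- function(track, window_frames = 5) {
  pts <- track$positions[, 1:2, drop = FALSE]
  n <- nrow(pts)
  half <- (window_frames - 1L) / 2L
  out <- rep(NA_real_, n)
  if (n >= window_frames) {
    prof <- curvature_profile(dg_polyline(pts), window_frames)
    out[(half + 1L):(n - half)] <- prof$kappa
  }
  out
}

#' Split a track into glide segments by a curvature threshold
#'
#' Glides are maximal runs of frames whose local track curvature stays below
#' `kappa_threshold`; runs shorter than `min_windows` windows are dropped
#' (one circle fit needs 3 points, so very short runs carry no curvature
#' information). Each segment gets its mean curvature and mean speed.
#'
#' @param kappa Per-frame curvature vector (e.g. [track_curvature()]), length
#'   `n_frames`; NA entries never start or extend a glide.
#' @param ks The track's `dg_kinematics` (length `n_frames - 1`).
#' @param kappa_threshold Curvature threshold in 1/um.
#' @param min_windows Minimum segment length in windows (default 3).
#' @param window_frames Window size used for `kappa` (default 5).
#' @return data.frame with columns `start`, `end` (frame indices),
#'   `mean_kappa`, `mean_speed`, `n_frames`.
#' @export
segment_glides <- function(kappa, ks, kappa_threshold, min_windows = 3,
                           window_frames = 5) {
  n_fr <- nrow(ks)
  if (length(kappa) != n_fr + 1L)
    stop("data error: curvature (", length(kappa),
         ") and kinematics (", n_fr, ") are misaligned")
  ok <- !is.na(kappa) & kappa < kappa_threshold
  runs <- true_runs(ok)
  min_len <- min_windows + window_frames - 1L
  runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
  if (nrow(runs) == 0)
    return(data.frame(start = integer(), end = integer(),
                      mean_kappa = numeric(), mean_speed = numeric(),
                      n_frames = integer()))
  runs$mean_kappa <- vapply(seq_len(nrow(runs)), function(i)
    mean(kappa[runs$start[i]:runs$end[i]]), numeric(1))
  runs$mean_speed <- vapply(seq_len(nrow(runs)), function(i)
    mean(ks$speed[runs$start[i]:min(runs$end[i], n_fr)]), numeric(1))
  runs$n_frames <- runs$end - runs$start + 1L
  runs
}

#' Select glide segments of median speed
#'
#' Keeps segments whose mean speed lies between the `lo`-th and `hi`-th
#' percentile (type-7, linear interpolation) of the pooled mean-speed
#' distribution. Used to select average-sized diatoms when comparing track
#' curvature against the (smaller) traced-raphe dataset.
#'
#' @param segments data.frame as returned by [segment_glides()] (pooled
#'   across tracks).
#' @param lo,hi Percentile bounds (defaults 45 and 55).
#' @return Filtered data.frame.
#' @export
median_speed_selection <- function(segments, lo = 45, hi = 55) {
  if (nrow(segments) == 0) stop("data error: no glide segments supplied")
  q <- stats::quantile(segments$mean_speed, c(lo, hi) / 100,
                       type = 7, names = FALSE)
  segments[segments$mean_speed >= q[1] & segments$mean_speed <= q[2], ,
           drop = FALSE]
}

#' Compare track and raphe curvature distributions
#'
#' Pools curvature values from gliding track segments and from traced
#' raphes, bins both on a shared logarithmic axis, and reports the
#' two-sample Kolmogorov-Smirnov distance, the histogram overlap
#' coefficient, and a permutation p-value for the KS distance.
#'
#' @param track_kappas,raphe_kappas Numeric curvature pools (1/um, > 0
#'   values are kept; zeros are floored to the smallest positive value).
#' @param n_bins Number of shared log bins (default 30).
#' @param n_perm Permutations for the p-value (default 199; 0 disables).
#' @param seed Optional RNG seed for the permutation test.
#' @return List with `ks_distance`, `overlap`, `p_value`, `breaks` (log10),
#'   `track_density`, `raphe_density`.
#' @export
compare_curvature_distributions <- function(track_kappas, raphe_kappas,
                                            n_bins = 30, n_perm = 199,
                                            seed = NULL) {
  tk <- track_kappas[is.finite(track_kappas)]
  rk <- raphe_kappas[is.finite(raphe_kappas)]
  if (length(tk) == 0 || length(rk) == 0) stop("empty curvature pool")
  floor_pos <- min(c(tk[tk > 0], rk[rk > 0], 1e-6))
  tk <- pmax(tk, floor_pos)
  rk <- pmax(rk, floor_pos)
  lt <- log10(tk); lr <- log10(rk)
  breaks <- seq(min(lt, lr), max(lt, lr), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9
  breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
  ht <- tabulate(findInterval(lt, breaks, all.inside = TRUE), n_bins)
  hr <- tabulate(findInterval(lr, breaks, all.inside = TRUE), n_bins)
  pt <- ht / sum(ht); pr <- hr / sum(hr)
  overlap <- sum(pmin(pt, pr))
  ks_stat <- function(a, b) {
    all_v <- sort(c(a, b))
    Fa <- stats::ecdf(a)(all_v)
    Fb <- stats::ecdf(b)(all_v)
    max(abs(Fa - Fb))
  }
  d_obs <- ks_stat(lt, lr)
  p_value <- NA_real_
  if (n_perm > 0) {
    pooled <- c(lt, lr)
    n1 <- length(lt)
    p_value <- with_seed(seed, {
      exceed <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(pooled), n1)
        ks_stat(pooled[idx], pooled[-idx]) >= d_obs
      }, logical(1))
      (sum(exceed) + 1) / (n_perm + 1)
    })
  }
  list(ks_distance = d_obs, overlap = overlap, p_value = p_value,
       breaks = breaks, track_density = pt, raphe_density = pr)
}
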