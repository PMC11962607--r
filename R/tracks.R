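#' Construct a single-cell track
#'
#' A track is one cell's uniformly sampled time series of centroid position
#' (micrometres), optional body orientation from ellipse fitting (radians),
#' and per-track metadata. 3D tracks from spot tracking carry no orientation.
#'
#' @param track_id Character id.
#' @param times Numeric vector of times in seconds, uniformly spaced.
#' @param positions Numeric matrix with one row per frame and 2 (x, y) or
#'   3 (x, y, z) columns, in micrometres.
#' @param theta Optional orientation in radians per frame (2D tracks only).
#' @param species Species label.
#' @param body_length Cell body length in micrometres (ellipse major axis).
#' @param unwrap If `TRUE` (default) the orientation series is corrected for
#'   the pi-ambiguity of the fitted ellipse via [unwrap_orientation()].
#' @return An object of class `dg_track`.
#' @export
dg_track <- function(track_id, times, positions, theta = NULL,
                     species = "unknown", body_length = NA_real_,
                     unwrap = TRUE) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("track '", track_id, "': needs at least 2 frames")
  if (length(times) != n) stop("track '", track_id, "': times/positions length mismatch")
  if (!all(is.finite(positions))) stop("track '", track_id, "': non-finite positions")
  if (!ncol(positions) %in% c(2L, 3L)) stop("positions must have 2 or 3 columns")
  dts <- diff(times)
  if (any(dts <= 0)) stop("track '", track_id, "': times not strictly increasing")
  if (diff(range(dts)) > 1e-9) {
    stop("track '", track_id, "': non-uniform time spacing")
  }
  if (!is.null(theta)) {
    if (length(theta) != n) stop("track '", track_id, "': theta length mismatch")
    if (anyNA(theta)) stop("track '", track_id, "': NaN/NA in orientation")
    theta <- theta %% (2 * pi)
    if (unwrap) theta <- unwrap_orientation(theta)
  }
  structure(
    list(track_id = as.character(track_id), species = species,
         times = as.numeric(times), positions = unname(positions),
         theta = theta, body_length = body_length,
         dt = dts[1]),
    class = "dg_track")
}

#' @export
print.dg_track <- function(x, ...) {
  cat(sprintf("<dg_track %s> %s, %d frames, dt = %g s, %dD%s, L = %s um\n",
              x$track_id, x$species, nrow(x$positions), x$dt,
              ncol(x$positions),
              if (is.null(x$theta)) " (no orientation)" else "",
              format(x$body_length)))
  invisible(x)
}

n_frames <- function(track) nrow(track$positions)

#' Correct the pi-ambiguity of ellipse orientations
#'
#' Ellipse fitting reports the body axis modulo pi, so the raw orientation
#' series contains spurious half-turn jumps. Frame by frame, whenever the
#' jump from the previous (corrected) frame exceeds pi/2, the current value
#' is replaced by `(theta + pi) mod 2pi` -- the smallest rotation is taken to
#' be the most likely. The first value is kept as reported.
#'
#' @param theta Orientation series in radians.
#' @return Corrected series in `[0, 2pi)` with consecutive absolute
#'   differences (mod 2pi) at most pi/2.
#' @export
unwrap_orientation <- function(theta) {
  if (anyNA(theta)) stop("NaN/NA in orientation series")
  n <- length(theta)
  if (n <= 1) return(theta %% (2 * pi))
  out <- theta %% (2 * pi)
  for (i in 2:n) {
    d <- (out[i] - out[i - 1]) %% (2 * pi)
    if (d > pi) d <- d - 2 * pi
    if (abs(d) > pi / 2) out[i] <- (out[i] + pi) %% (2 * pi)
  }
  out
}

## Circular difference mapped to (-pi, pi]; used for omega = dtheta/dt after
## unwrapping (residual jumps are < pi/2 by construction).
circ_diff <- function(theta) {
  d <- diff(theta) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

#' Frame-wise kinematics of a track
#'
#' Forward-difference velocity `v(t) = (r(t+dt) - r(t))/dt` decomposed into a
#' signed tangential component `v_par = v . u_par` along the body axis
#' `u_par = [cos theta, sin theta]` and a signed normal component
#' `v_perp = v . u_perp` with `u_perp = [-sin theta, cos theta]`, plus the
#' rotation rate `omega = dtheta/dt`. Velocities are assigned to the starting
#' frame of each interval, so the series has `frames - 1` entries. For 3D
#' tracks (no orientation) only speed and heading-free quantities are filled.
#'
#' @param track A [dg_track()].
#' @return A `dg_kinematics` data.frame with columns `t`, `v_par`, `v_perp`,
#'   `omega`, `speed`, `heading`, and attribute `dt`.
#' @export
compute_kinematics <- function(track) {
  stopifnot(inherits(track, "dg_track"))
  n <- n_frames(track)
  if (n < 2) stop("track shorter than 2 frames")
  dt <- track$dt
  dr <- diff(track$positions) / dt
  speed <- sqrt(rowSums(dr^2))
  if (!is.null(track$theta) && ncol(track$positions) == 2) {
    th <- track$theta[-n]
    u_par <- cbind(cos(th), sin(th))
    u_perp <- cbind(-sin(th), cos(th))
    v_par <- rowSums(dr * u_par)
    v_perp <- rowSums(dr * u_perp)
    omega <- circ_diff(track$theta) / dt
    heading <- atan2(dr[, 2], dr[, 1])
  } else {
    v_par <- v_perp <- omega <- rep(NA_real_, n - 1)
    heading <- rep(NA_real_, n - 1)
  }
  out <- data.frame(t = track$times[-n], v_par = v_par, v_perp = v_perp,
                    omega = omega, speed = speed, heading = heading)
  attr(out, "dt") <- dt
  attr(out, "track_id") <- track$track_id
  class(out) <- c("dg_kinematics", "data.frame")
  out
}

#' Cumulative tangential glide distance
#'
#' Running sum `S(t) = sum v_par dt`, the signed distance glided along the
#' body axis. Straight persistent glides appear as near-constant slope and
#' reversals as slope sign changes.
#'
#' @param ks A `dg_kinematics` object (or numeric `v_par` series).
#' @param dt Frame interval in seconds (taken from `ks` when available).
#' @return Numeric vector of length `frames` with `S[1] = 0`.
#' @export
cumulative_tangential <- function(ks, dt = NULL) {
  v <- if (is.data.frame(ks)) ks$v_par else as.numeric(ks)
  dt <- dt %||% attr(ks, "dt") %||% 1
  c(0, cumsum(v * dt))
}

#' Keep only clearly motile tracks
#'
#' Retains tracks whose total path length (sum of frame-to-frame
#' displacements) is at least `factor` times the cell body length. The
#' threshold is inclusive. Total path length (not net displacement) is used,
#' so a cell shuttling back and forth still counts as motile.
#'
#' @param tracks List of [dg_track()] objects.
#' @param factor Minimum number of body lengths travelled (default 15).
#' @return Filtered list of tracks.
#' @export
filter_motile <- function(tracks, factor = 15) {
  keep <- vapply(tracks, function(tr) {
    if (!is.finite(tr$body_length) || tr$body_length <= 0)
      stop("track '", tr$track_id, "': body_length must be positive")
    path <- sum(sqrt(rowSums(diff(tr$positions)^2)))
    path >= factor * tr$body_length
  }, logical(1))
  tracks[keep]
}

## ---- canonical tabular track format ---------------------------------------

#' Read tracks from a tabular file
#'
#' The canonical dialect is a delimiter-separated text file with a header and
#' columns `track_id, t, x, y[, z][, theta]` plus optional `species` and
#' `body_length` columns (constant within a track); units are um, s, rad.
#' The `"trackmate"` dialect maps typical tracking-software spot/ellipse
#' table exports (`TRACK_ID`, `POSITION_T`, `POSITION_X`, ...) onto the same
#' fields; column mapping and unit conversion factors are configurable.
#'
#' @param path File path.
#' @param dialect `"canonical"` or `"trackmate"`.
#' @param mapping Named list overriding the dialect's column mapping.
#' @param units Named list of multiplicative conversion factors to um/s/rad,
#'   e.g. `list(xy = 1, t = 1, theta = pi/180)`.
#' @param sep Field separator (default `","`).
#' @return List of [dg_track()] objects, frames sorted by time.
#' @export
load_tracks <- function(path, dialect = c("canonical", "trackmate"),
                        mapping = NULL, units = NULL, sep = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  map <- switch(dialect,
    canonical = list(track_id = "track_id", t = "t", x = "x", y = "y",
                     z = "z", theta = "theta", species = "species",
                     body_length = "body_length"),
    trackmate = list(track_id = "TRACK_ID", t = "POSITION_T",
                     x = "POSITION_X", y = "POSITION_Y", z = "POSITION_Z",
                     theta = "ELLIPSE_THETA", species = "SPECIES",
                     body_length = "ELLIPSE_MAJOR"))
  if (!is.null(mapping)) map[names(mapping)] <- mapping
  un <- list(xy = 1, t = 1, theta = 1)
  if (!is.null(units)) un[names(units)] <- units
  required <- c("track_id", "t", "x", "y")
  missing_cols <- setdiff(unlist(map[required]), names(df))
  if (length(missing_cols) > 0)
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  has <- function(field) map[[field]] %in% names(df)
  ids <- as.character(df[[map$track_id]])
  lapply(split(seq_len(nrow(df)), ids), function(idx) {
    sub <- df[idx, , drop = FALSE]
    o <- order(sub[[map$t]])
    sub <- sub[o, , drop = FALSE]
    tt <- sub[[map$t]] * un$t
    if (anyDuplicated(tt))
      stop("data error: track '", sub[[map$track_id]][1],
           "': duplicated frame time")
    pos <- cbind(sub[[map$x]], sub[[map$y]])
    if (has("z") && !all(is.na(sub[[map$z]]))) pos <- cbind(pos, sub[[map$z]])
    pos <- pos * un$xy
    theta <- if (has("theta") && ncol(pos) == 2) sub[[map$theta]] * un$theta
    dg_track(track_id = sub[[map$track_id]][1],
             times = tt, positions = pos, theta = theta,
             species = if (has("species")) sub[[map$species]][1] else "unknown",
             body_length = if (has("body_length"))
               sub[[map$body_length]][1] * un$xy else NA_real_)
  })
}

#' Write tracks in the canonical tabular format
#'
#' @param tracks List of [dg_track()] objects.
#' @param path Output file path.
#' @param sep Field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, sep = ",") {
  rows <- lapply(tracks, function(tr) {
    d <- data.frame(track_id = tr$track_id, species = tr$species,
                    body_length = tr$body_length,
                    t = tr$times, x = tr$positions[, 1], y = tr$positions[, 2])
    if (ncol(tr$positions) == 3) d$z <- tr$positions[, 3]
    if (!is.null(tr$theta)) d$theta <- tr$theta
    d
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(d) {
    d[setdiff(all_cols, names(d))] <- NA
    d[all_cols]
  })
  df <- do.call(rbind, rows)
  # %.17g round-trips doubles exactly through the text format
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), "NA", sprintf("%.17g", x)))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
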