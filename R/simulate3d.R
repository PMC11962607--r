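#' Construct a 3D body frame
#'
#' The moving orthonormal frame `E = [E_yaw, E_pitch, E_roll]` (columns):
#' `E_roll` is the heading (long body axis, direction of self-propulsion),
#' `E_yaw` the normal axis (top-to-bottom of the cell, about which chiral
#' yaw occurs), `E_pitch` the transverse axis.
#'
#' @param m 3x3 matrix with the three unit axes as columns (default: the
#'   identity, i.e. `E_yaw = x, E_pitch = y, E_roll = z`).
#' @return A validated `dg_body_frame` (3x3 rotation matrix).
#' @export
body_frame <- function(m = diag(3)) {
  m <- unclass(as.matrix(m))
  attributes(m) <- list(dim = dim(m))
  stopifnot(nrow(m) == 3, ncol(m) == 3)
  g <- crossprod(m) - diag(3)
  if (max(abs(g)) > 1e-6)
    stop("data error: frame axes not orthonormal (max deviation ",
         signif(max(abs(g)), 3), ")")
  if (det(m) < 0) stop("data error: frame is left-handed")
  structure(m, class = "dg_body_frame")
}

## Rodrigues rotation matrix about unit axis `a` by angle `phi`.
axis_rotation <- function(a, phi) {
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * cos(phi) + sin(phi) * K + (1 - cos(phi)) * tcrossprod(a)
}

#' Rotate a body frame about its own axes
#'
#' Applies yaw, pitch, and roll rotations (in that order) about the frame's
#' current yaw, pitch, and roll axes, then re-orthonormalizes by polar
#' decomposition to suppress numerical drift.
#'
#' @param frame A [body_frame()] (or plain 3x3 matrix, validated).
#' @param yaw_angle,pitch_angle,roll_angle Rotation angles in radians.
#' @return The rotated `dg_body_frame`.
#' @export
rotate_frame <- function(frame, yaw_angle = 0, pitch_angle = 0,
                         roll_angle = 0) {
  E <- unclass(body_frame(frame))
  if (yaw_angle != 0)   E <- axis_rotation(E[, 1], yaw_angle) %*% E
  if (pitch_angle != 0) E <- axis_rotation(E[, 2], pitch_angle) %*% E
  if (roll_angle != 0)  E <- axis_rotation(E[, 3], roll_angle) %*% E
  structure(polar_orthonormalize(E), class = "dg_body_frame")
}

## Uniformly random rotation (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  d <- sign(diag(qr.R(qr_d)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Simulate one 3D gliding trajectory
#'
#' 3D extension of the state-switching Langevin model using the moving body
#' frame. In Glide, the frame yaws with drift `s omega_mu_G` plus noise and
#' pitches/rolls with noise only (chiral motion occurs only about the
#' normal axis), while the position advances along `E_roll` with drift
#' `s v_par_mu_G` and noise. Pivot rotates yaw (with drift) and pitch (noise
#' only on drift-free axis) about the trailing end at radius `L_bar/2`.
#' Stop and Reverse are noise-only; polarity flips on entry to Reverse. To
#' mimic collisions with obstacles, the Glide dwell can be capped by a
#' truncated-normal bound (`min` of the Markov draw and the bound draw).
#'
#' @inheritParams simulate_track_2d
#' @param bound_params `list(mean, sd)` for the obstacle dwell bound in
#'   seconds (e.g. `list(mean = 37, sd = 7.4)`), or `NULL` to disable.
#' @param frame0 Initial [body_frame()] (default: uniformly random).
#' @param noise_axes Axes receiving rotational noise in Glide (default all
#'   three; restricting to `"yaw"` with a planar initial frame reduces the
#'   dynamics to the 2D model).
#' @return A 3D [dg_track()] (no orientation series) with attribute
#'   `hidden` (per-frame `label`, `polarity`, sojourn log).
#' @export
simulate_track_3d <- function(params, model, T_total, dt = 0.1,
                              delta_out = 1, seed = NULL,
                              bound_params = NULL,
                              reverse_mode = c("instant", "dwell"),
                              frame0 = NULL, state0 = NULL,
                              noise_axes = c("yaw", "pitch", "roll"),
                              track_id = "sim3d",
                              species = params$species) {
  reverse_mode <- match.arg(reverse_mode)
  stopifnot(T_total >= delta_out)
  noise_on <- c(yaw = "yaw" %in% noise_axes,
                pitch = "pitch" %in% noise_axes,
                roll = "roll" %in% noise_axes)
  with_seed(seed, {
    E <- if (is.null(frame0)) random_rotation() else unclass(body_frame(frame0))
    if (is.null(state0)) {
      tf <- stationary_distribution(model)
      inst <- vapply(model$dwell_models, function(d) d$family == "instant",
                     logical(1))
      tf[inst] <- 0
      state0 <- sample(model$states, 1, prob = tf / sum(tf))
    }
    p <- params
    n_out <- floor(round(T_total / delta_out, 9)) + 1L
    out_t <- (seq_len(n_out) - 1) * delta_out
    pos <- matrix(NA_real_, n_out, 3)
    out_lab <- rep(NA_character_, n_out)
    out_pol <- rep(NA_integer_, n_out)
    r <- c(0, 0, 0); s <- 1L; state <- state0; t_now <- 0
    pos[1, ] <- r; out_lab[1] <- state; out_pol[1] <- s
    soj <- list()

    while (t_now < T_total - 1e-9) {
      if (state == "Reverse" && reverse_mode == "instant") {
        s <- -s
        soj[[length(soj) + 1L]] <- data.frame(t = t_now, state = "Reverse",
                                              polarity = s, duration = 0)
        state <- "Glide"
        next
      }
      if (state == "Reverse") s <- -s
      d <- draw_dwell(model, state,
                      glide_bound = if (state == "Glide") bound_params)
      t_end <- min(t_now + d$duration, T_total)
      soj[[length(soj) + 1L]] <- data.frame(t = t_now, state = state,
                                            polarity = s,
                                            duration = t_end - t_now)
      times <- sojourn_steps(t_now, t_end, dt, delta_out)
      for (k in seq_len(max(length(times) - 1L, 0L))) {
        h <- times[k + 1] - times[k]
        sq <- sqrt(h)
        if (state == "Glide") {
          yaw <- s * p$omega_mu_G * h +
            (if (noise_on["yaw"]) p$omega_sigma_G * sq * stats::rnorm(1) else 0)
          pitch <- if (noise_on["pitch"])
            p$omega_sigma_G * sq * stats::rnorm(1) else 0
          roll <- if (noise_on["roll"])
            p$omega_sigma_G * sq * stats::rnorm(1) else 0
          E <- rotate_frame(E, yaw, pitch, roll)
          r <- r + E[, 3] * (s * p$v_par_mu_G * h +
                               p$v_par_sigma_G * sq * stats::rnorm(1))
        } else if (state == "Pivot") {
          yaw <- s * p$omega_mu_P * h + p$omega_sigma_P * sq * stats::rnorm(1)
          pitch <- p$omega_sigma_P * sq * stats::rnorm(1)
          roll_old <- E[, 3]
          E <- rotate_frame(E, yaw, pitch, 0)
          r <- r + s * (p$L_bar / 2) * (E[, 3] - roll_old) +
            roll_old * p$v_par_sigma_S * sq * stats::rnorm(1)
        } else { # Stop / finite-dwell Reverse
          yaw <- p$omega_sigma_S * sq * stats::rnorm(1)
          pitch <- p$omega_sigma_S * sq * stats::rnorm(1)
          E <- rotate_frame(E, yaw, pitch, 0)
          r <- r + E[, 3] * p$v_par_sigma_S * sq * stats::rnorm(1)
        }
        tk <- times[k + 1]
        if (abs(tk / delta_out - round(tk / delta_out)) < 1e-9) {
          idx <- as.integer(round(tk / delta_out)) + 1L
          pos[idx, ] <- r
          out_lab[idx] <- state
          out_pol[idx] <- s
        }
      }
      t_now <- t_end
      if (is.null(d$next_state) || t_now >= T_total - 1e-9) break
      state <- d$next_state
    }
    out_lab[is.na(out_lab)] <- state
    out_pol[is.na(out_pol)] <- s
    if (anyNA(pos)) stop("internal error: unemitted frames")
    tr <- dg_track(track_id = track_id, times = out_t, positions = pos,
                   theta = NULL, species = species,
                   body_length = params$L_bar)
    attr(tr, "hidden") <- list(label = out_lab, polarity = out_pol,
                               sojourns = do.call(rbind, soj))
    tr
  })
}

#' Simulate an ensemble of 3D tracks
#'
#' @inheritParams simulate_track_3d
#' @param n_tracks Number of tracks.
#' @return List of 3D [dg_track()] objects.
#' @export
simulate_tracks_3d <- function(params, model, n_tracks, T_total, dt = 0.1,
                               delta_out = 1, seed = 1L, ...) {
  lapply(seq_len(n_tracks), function(i)
    simulate_track_3d(params, model, T_total, dt = dt,
                      delta_out = delta_out,
                      seed = derive_seed(seed, paste0("track3d", i)),
                      track_id = sprintf("sim3d_%04d", i), ...))
}
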