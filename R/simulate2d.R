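#' Draw a sojourn duration and the next state
#'
#' Duration comes from the current state's dwell model (exponential from the
#' transition rates, lognormal where specified, zero for instantaneous
#' reversals); the next state is drawn from the embedded transition
#' probabilities (Reverse always returns to Glide). An optional upper bound
#' on the Glide dwell (truncated-normal draw, used to mimic obstacle
#' collisions in 3D) is applied as `min(dwell, bound)`.
#'
#' @param model A `dg_transition_model`.
#' @param state Current state name.
#' @param glide_bound Optional `list(mean, sd)` for the truncated-normal
#'   (at 0) upper bound on Glide dwell.
#' @return List with `duration` (s; `Inf` for absorbing states) and
#'   `next_state` (or `NULL` when absorbing).
#' @export
draw_dwell <- function(model, state, glide_bound = NULL) {
  dm <- model$dwell_models[[state]]
  duration <- switch(dm$family,
    exponential = if (dm$rate > 0) stats::rexp(1, dm$rate) else Inf,
    lognormal = stats::rlnorm(1, dm$meanlog, dm$sdlog),
    instant = 0)
  if (state == "Glide" && !is.null(glide_bound)) {
    bound <- rnorm_trunc_pos(1, glide_bound$mean, glide_bound$sd)
    duration <- min(duration, bound)
  }
  p <- model$embedded[state, ]
  next_state <- if (sum(p) == 0) NULL else
    sample(model$states, 1, prob = p)
  list(duration = duration, next_state = next_state)
}

## Normal(mean, sd) truncated at 0 via inverse-CDF sampling (all draws > 0).
rnorm_trunc_pos <- function(n, mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, p0, 1)
  stats::qnorm(u, mean, sd)
}

u_par_of <- function(theta) c(cos(theta), sin(theta))

#' Advance the 2D simulation by one Euler-Maruyama step
#'
#' Reference single-step integrator for the state-switching Langevin model.
#' In Glide the cell translates along its body axis with drift
#' `s v_par_mu_G` and rotates with drift `s omega_mu_G`; in Pivot the
#' centroid follows an exact end-anchored rotation at radius `L_bar/2`
#' about the trailing end; Stop (and finite-dwell Reverse) have zero drift.
#' All states add the corresponding Gaussian fluctuations. Reverse with
#' instantaneous convention does not use this function (polarity flips at
#' the transition itself).
#'
#' @param sim List with `r` (length-2 position), `theta`, `s` (polarity),
#'   `state`, `t`.
#' @param params A `dg_motility_params`.
#' @param dt Step size (s).
#' @param noise Optional list `(xi_tra, xi_rot)` of standard-normal draws;
#'   drawn internally when `NULL`.
#' @return Updated `sim` list.
#' @export
state_step <- function(sim, params, dt, noise = NULL) {
  stopifnot(dt > 0)
  if (is.null(noise)) noise <- list(xi_tra = stats::rnorm(1),
                                    xi_rot = stats::rnorm(1))
  th <- sim$theta; s <- sim$s
  u <- u_par_of(th)
  p <- params
  sq <- sqrt(dt)
  if (sim$state == "Glide") {
    dth <- s * p$omega_mu_G * dt + p$omega_sigma_G * sq * noise$xi_rot
    dr <- u * (s * p$v_par_mu_G * dt + p$v_par_sigma_G * sq * noise$xi_tra)
  } else if (sim$state == "Pivot") {
    dth <- s * p$omega_mu_P * dt + p$omega_sigma_P * sq * noise$xi_rot
    dr <- s * (p$L_bar / 2) * (u_par_of(th + dth) - u) +
      u * p$v_par_sigma_S * sq * noise$xi_tra
  } else if (sim$state %in% c("Stop", "Reverse")) {
    dth <- p$omega_sigma_S * sq * noise$xi_rot
    dr <- u * p$v_par_sigma_S * sq * noise$xi_tra
  } else stop("logic error: unknown state '", sim$state, "'")
  sim$r <- sim$r + dr
  sim$theta <- th + dth
  sim$t <- sim$t + dt
  sim
}

## Integration time points for one sojourn: internal grid of width dt from
## t0, every emission time (multiple of delta_out) inside, and the sojourn
## end. Rounded to ns to dedupe float coincidences.
sojourn_steps <- function(t0, t1, dt, delta_out) {
  grid <- seq(t0, t1, by = dt)
  e0 <- ceiling((t0 + 1e-9) / delta_out) * delta_out
  emis <- if (e0 <= t1 + 1e-9) seq(e0, t1 + 1e-9, by = delta_out) else numeric(0)
  times <- sort(unique(round(c(grid, emis, t1), 9)))
  times[times <= round(t1, 9)]
}

## Vectorized within-sojourn integration. Returns theta and positions at
## `times` (first entry = start, no update).
integrate_sojourn <- function(times, state, r0, theta0, s, params) {
  n <- length(times) - 1L
  if (n < 1) return(list(x = r0[1], y = r0[2], theta = theta0))
  dts <- diff(times)
  sq <- sqrt(dts)
  p <- params
  if (state == "Glide") {
    dth <- s * p$omega_mu_G * dts + p$omega_sigma_G * sq * stats::rnorm(n)
    theta <- theta0 + cumsum(dth)
    th_prev <- c(theta0, theta[-n])
    amp <- s * p$v_par_mu_G * dts + p$v_par_sigma_G * sq * stats::rnorm(n)
    dx <- cos(th_prev) * amp
    dy <- sin(th_prev) * amp
  } else if (state == "Pivot") {
    dth <- s * p$omega_mu_P * dts + p$omega_sigma_P * sq * stats::rnorm(n)
    theta <- theta0 + cumsum(dth)
    th_prev <- c(theta0, theta[-n])
    amp <- p$v_par_sigma_S * sq * stats::rnorm(n)
    dx <- s * (p$L_bar / 2) * (cos(theta) - cos(th_prev)) + cos(th_prev) * amp
    dy <- s * (p$L_bar / 2) * (sin(theta) - sin(th_prev)) + sin(th_prev) * amp
  } else { # Stop / finite-dwell Reverse
    dth <- p$omega_sigma_S * sq * stats::rnorm(n)
    theta <- theta0 + cumsum(dth)
    th_prev <- c(theta0, theta[-n])
    amp <- p$v_par_sigma_S * sq * stats::rnorm(n)
    dx <- cos(th_prev) * amp
    dy <- sin(th_prev) * amp
  }
  list(x = r0[1] + c(0, cumsum(dx)), y = r0[2] + c(0, cumsum(dy)),
       theta = c(theta0, theta))
}

#' Simulate one 2D gliding trajectory
#'
#' Hybrid Gillespie-Langevin simulation: sojourn durations and state
#' switches come from the transition model (dwell boundaries not aligned to
#' the integration grid are handled with partial steps), and within each
#' sojourn the position and orientation evolve by Euler-Maruyama integration
#' of the state's Langevin dynamics. Polarity flips at each transition into
#' Reverse; with the default instantaneous-Reverse convention the cell
#' immediately resumes gliding in the opposite direction. The trajectory is
#' emitted at the recording interval `delta_out` regardless of the internal
#' step `dt`.
#'
#' @param params A [motility_parameters()].
#' @param model A [transition_model()].
#' @param T_total Duration (s).
#' @param dt Internal integration step (s, default 0.1).
#' @param delta_out Recording interval (s, default 1).
#' @param seed RNG seed (fixed seed gives a bit-identical track).
#' @param reverse_mode `"instant"` (default) or `"dwell"` (Reverse consumes
#'   its estimated dwell with noise-only dynamics).
#' @param handedness `"coupled"` (chiral rotation drift carries the sign of
#'   `s(t)`, as in the model equations) or `"fixed"` (one handedness drawn
#'   per cell, independent of polarity).
#' @param theta0,state0 Optional initial orientation / state (defaults:
#'   uniform angle; state from the stationary time fractions).
#' @param glide_bound Optional obstacle bound passed to [draw_dwell()].
#' @param track_id,species Track metadata.
#' @return A [dg_track()] with attribute `hidden`: list with per-frame true
#'   `label` and `polarity`, and the sojourn log (`data.frame` of start
#'   times, states, polarity).
#' @export
simulate_track_2d <- function(params, model, T_total, dt = 0.1,
                              delta_out = 1, seed = NULL,
                              reverse_mode = c("instant", "dwell"),
                              handedness = c("coupled", "fixed"),
                              theta0 = NULL, state0 = NULL,
                              glide_bound = NULL,
                              track_id = "sim", species = params$species) {
  reverse_mode <- match.arg(reverse_mode)
  handedness <- match.arg(handedness)
  stopifnot(T_total >= delta_out)
  with_seed(seed, {
    theta0 <- theta0 %||% stats::runif(1, 0, 2 * pi)
    if (is.null(state0)) {
      tf <- stationary_distribution(model)
      # never start inside an instantaneous state
      inst <- vapply(model$dwell_models, function(d) d$family == "instant",
                     logical(1))
      tf[inst] <- 0
      state0 <- sample(model$states, 1, prob = tf / sum(tf))
    }
    p_sim <- params
    hand <- if (handedness == "fixed") sample(c(-1, 1), 1) else NULL

    n_out <- floor(round(T_total / delta_out, 9)) + 1L
    out_t <- (seq_len(n_out) - 1) * delta_out
    out_x <- out_y <- out_th <- rep(NA_real_, n_out)
    out_lab <- rep(NA_character_, n_out)
    out_pol <- rep(NA_integer_, n_out)

    r <- c(0, 0); theta <- theta0; s <- 1L
    state <- state0; t_now <- 0
    out_x[1] <- 0; out_y[1] <- 0; out_th[1] <- theta0
    out_lab[1] <- state; out_pol[1] <- s
    soj <- list()

    while (t_now < T_total - 1e-9) {
      if (state == "Reverse" && reverse_mode == "instant") {
        s <- -s
        soj[[length(soj) + 1L]] <- data.frame(t = t_now, state = "Reverse",
                                              polarity = s, duration = 0)
        state <- "Glide"  # Reverse exits only to Glide
        next
      }
      if (state == "Reverse") s <- -s
      d <- draw_dwell(model, state, glide_bound = glide_bound)
      t_end <- min(t_now + d$duration, T_total)
      soj[[length(soj) + 1L]] <- data.frame(t = t_now, state = state,
                                            polarity = s,
                                            duration = t_end - t_now)
      times <- sojourn_steps(t_now, t_end, dt, delta_out)
      if (length(times) >= 2) {
        path <- integrate_sojourn_hand(times, state, r, theta, s, p_sim,
                                       hand)
        emit <- which(abs(times / delta_out -
                            round(times / delta_out)) < 1e-9 & times > t_now)
        if (length(emit) > 0) {
          idx <- as.integer(round(times[emit] / delta_out)) + 1L
          out_x[idx] <- path$x[emit]
          out_y[idx] <- path$y[emit]
          out_th[idx] <- path$theta[emit]
          out_lab[idx] <- state
          out_pol[idx] <- s
        }
        m <- length(times)
        r <- c(path$x[m], path$y[m]); theta <- path$theta[m]
      }
      t_now <- t_end
      if (is.null(d$next_state) || t_now >= T_total - 1e-9) break
      state <- d$next_state
    }
    # frames at sojourn boundaries belong to the next sojourn; fill any
    # still-missing frames (can only be the final boundary) with current state
    out_lab[is.na(out_lab)] <- state
    out_pol[is.na(out_pol)] <- s
    if (anyNA(out_x)) stop("internal error: unemitted frames")
    tr <- dg_track(track_id = track_id, times = out_t,
                   positions = cbind(out_x, out_y),
                   theta = out_th %% (2 * pi), species = species,
                   body_length = params$L_bar, unwrap = FALSE)
    attr(tr, "hidden") <- list(
      label = out_lab, polarity = out_pol,
      sojourns = do.call(rbind, soj),
      theta_true = out_th)
    tr
  })
}

## Dispatch wrapper: with fixed handedness the glide rotation drift uses the
## per-cell sign instead of s; translation always uses s.
integrate_sojourn_hand <- function(times, state, r0, theta0, s, params,
                                   hand) {
  if (is.null(hand) || state != "Glide")
    return(integrate_sojourn(times, state, r0, theta0, s, params))
  # fixed handedness: rotation drift sign = hand, translation sign = s
  n <- length(times) - 1L
  dts <- diff(times); sq <- sqrt(dts)
  p <- params
  dth <- hand * abs(p$omega_mu_G) * dts + p$omega_sigma_G * sq * stats::rnorm(n)
  theta <- theta0 + cumsum(dth)
  th_prev <- c(theta0, theta[-n])
  amp <- s * p$v_par_mu_G * dts + p$v_par_sigma_G * sq * stats::rnorm(n)
  list(x = r0[1] + c(0, cumsum(cos(th_prev) * amp)),
       y = r0[2] + c(0, cumsum(sin(th_prev) * amp)),
       theta = c(theta0, theta))
}

#' Simulate an ensemble of 2D tracks
#'
#' @inheritParams simulate_track_2d
#' @param n_tracks Number of tracks.
#' @param seed Base seed; track `i` uses a seed derived from it.
#' @return List of [dg_track()] objects.
#' @export
simulate_tracks_2d <- function(params, model, n_tracks, T_total, dt = 0.1,
                               delta_out = 1, seed = 1L, ...) {
  lapply(seq_len(n_tracks), function(i)
    simulate_track_2d(params, model, T_total, dt = dt,
                      delta_out = delta_out,
                      seed = derive_seed(seed, paste0("track", i)),
                      track_id = sprintf("sim_%04d", i), ...))
}

#' Transition model with Glide as the only accessible state
#'
#' Control model for separating the roles of rotational fluctuation and
#' state switching in the ballistic-to-diffusive transition: the cell never
#' leaves Glide.
#'
#' @return A `dg_transition_model` with an absorbing Glide state.
#' @export
glide_only_model <- function() {
  Q <- matrix(0, 4, 4, dimnames = list(DG_STATES, DG_STATES))
  transition_model(Q = Q)
}
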