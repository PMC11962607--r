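#' Fixture ground-truth species profiles
#'
#' Five synthetic motility profiles loosely mimicking the qualitative
#' regimes observed across gliding diatom species: a fast straight glider,
#' a frequent reverser, a chiral looper (nonzero mean glide rotation,
#' loop period about 41 s), a periodic reverser with lognormal glide dwells
#' (median 11.5 s, so reversals recur about every 23 s), and a slow erratic
#' mover. They are package choices for testing identifiability -- not
#' calibrated to any real species -- and are therefore named
#' `species_like_*`. All profiles keep reversals as exits from Glide only
#' (a reversal is kinematically detectable only between two glides) and
#' treat Reverse as instantaneous.
#'
#' @return Named list; each element has `params`
#'   ([motility_parameters()]) and `model` ([transition_model()]).
#' @export
fixture_profiles <- function() {
  mk_model <- function(gs, gp, gr, sg, sp, pg, ps, glide_dwell = NULL) {
    Q <- matrix(0, 4, 4, dimnames = list(DG_STATES, DG_STATES))
    Q["Glide", c("Stop", "Pivot", "Reverse")] <- c(gs, gp, gr)
    Q["Stop", c("Glide", "Pivot")] <- c(sg, sp)
    Q["Pivot", c("Glide", "Stop")] <- c(pg, ps)
    Q["Reverse", "Glide"] <- 1  # placeholder; dwell overridden to instant
    diag(Q) <- -rowSums(Q)
    dm <- list(Reverse = list(family = "instant"))
    if (!is.null(glide_dwell)) dm$Glide <- glide_dwell
    transition_model(Q = Q, dwell_models = dm)
  }
  list(
    species_like_straight_glider = list(
      params = motility_parameters(
        v_par_mu_G = 5.0, v_par_sigma_G = 1.2, omega_mu_G = 0,
        omega_sigma_G = 0.02, v_par_sigma_S = 0.5, omega_sigma_S = 0.06,
        omega_mu_P = 0.3, omega_sigma_P = 0.08, L_bar = 40,
        species = "species_like_straight_glider"),
      model = mk_model(0.018, 0.006, 0.016, 0.05, 0.01, 0.08, 0.02)),
    species_like_frequent_reverser = list(
      params = motility_parameters(
        v_par_mu_G = 1.5, v_par_sigma_G = 0.5, omega_mu_G = 0,
        omega_sigma_G = 0.025, v_par_sigma_S = 0.4, omega_sigma_S = 0.06,
        omega_mu_P = 0.25, omega_sigma_P = 0.08, L_bar = 30,
        species = "species_like_frequent_reverser"),
      model = mk_model(0.025, 0.005, 0.08, 0.06, 0.01, 0.08, 0.02)),
    species_like_chiral_looper = list(
      params = motility_parameters(
        v_par_mu_G = 1.5, v_par_sigma_G = 0.4, omega_mu_G = 2 * pi / 41,
        omega_sigma_G = 0.02, v_par_sigma_S = 0.25, omega_sigma_S = 0.05,
        omega_mu_P = 0.3, omega_sigma_P = 0.1, L_bar = 10, chiral = TRUE,
        species = "species_like_chiral_looper"),
      model = mk_model(0.015, 0.007, 0.013, 0.05, 0.01, 0.08, 0.02)),
    species_like_periodic_reverser = list(
      params = motility_parameters(
        v_par_mu_G = 3.0, v_par_sigma_G = 0.8, omega_mu_G = 0,
        omega_sigma_G = 0.015, v_par_sigma_S = 0.5, omega_sigma_S = 0.05,
        omega_mu_P = 0.2, omega_sigma_P = 0.06, L_bar = 50,
        species = "species_like_periodic_reverser"),
      model = mk_model(0.0164, 0.0082, 0.0574, 0.05, 0.01, 0.1, 0.02,
                       glide_dwell = list(family = "lognormal",
                                          meanlog = log(11.5),
                                          sdlog = 0.35))),
    species_like_slow_erratic = list(
      params = motility_parameters(
        v_par_mu_G = 1.0, v_par_sigma_G = 0.35, omega_mu_G = 0,
        omega_sigma_G = 0.025, v_par_sigma_S = 0.3, omega_sigma_S = 0.06,
        omega_mu_P = 0.2, omega_sigma_P = 0.08, L_bar = 15,
        species = "species_like_slow_erratic"),
      model = mk_model(0.02, 0.01, 0.01, 0.035, 0.015, 0.05, 0.025)))
}

#' Define a synthetic ground truth
#'
#' Bundles a motility parameter set, a transition model, the measurement
#' model (localization noise, orientation noise, the pi-ambiguity of
#' ellipse orientations), and the experiment dimensions, so a dataset is
#' reproducible from `(ground_truth, seed)` alone.
#'
#' Measurement defaults: `sigma_loc = 0.1` um (sub-pixel centroid
#' precision) and `sigma_or = 0.005` rad, consistent with
#' `sigma_loc / (L_bar / 2)` for a 40 um cell -- ellipse orientation of an
#' elongated cell is constrained far more tightly than a degree.
#'
#' @param params A [motility_parameters()], or a profile name from
#'   [fixture_profiles()].
#' @param model A [transition_model()] (ignored when `params` is a profile
#'   name).
#' @param n_tracks,duration Ensemble size and track duration (s).
#' @param sigma_loc Localization noise SD (um).
#' @param sigma_or Orientation noise SD (rad).
#' @param pi_ambiguity Report orientations modulo pi with a random branch
#'   (as an ellipse fit does)?
#' @param dimension 2 or 3.
#' @param dt_sim,delta_out Integrator step and recording interval (s).
#' @param seed Base RNG seed.
#' @return A `dg_ground_truth`.
#' @export
ground_truth <- function(params, model = NULL, n_tracks = 50,
                         duration = 600, sigma_loc = 0.1,
                         sigma_or = 0.005, pi_ambiguity = TRUE,
                         dimension = 2, dt_sim = 0.1, delta_out = 1,
                         seed = 1L) {
  if (is.character(params)) {
    prof <- fixture_profiles()[[params]]
    if (is.null(prof)) stop("unknown fixture profile: ", params)
    model <- prof$model
    params <- prof$params
  }
  stopifnot(inherits(params, "dg_motility_params"),
            inherits(model, "dg_transition_model"),
            sigma_loc >= 0, sigma_or >= 0, dimension %in% c(2, 3))
  structure(list(params = params, model = model, n_tracks = n_tracks,
                 duration = duration, sigma_loc = sigma_loc,
                 sigma_or = sigma_or, pi_ambiguity = pi_ambiguity,
                 dimension = dimension, dt_sim = dt_sim,
                 delta_out = delta_out, seed = as.integer(seed)),
            class = "dg_ground_truth")
}

#' Generate an observed dataset from a ground truth
#'
#' Simulates the ensemble with the state-switching Langevin model, then
#' applies the measurement model: additive Gaussian localization noise on
#' positions, Gaussian orientation noise, and (optionally) reporting the
#' orientation modulo pi with an independent random branch per frame, as
#' ellipse fitting does. The true (noise-free) states, polarity, and
#' orientation remain available in each track's `hidden` attribute for
#' scoring.
#'
#' @param gt A [ground_truth()].
#' @return List of observed [dg_track()] objects (orientation left
#'   uncorrected; apply [unwrap_orientation()] downstream).
#' @export
generate_tracks <- function(gt) {
  stopifnot(inherits(gt, "dg_ground_truth"))
  sim <- if (gt$dimension == 2)
    simulate_tracks_2d(gt$params, gt$model, gt$n_tracks, gt$duration,
                       dt = gt$dt_sim, delta_out = gt$delta_out,
                       seed = gt$seed)
  else
    simulate_tracks_3d(gt$params, gt$model, gt$n_tracks, gt$duration,
                       dt = gt$dt_sim, delta_out = gt$delta_out,
                       seed = gt$seed)
  lapply(seq_along(sim), function(i) {
    tr <- sim[[i]]
    hidden <- attr(tr, "hidden")
    with_seed(derive_seed(gt$seed, paste0("measure", i)), {
      n <- n_frames(tr)
      pos <- tr$positions +
        matrix(stats::rnorm(n * ncol(tr$positions), 0, gt$sigma_loc),
               n, ncol(tr$positions))
      theta <- tr$theta
      if (!is.null(theta)) {
        theta <- theta + stats::rnorm(n, 0, gt$sigma_or)
        if (gt$pi_ambiguity)
          theta <- (theta %% pi) + pi * stats::rbinom(n, 1, 0.5)
      }
      obs <- dg_track(track_id = tr$track_id, times = tr$times,
                      positions = pos, theta = theta,
                      species = tr$species, body_length = tr$body_length,
                      unwrap = FALSE)
      attr(obs, "hidden") <- hidden
      obs
    })
  })
}

#' Generate a synthetic raphe trace with known curvature
#'
#' Analytic point lists emulating traced raphe morphologies: a straight
#' raphe (`line`), a constant-curvature `arc`, a `sigmoid` (S-shaped valve
#' outline, curvature changing sign at the inflection), and a
#' `helix_projection` (sinusoidal 2D projection of a helical raphe). The
#' true pointwise curvature magnitude is attached as attribute
#' `kappa_true`.
#'
#' @param shape One of `"line"`, `"arc"`, `"sigmoid"`,
#'   `"helix_projection"`.
#' @param length Extent along the main axis (um).
#' @param n_points Number of points.
#' @param radius Arc radius (um; `arc` only).
#' @param amplitude,wavelength Shape parameters for `sigmoid` (tanh
#'   amplitude/width) and `helix_projection` (sine amplitude/period).
#' @return A `dg_polyline` of kind `"raphe"` with attribute `kappa_true`.
#' @export
generate_raphe <- function(shape = c("line", "arc", "sigmoid",
                                     "helix_projection"),
                           length = 50, n_points = 100, radius = 20,
                           amplitude = 5, wavelength = 25) {
  shape <- match.arg(shape)
  if (shape == "line") {
    x <- seq(0, length, length.out = n_points)
    pts <- cbind(x, 0 * x)
    kappa <- rep(0, n_points)
  } else if (shape == "arc") {
    phi <- seq(0, length / radius, length.out = n_points)
    pts <- cbind(radius * sin(phi), radius * (1 - cos(phi)))
    kappa <- rep(1 / radius, n_points)
  } else if (shape == "sigmoid") {
    x <- seq(-length / 2, length / 2, length.out = n_points)
    b <- wavelength
    y <- amplitude * tanh(x / b)
    d1 <- amplitude / b * (1 - tanh(x / b)^2)
    d2 <- -2 * amplitude / b^2 * tanh(x / b) * (1 - tanh(x / b)^2)
    pts <- cbind(x, y)
    kappa <- abs(d2) / (1 + d1^2)^1.5
  } else {
    x <- seq(0, length, length.out = n_points)
    y <- amplitude * sin(2 * pi * x / wavelength)
    d1 <- amplitude * 2 * pi / wavelength * cos(2 * pi * x / wavelength)
    d2 <- -amplitude * (2 * pi / wavelength)^2 * sin(2 * pi * x / wavelength)
    pts <- cbind(x, y)
    kappa <- abs(d2) / (1 + d1^2)^1.5
  }
  out <- dg_polyline(pts, kind = "raphe")
  attr(out, "kappa_true") <- kappa
  out
}

#' End-to-end parameter recovery experiment
#'
#' Runs the full analysis pipeline (orientation correction, kinematics,
#' state classification with data-derived thresholds, transition-model
#' estimation, distribution calibration) on a dataset generated from a
#' known ground truth, and scores every recovered quantity against the
#' truth. The transition rates are compared in the instantaneous-Reverse
#' convention of the simulator.
#'
#' @param gt A [ground_truth()].
#' @param tol_params Relative tolerance for the 8 Langevin parameters
#'   (default 0.15).
#' @param tol_rates Relative tolerance for free transition rates
#'   (default 0.10).
#' @param tracks Optional pre-generated observed tracks (from
#'   [generate_tracks()]); generated fresh when `NULL`.
#' @return A `dg_recovery` list: `params` and `rates` comparison tables,
#'   `calibration`, `identifiable` flag, `pass`.
#' @export
recovery_experiment <- function(gt, tol_params = 0.15, tol_rates = 0.10,
                                tracks = NULL) {
  if (is.null(tracks)) tracks <- generate_tracks(gt)
  tracks <- lapply(tracks, function(tr) {
    if (!is.null(tr$theta)) tr$theta <- unwrap_orientation(tr$theta)
    tr
  })
  ks_list <- lapply(tracks, compute_kinematics)
  cls <- classify_dataset(ks_list)
  calib <- tryCatch(
    calibrate_species(ks_list, cls$states, tracks = tracks,
                      species = gt$params$species,
                      seed = derive_seed(gt$seed, "calib")),
    error = function(e) e)
  if (inherits(calib, "error")) {
    # calibration impossible (e.g. glide speed below the noise floor):
    # report non-identifiability instead of silently wrong estimates
    empty <- data.frame(param = MOTILITY_PARAM_NAMES, truth = NA_real_,
                        estimate = NA_real_, rel_error = NA_real_,
                        pass = FALSE)
    return(structure(list(params = empty,
                          rates = data.frame(), calibration = NULL,
                          est_model = NULL, identifiable = FALSE,
                          pass = FALSE,
                          error = conditionMessage(calib)),
                     class = "dg_recovery"))
  }
  est_model <- estimate_transition_model(cls$states, dt = gt$delta_out,
                                         reverse_convention = "instant")

  truth <- gt$params
  est <- calib$params
  # identifiability guard: the glide mode must sit above the apparent noise
  noise_floor <- sqrt(2) * gt$sigma_loc / gt$delta_out
  identifiable <- est$v_par_mu_G > 3 * noise_floor &&
    cls$thresholds$v_stop < est$v_par_mu_G
  rows <- lapply(MOTILITY_PARAM_NAMES, function(p) {
    tv <- truth[[p]]; ev <- est[[p]]
    if (!is.finite(tv) || !is.finite(ev))
      return(data.frame(param = p, truth = tv, estimate = ev,
                        rel_error = NA_real_, pass = FALSE))
    if (tv == 0) {
      # zero-mean channel: pass when the fit selected the non-chiral model
      pass <- ev == 0
      return(data.frame(param = p, truth = 0, estimate = ev,
                        rel_error = NA_real_, pass = pass))
    }
    re <- abs(ev - tv) / abs(tv)
    data.frame(param = p, truth = tv, estimate = ev, rel_error = re,
               pass = re <= tol_params)
  })
  params_tab <- do.call(rbind, rows)

  # ground-truth rates in the instantaneous-Reverse convention
  gt_rates <- effective_rates(gt$model)
  est_rates <- effective_rates(est_model)
  ridx <- which(gt_rates > 0, arr.ind = TRUE)
  rates_tab <- data.frame(
    from = rownames(gt_rates)[ridx[, 1]],
    to = colnames(gt_rates)[ridx[, 2]],
    truth = gt_rates[ridx], estimate = est_rates[ridx])
  rates_tab$rel_error <- abs(rates_tab$estimate - rates_tab$truth) /
    rates_tab$truth
  rates_tab$pass <- rates_tab$rel_error <= tol_rates
  # Reverse -> Glide is structural (probability 1), not a free rate
  rates_tab <- rates_tab[rates_tab$from != "Reverse", , drop = FALSE]

  structure(list(params = params_tab, rates = rates_tab,
                 calibration = calib, est_model = est_model,
                 identifiable = identifiable,
                 pass = identifiable && all(params_tab$pass) &&
                   all(rates_tab$pass)),
            class = "dg_recovery")
}

## Exit rates i -> j as embedded probability / mean dwell, the natural
## comparison scale across exponential and lognormal dwell models.
effective_rates <- function(model) {
  md <- model$mean_dwell
  R <- model$embedded * ifelse(is.finite(md) & md > 0, 1 / md, 0)
  dimnames(R) <- dimnames(model$embedded)
  R
}

#' @export
print.dg_recovery <- function(x, ...) {
  cat("<dg_recovery> overall:", if (x$pass) "PASS" else "FAIL",
      if (!x$identifiable) "(non-identifiable: glide speed at noise floor)",
      "\n")
  print(transform(x$params, truth = signif(truth, 3),
                  estimate = signif(estimate, 3),
                  rel_error = round(rel_error, 3)))
  print(transform(x$rates, truth = signif(truth, 3),
                  estimate = signif(estimate, 3),
                  rel_error = round(rel_error, 3)))
  invisible(x)
}
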