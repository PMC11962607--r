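#' Construct the calibrated motility parameter set
#'
#' The eight free parameters of the state-switching Langevin model for one
#' species, plus the mean body length and a chirality flag. Glide has mean
#' tangential speed `v_par_mu_G` (um/s) and rotation drift `omega_mu_G`
#' (rad/s, nonzero only for chiral species), with fluctuation magnitudes
#' `v_par_sigma_G` (um s^-1/2) and `omega_sigma_G` (rad s^-1/2). Stop,
#' Pivot, and Reverse share the translational fluctuation `v_par_sigma_S`;
#' Stop and Reverse share the rotational fluctuation `omega_sigma_S`; Pivot
#' has rotation drift `omega_mu_P` and fluctuation `omega_sigma_P`. The
#' derived diffusivities are `D_tra = v_par_sigma_G^2 / 2` and
#' `D_rot = omega_sigma_G^2 / 2`.
#'
#' @param v_par_mu_G,v_par_sigma_G,omega_mu_G,omega_sigma_G Glide parameters.
#' @param v_par_sigma_S,omega_sigma_S Shared non-glide fluctuation magnitudes.
#' @param omega_mu_P,omega_sigma_P Pivot rotation parameters.
#' @param L_bar Mean body length (um).
#' @param chiral Logical; nonzero mean glide rotation (looping species).
#' @param species Species label.
#' @return A `dg_motility_params`.
#' @export
motility_parameters <- function(v_par_mu_G, v_par_sigma_G,
                                omega_mu_G = 0, omega_sigma_G,
                                v_par_sigma_S, omega_sigma_S,
                                omega_mu_P = NA_real_,
                                omega_sigma_P = NA_real_,
                                L_bar, chiral = omega_mu_G != 0,
                                species = "unknown") {
  sig <- c(v_par_sigma_G, omega_sigma_G, v_par_sigma_S, omega_sigma_S)
  if (any(is.finite(sig) & sig < 0)) stop("sigma parameters must be >= 0")
  if (!is.na(v_par_mu_G) && v_par_mu_G <= 0)
    stop("v_par_mu_G must be positive")
  structure(list(
    v_par_mu_G = v_par_mu_G, v_par_sigma_G = v_par_sigma_G,
    omega_mu_G = omega_mu_G, omega_sigma_G = omega_sigma_G,
    v_par_sigma_S = v_par_sigma_S, omega_sigma_S = omega_sigma_S,
    omega_mu_P = omega_mu_P, omega_sigma_P = omega_sigma_P,
    L_bar = L_bar, chiral = isTRUE(chiral), species = species,
    D_tra = v_par_sigma_G^2 / 2, D_rot = omega_sigma_G^2 / 2),
    class = "dg_motility_params")
}

#' @export
print.dg_motility_params <- function(x, ...) {
  cat(sprintf("<dg_motility_params> %s%s, L = %g um\n",
              x$species, if (x$chiral) " (chiral)" else "", x$L_bar))
  p <- unlist(x[c("v_par_mu_G", "v_par_sigma_G", "omega_mu_G",
                  "omega_sigma_G", "v_par_sigma_S", "omega_sigma_S",
                  "omega_mu_P", "omega_sigma_P")])
  print(signif(p, 4))
  invisible(x)
}

## The eight calibrated parameter names, in canonical order.
MOTILITY_PARAM_NAMES <- c("v_par_mu_G", "v_par_sigma_G", "omega_mu_G",
                          "omega_sigma_G", "v_par_sigma_S", "omega_sigma_S",
                          "omega_mu_P", "omega_sigma_P")

#' Rescale glide velocity segments to a common mean speed
#'
#' Each glide's velocities are multiplied by the global mean glide speed
#' divided by that glide's own (signed) mean speed, so all glides acquire
#' the same mean speed -- oriented to the positive branch -- while each
#' glide's mean-to-SD ratio is preserved in magnitude. This removes
#' glide-to-glide speed variability and aligns the polarity of all glides,
#' so their fluctuations can be pooled before coarse-graining.
#'
#' @param segments List of numeric `v_par` series, one per glide.
#' @param global_mean Optional global mean glide speed (um/s); by default
#'   the mean of `|v_par|` pooled over all segments.
#' @param min_mean Segments with `|mean|` below this are skipped with a
#'   warning (scale factor undefined).
#' @return List with `segments` (rescaled, all with mean `+global_mean`),
#'   `factors` (signed), `global_mean`, `skipped`, `kept` (indices).
#' @export
rescale_glides <- function(segments, global_mean = NULL, min_mean = 1e-9) {
  stopifnot(length(segments) > 0)
  g <- global_mean %||% mean(abs(unlist(segments, use.names = FALSE)))
  means <- vapply(segments, mean, numeric(1))
  skipped <- which(abs(means) < min_mean)
  if (length(skipped) > 0)
    warning(length(skipped), " glide(s) with near-zero mean speed skipped")
  keep <- setdiff(seq_along(segments), skipped)
  factors <- g / means[keep]
  out <- Map(function(s, f) s * f, segments[keep], factors)
  list(segments = out, factors = factors, global_mean = g, skipped = skipped,
       kept = keep)
}

#' Decorrelate and coarse-grain a velocity series
#'
#' Randomly permutes the series (removing temporal correlations) and then
#' applies a moving average of `window` frames. The marginal spread of the
#' output is the per-frame spread divided by `sqrt(window)`; the
#' distribution fits de-scale accordingly (see `cg_factor`).
#'
#' @param series Numeric series (length >= window).
#' @param window Moving-average width in frames (default 5).
#' @param seed Optional RNG seed for the permutation.
#' @return Coarse-grained series of length `length(series) - window + 1`.
#' @export
coarse_grain <- function(series, window = 5, seed = NULL) {
  n <- length(series)
  if (n < window) stop("series shorter than the coarse-graining window")
  with_seed(seed, {
    perm <- series[sample.int(n)]
    as.numeric(stats::filter(perm, rep(1 / window, window),
                             sides = 2))[!is.na(
      stats::filter(seq_len(n), rep(1 / window, window), sides = 2))]
  })
}

## Negative log-likelihood of the symmetric equal-variance two-normal
## mixture 0.5 N(mu, sigma) + 0.5 N(-mu, sigma).
symm_mixture_nll <- function(par, x) {
  mu <- par[1]; sigma <- exp(par[2])
  a <- stats::dnorm(x, mu, sigma, log = TRUE)
  b <- stats::dnorm(x, -mu, sigma, log = TRUE)
  m <- pmax(a, b)
  -sum(m + log(exp(a - m) + exp(b - m)) - log(2))
}

#' Fit a symmetric two-component normal mixture
#'
#' Maximum likelihood for `0.5 N(mu, sigma) + 0.5 N(-mu, sigma)` with the
#' equal-variance constraint hard-coded, via `optim` with three restarts
#' (`mu` initialized at 0, `mean(|x|)`, and twice that). The reported `mu`
#' is nonnegative.
#'
#' @param x Samples (already symmetrized by construction or by pooling
#'   `c(x, -x)`).
#' @return List with `mu`, `sigma`, `loglik`, `convergence`.
#' @export
fit_symmetric_mixture <- function(x) {
  stopifnot(length(x) >= 10)
  s0 <- stats::sd(x)
  if (!is.finite(s0) || s0 < 1e-12)  # degenerate: noise-free data
    return(list(mu = mean(abs(x)), sigma = 0, loglik = Inf,
                convergence = 0L))
  inits <- list(c(0, log(s0)),
                c(mean(abs(x)), log(max(s0 / 2, 1e-6))),
                c(2 * mean(abs(x)), log(max(s0 / 2, 1e-6))))
  best <- NULL
  for (p0 in inits) {
    fit <- tryCatch(
      stats::optim(p0, symm_mixture_nll, x = x, method = "BFGS",
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("mixture fit failed to converge")
  list(mu = abs(best$par[1]), sigma = exp(best$par[2]),
       loglik = -best$value, convergence = best$convergence)
}

## Drop samples more than k robust SDs from the median: state-boundary
## frames misassigned by the classifier leave a thin contamination of
## far-off values that would otherwise leak through the coarse-graining
## into every overlapping window.
trim_outliers <- function(x, k = 6) {
  if (length(x) < 20) return(x)
  m <- stats::median(x)
  s <- stats::mad(x)
  if (!is.finite(s) || s <= 0) return(x)
  x[abs(x - m) <= k * s]
}

## Chirality test on the raw per-frame glide rotation pool: a symmetric
## two-normal mixture must beat the zero-mean normal by AIC AND be well
## separated (mu > 2 sigma). Run before any sign orientation, where a
## genuinely zero-mean channel cannot fake a displaced mode.
detect_chirality <- function(omega_raw) {
  if (length(omega_raw) < 100) return(FALSE)
  xo <- c(omega_raw, -omega_raw)
  fit <- tryCatch(fit_symmetric_mixture(xo), error = function(e) NULL)
  if (is.null(fit)) return(FALSE)
  s0 <- max(stats::mad(xo, center = 0), 1e-12)
  ll0 <- sum(stats::dnorm(xo, 0, s0, log = TRUE))
  aic_mix <- 2 * 2 - 2 * fit$loglik
  aic_norm <- 2 * 1 - 2 * ll0
  aic_mix < aic_norm && fit$mu > 2 * fit$sigma
}

cg_descale <- function(cg_factor = c("sqrt5", "5"), window = 5) {
  cg_factor <- match.arg(cg_factor)
  if (cg_factor == "sqrt5") sqrt(window) else window
}

#' Fit the Glide velocity and rotation distributions
#'
#' The symmetrized (`c(x, -x)`) coarse-grained tangential velocities are fit
#' by the symmetric two-normal mixture, giving the mean glide speed and,
#' after de-scaling by the coarse-graining factor, the glide fluctuation
#' magnitude. The rotation channel is fit the same way for chiral species
#' and as a zero-mean normal otherwise.
#'
#' @param v_coarse,omega_coarse Coarse-grained glide samples (pooled over
#'   glides; not yet symmetrized).
#' @param chiral Fit the rotation channel as a mixture (`TRUE`) or zero-mean
#'   normal (`FALSE`); `"auto"` selects by AIC.
#' @param cg_factor De-scaling convention for the coarse-grained sigma:
#'   `"sqrt5"` (divide-by-sqrt(window), self-consistent for averaging
#'   decorrelated samples; default) or `"5"` (divide-by-window).
#' @param window Coarse-graining window used upstream (default 5).
#' @return List with `v_par_mu_G`, `v_par_sigma_G`, `omega_mu_G`,
#'   `omega_sigma_G`, `chiral`, and the raw fits.
#' @export
fit_glide_distribution <- function(v_coarse, omega_coarse, chiral = "auto",
                                   cg_factor = c("sqrt5", "5"), window = 5,
                                   robust = TRUE) {
  f <- cg_descale(match.arg(cg_factor), window)
  xv <- c(v_coarse, -v_coarse)
  fit_v <- robust_refine(fit_symmetric_mixture(xv), xv, robust)
  xo <- c(omega_coarse, -omega_coarse)
  fit_o_mix <- robust_refine(fit_symmetric_mixture(xo), xo, robust)
  sigma0 <- if (robust) stats::mad(xo, center = 0) else sqrt(mean(xo^2))
  ll0 <- sum(stats::dnorm(xo, 0, max(sigma0, 1e-12), log = TRUE))
  if (identical(chiral, "auto")) {
    # mixture has one extra parameter; require AIC improvement
    chiral <- (2 * 2 - 2 * fit_o_mix$loglik) < (2 * 1 - 2 * ll0)
  }
  if (chiral) {
    omega_mu <- fit_o_mix$mu
    omega_sigma <- fit_o_mix$sigma * f
  } else {
    omega_mu <- 0
    omega_sigma <- sigma0 * f
  }
  list(v_par_mu_G = fit_v$mu, v_par_sigma_G = fit_v$sigma * f,
       omega_mu_G = omega_mu, omega_sigma_G = omega_sigma,
       chiral = chiral, fit_v = fit_v, fit_omega = fit_o_mix)
}

## Median/MAD refinement of a well-separated symmetric mixture fit: boundary
## frames misassigned by the classifier leave a small fraction of far
## outliers that inflate the Gaussian MLE sigma; the median of |x| and the
## MAD are immune to them. Applied only when the fitted components are well
## separated (mu > 2 sigma), where |x| cleanly isolates one component.
robust_refine <- function(fit, x, robust = TRUE) {
  if (!robust || !is.finite(fit$mu) || fit$mu <= 2 * fit$sigma) return(fit)
  ax <- abs(x)
  fit$mu <- stats::median(ax)
  fit$sigma <- stats::mad(ax)
  fit
}

#' Fit the Stop fluctuation magnitudes
#'
#' Zero-mean normal MLE on the symmetrized coarse-grained Stop samples for
#' both channels (there is no mean displacement or rotation in a stop); any
#' residual sample mean is reported as a diagnostic, not corrected.
#'
#' @param v_coarse,omega_coarse Coarse-grained Stop samples.
#' @inheritParams fit_glide_distribution
#' @return List with `v_par_sigma_S`, `omega_sigma_S`, `bias_v`,
#'   `bias_omega`.
#' @export
fit_stop_distribution <- function(v_coarse, omega_coarse,
                                  cg_factor = c("sqrt5", "5"), window = 5,
                                  robust = TRUE) {
  if (length(v_coarse) < 20 || length(omega_coarse) < 20)
    stop("data error: fewer than 20 Stop samples")
  f <- cg_descale(match.arg(cg_factor), window)
  sig <- function(x) if (robust) stats::mad(c(x, -x), center = 0)
                     else sqrt(mean(c(x, -x)^2))
  list(v_par_sigma_S = sig(v_coarse) * f,
       omega_sigma_S = sig(omega_coarse) * f,
       bias_v = mean(v_coarse), bias_omega = mean(omega_coarse))
}

#' Fit the Pivot rotation distribution
#'
#' Symmetric two-normal mixture on the symmetrized coarse-grained Pivot
#' rotation rates: clockwise and counterclockwise pivots occur with means of
#' equal magnitude and opposite sign.
#'
#' @param omega_coarse Coarse-grained Pivot rotation samples.
#' @inheritParams fit_glide_distribution
#' @return List with `omega_mu_P`, `omega_sigma_P`, and the raw fit.
#' @export
fit_pivot_distribution <- function(omega_coarse,
                                   cg_factor = c("sqrt5", "5"), window = 5,
                                   robust = TRUE) {
  if (length(omega_coarse) < 20)
    stop("data error: fewer than 20 Pivot samples")
  f <- cg_descale(match.arg(cg_factor), window)
  x <- c(omega_coarse, -omega_coarse)
  fit <- robust_refine(fit_symmetric_mixture(x), x, robust)
  list(omega_mu_P = fit$mu, omega_sigma_P = fit$sigma * f, fit = fit)
}

## Per-state runs of at least `min_len` frames, trimmed by `trim` frames at
## both ends (guards against state-boundary smearing from the velocity
## filter). Returns list of index vectors.
state_runs <- function(labels, state, trim = 0, min_len = 2 * trim + 2) {
  runs <- true_runs(as.character(labels) == state)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    a <- runs$start[i] + trim
    b <- runs$end[i] - trim
    if (b - a + 1L >= min_len - 2 * trim && b >= a)
      out[[length(out) + 1L]] <- a:b
  }
  out
}

#' Calibrate the motility model for one species
#'
#' Orchestrates the full calibration: extracts per-state frame runs from the
#' classified tracks, rescales glide velocities to a common mean speed
#' (applying the same per-glide factors to the rotation rates),
#' decorrelates and coarse-grains each run, fits the Glide / Stop / Pivot
#' distributions, and estimates the four-state transition model.
#'
#' @param ks_list List of `dg_kinematics`, one per track.
#' @param states_list Matching list of `dg_states`.
#' @param tracks Optional list of `dg_track` (supplies body lengths).
#' @param species Species label.
#' @param cg_factor,window Coarse-graining convention (see
#'   [fit_glide_distribution()]).
#' @param trim Frames trimmed from each end of every state run before
#'   pooling (default 3).
#' @param chiral `"auto"`, `TRUE`, or `FALSE`.
#' @param dt Frame interval (s).
#' @param seed Seed for the coarse-graining permutations.
#' @param L_bar Mean body length override (um).
#' @param noise_correction Estimate the localization and orientation
#'   measurement noise from the Stop-state MSD/variance intercepts and
#'   subtract it in quadrature from the fitted fluctuation magnitudes
#'   (default TRUE; needs `tracks`).
#' @return A `dg_calibration`: list with `params`
#'   ([motility_parameters()]), `model` ([estimate_transition_model()]
#'   result), and `diagnostics` (sample sizes, fits, flags).
#' @export
calibrate_species <- function(ks_list, states_list, tracks = NULL,
                              species = "unknown",
                              cg_factor = c("sqrt5", "5"), window = 5,
                              trim = 3, chiral = "auto", dt = 1,
                              seed = 1L, L_bar = NA_real_,
                              noise_correction = TRUE) {
  cg_factor <- match.arg(cg_factor)
  stopifnot(length(ks_list) == length(states_list))
  flags <- character(0)

  pull_runs <- function(state, channel, min_len) {
    segs <- list()
    for (i in seq_along(ks_list)) {
      runs <- state_runs(states_list[[i]]$label, state, trim = trim,
                         min_len = min_len)
      for (r in runs)
        segs[[length(segs) + 1L]] <- ks_list[[i]][[channel]][r]
    }
    segs
  }
  min_len <- 2 * trim + window

  # Glide: rescale v to the common mean (signed factors orient every glide
  # to the positive branch); omega is scaled by the same magnitudes.
  v_glides <- pull_runs("Glide", "v_par", min_len)
  o_glides <- pull_runs("Glide", "omega", min_len)
  if (length(v_glides) == 0) stop("calibration stage glide: no glide runs")
  rs <- rescale_glides(v_glides)
  o_glides <- Map(function(s, f) s * abs(f), o_glides[rs$kept], rs$factors)
  # gate the rotation pool on high instantaneous speed: sojourns too short
  # for the classifier to see hide inside long glide runs and carry
  # stop/pivot-level rotation; their raw speed is low, and conditioning on
  # |v_par| does not bias omega (independent fluctuations in the model)
  o_glides <- Map(function(o, v) o[abs(v) >= 0.5 * rs$global_mean],
                  o_glides, v_glides[rs$kept])
  # rescaling aligns all glides to the same (positive) mean, so segments can
  # be pooled before the decorrelating permutation: the moving windows then
  # draw from the full pool and per-segment length does not bias the spread
  cg <- function(segs, tag, orient = FALSE) {
    if (length(segs) == 0) return(numeric(0))
    if (orient) segs <- lapply(segs, function(s) s * sign(mean(s) + 1e-300))
    pooled <- trim_outliers(unlist(segs, use.names = FALSE))
    if (length(pooled) < window) return(numeric(0))
    coarse_grain(pooled, window, seed = derive_seed(seed, tag))
  }
  # chirality is decided on the raw (per-frame) glide rotation pool: the
  # ellipse pi-ambiguity makes the sign coupling between v and omega
  # unobservable, so the rotation channel is assessed on its own
  if (identical(chiral, "auto"))
    chiral <- detect_chirality(trim_outliers(
      unlist(o_glides, use.names = FALSE)))
  v_g <- cg(rs$segments, "vG")
  o_g <- cg(o_glides, "oG", orient = chiral)
  glide_fit <- fit_glide_distribution(v_g, o_g, chiral = chiral,
                                      cg_factor = cg_factor, window = window)

  # Stop
  v_stops <- pull_runs("Stop", "v_par", min_len)
  o_stops <- pull_runs("Stop", "omega", min_len)
  stop_fit <- NULL
  if (length(v_stops) > 0) {
    v_s <- cg(v_stops, "vS"); o_s <- cg(o_stops, "oS")
    stop_fit <- tryCatch(
      fit_stop_distribution(v_s, o_s, cg_factor, window),
      error = function(e) { flags <<- c(flags, conditionMessage(e)); NULL })
  } else flags <- c(flags, "no Stop runs; Stop parameters absent")

  # Pivot
  o_pivots <- pull_runs("Pivot", "omega", min_len)
  pivot_fit <- NULL
  if (length(o_pivots) > 0) {
    # orient each pivot by its own rotation direction before pooling
    o_p <- cg(o_pivots, "oP", orient = TRUE)
    pivot_fit <- tryCatch(
      fit_pivot_distribution(o_p, cg_factor, window),
      error = function(e) { flags <<- c(flags, conditionMessage(e)); NULL })
  } else flags <- c(flags, "no Pivot runs; Pivot parameters absent")

  model <- estimate_transition_model(states_list, dt = dt)

  # Static (measurement) error correction, the standard intercept method of
  # single-particle tracking: during stops the true MSD grows linearly while
  # iid localization noise adds a constant 4 sigma_loc^2, and the variance
  # of orientation increments adds 2 sigma_or^2. Both intercepts are
  # estimable from the data alone, and the fitted fluctuation magnitudes
  # are then corrected in quadrature (per-frame velocity noise is
  # 2 sigma_loc^2 / dt^2, rotation noise 2 sigma_or^2 / dt^2).
  noise_est <- if (!is.null(tracks) && noise_correction)
    estimate_measurement_noise(tracks, states_list, dt = dt, trim = trim)
  else list(sigma_loc = 0, sigma_or = 0)
  desub <- function(sig, floor_var) {
    if (!is.finite(sig)) return(sig)
    sqrt(max(sig^2 - floor_var, (0.1 * sig)^2))
  }
  v_floor <- 2 * noise_est$sigma_loc^2 / dt^2
  o_floor <- 2 * noise_est$sigma_or^2 / dt^2
  glide_fit$v_par_sigma_G <- desub(glide_fit$v_par_sigma_G, v_floor)
  glide_fit$omega_sigma_G <- desub(glide_fit$omega_sigma_G, o_floor)
  if (!is.null(stop_fit)) {
    stop_fit$v_par_sigma_S <- desub(stop_fit$v_par_sigma_S, v_floor)
    stop_fit$omega_sigma_S <- desub(stop_fit$omega_sigma_S, o_floor)
  }
  if (!is.null(pivot_fit))
    pivot_fit$omega_sigma_P <- desub(pivot_fit$omega_sigma_P, o_floor)

  if (is.na(L_bar) && !is.null(tracks))
    L_bar <- mean(vapply(tracks, function(t) t$body_length, numeric(1)),
                  na.rm = TRUE)
  params <- motility_parameters(
    v_par_mu_G = glide_fit$v_par_mu_G,
    v_par_sigma_G = glide_fit$v_par_sigma_G,
    omega_mu_G = glide_fit$omega_mu_G,
    omega_sigma_G = glide_fit$omega_sigma_G,
    v_par_sigma_S = stop_fit$v_par_sigma_S %||% NA_real_,
    omega_sigma_S = stop_fit$omega_sigma_S %||% NA_real_,
    omega_mu_P = pivot_fit$omega_mu_P %||% NA_real_,
    omega_sigma_P = pivot_fit$omega_sigma_P %||% NA_real_,
    L_bar = L_bar, chiral = glide_fit$chiral, species = species)

  structure(list(
    params = params, model = model,
    diagnostics = list(
      n_glide_runs = length(rs$segments), n_glide_samples = length(v_g),
      n_stop_runs = length(v_stops), n_pivot_runs = length(o_pivots),
      global_mean_glide_speed = rs$global_mean,
      glide_fit = glide_fit, stop_fit = stop_fit, pivot_fit = pivot_fit,
      cg_factor = cg_factor, window = window, trim = trim,
      measurement_noise = noise_est,
      flags = c(flags, model$flags))),
    class = "dg_calibration")
}


## Intercept-based measurement-noise estimate from Stop-state runs: pooled
## squared displacements at lags 1..4 follow MSD(tau) = slope tau +
## 4 sigma_loc^2, and orientation-increment variances follow
## V(tau) = slope tau + 2 sigma_or^2. Negative intercepts clamp to zero.
estimate_measurement_noise <- function(tracks, states_list, dt = 1,
                                       trim = 2, max_lag = 4L) {
  msd_tau <- matrix(0, max_lag, 2)  # sums, counts
  dth_pool <- lapply(seq_len(max_lag), function(L) list())
  for (i in seq_along(tracks)) {
    runs <- state_runs(states_list[[i]]$label, "Stop", trim = trim,
                       min_len = max_lag + 2)
    pos <- tracks[[i]]$positions
    th <- tracks[[i]]$theta
    for (r in runs) {
      r <- r[r <= nrow(pos)]
      for (L in seq_len(max_lag)) {
        if (length(r) <= L) next
        a <- r[seq_len(length(r) - L)]
        d2 <- rowSums((pos[a + L, , drop = FALSE] -
                         pos[a, , drop = FALSE])^2)
        msd_tau[L, ] <- msd_tau[L, ] + c(sum(d2), length(d2))
        if (!is.null(th)) {
          dth <- (th[a + L] - th[a] + pi) %% (2 * pi) - pi
          dth_pool[[L]][[length(dth_pool[[L]]) + 1L]] <- dth
        }
      }
    }
  }
  ok <- msd_tau[, 2] > 20
  loc <- 0
  if (sum(ok) >= 2) {
    y <- msd_tau[ok, 1] / msd_tau[ok, 2]
    tau <- which(ok) * dt
    loc <- max(unname(stats::coef(stats::lm(y ~ tau))[1]), 0)
  }
  # the orientation intercept is a small fraction of the lag-1 variance, so
  # it needs a tail-robust per-lag variance (hidden pivot frames inside
  # stops contaminate the means): MAD^2 of the pooled increments
  vth <- vapply(dth_pool, function(l) {
    x <- unlist(l, use.names = FALSE)
    if (length(x) < 50) return(NA_real_)
    stats::mad(x, center = 0)^2
  }, numeric(1))
  orr <- 0
  if (sum(is.finite(vth)) >= 2) {
    tau <- (seq_len(max_lag) * dt)[is.finite(vth)]
    orr <- max(unname(stats::coef(stats::lm(vth[is.finite(vth)] ~ tau))[1]),
               0)
  }
  list(sigma_loc = sqrt(loc / 4), sigma_or = sqrt(orr / 2))
}

#' Write / read a species profile file
#'
#' Serializes a calibration (motility parameters + transition model +
#' provenance) to a human-readable YAML profile so calibrated species
#' profiles can ship as plain-text fixtures.
#'
#' @param calib A `dg_calibration`, or a list with `params` and `model`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_species_profile <- function(calib, path) {
  p <- calib$params
  m <- calib$model
  obj <- list(
    species = p$species,
    parameters = lapply(p[MOTILITY_PARAM_NAMES], as.numeric),
    L_bar = as.numeric(p$L_bar),
    chiral = p$chiral,
    transition_model = list(
      states = m$states,
      embedded = apply(m$embedded, 1, as.numeric, simplify = FALSE),
      dwell_models = m$dwell_models))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_species_profile
#' @export
read_species_profile <- function(path) {
  obj <- yaml::read_yaml(path)
  pars <- obj$parameters
  params <- motility_parameters(
    v_par_mu_G = pars$v_par_mu_G, v_par_sigma_G = pars$v_par_sigma_G,
    omega_mu_G = pars$omega_mu_G, omega_sigma_G = pars$omega_sigma_G,
    v_par_sigma_S = pars$v_par_sigma_S, omega_sigma_S = pars$omega_sigma_S,
    omega_mu_P = pars$omega_mu_P, omega_sigma_P = pars$omega_sigma_P,
    L_bar = obj$L_bar, chiral = obj$chiral, species = obj$species)
  emb <- do.call(rbind, lapply(obj$transition_model$embedded, as.numeric))
  rs <- rowSums(emb)
  emb[rs > 0, ] <- emb[rs > 0, , drop = FALSE] / rs[rs > 0]  # renormalize
  model <- transition_model(embedded = emb,
                            dwell_models = obj$transition_model$dwell_models,
                            states = obj$transition_model$states)
  list(params = params, model = model)
}
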