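DG_STATES <- c("Glide", "Stop", "Pivot", "Reverse")

#' Construct a four-state transition model
#'
#' Describes switching between the four motility states as a continuous-time
#' Markov (or semi-Markov) process: an embedded jump chain plus a dwell-time
#' model per state. Exponential dwells make the process a CTMC with
#' generator `Q`; a lognormal Glide dwell (as observed in species with
#' periodic reversals) makes it semi-Markov. Transitions out of Reverse may
#' only go to Glide: a reversal re-establishes directed motion.
#'
#' @param Q Optional 4x4 generator (rows sum to 0, off-diagonals >= 0),
#'   rows/cols ordered as `states`. When supplied, the embedded chain and
#'   exponential dwell models are derived from it.
#' @param embedded Optional 4x4 embedded transition-probability matrix
#'   (zero diagonal, rows sum to 1; all-zero rows mark absorbing states).
#'   Required if `Q` is not given.
#' @param dwell_models Named list overriding the dwell model per state; each
#'   entry is `list(family = "exponential", rate = )`,
#'   `list(family = "lognormal", meanlog = , sdlog = )`, or
#'   `list(family = "instant")` (zero dwell, used for instantaneous
#'   reversals).
#' @param states State names (fixed order).
#' @return A `dg_transition_model` with elements `states`, `Q` (NA rows for
#'   non-exponential states), `embedded`, `dwell_models`, `mean_dwell`.
#' @export
transition_model <- function(Q = NULL, embedded = NULL, dwell_models = NULL,
                             states = DG_STATES) {
  k <- length(states)
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    stopifnot(nrow(Q) == k, ncol(Q) == k)
    dimnames(Q) <- list(states, states)
    off <- Q; diag(off) <- 0
    if (any(off < -1e-12)) stop("negative off-diagonal rate")
    if (any(abs(rowSums(Q)) > 1e-8)) stop("generator rows must sum to 0")
    exit <- -diag(Q)
    embedded <- matrix(0, k, k, dimnames = list(states, states))
    for (i in seq_len(k)) if (exit[i] > 0) embedded[i, ] <- off[i, ] / exit[i]
    dm <- lapply(seq_len(k), function(i)
      list(family = "exponential", rate = exit[i]))
    names(dm) <- states
  } else {
    if (is.null(embedded)) stop("supply Q or embedded")
    embedded <- as.matrix(embedded)
    dimnames(embedded) <- list(states, states)
    dm <- lapply(states, function(s) list(family = "exponential", rate = 0))
    names(dm) <- states
  }
  if (!is.null(dwell_models)) dm[names(dwell_models)] <- dwell_models
  if (any(diag(embedded) != 0)) stop("embedded diagonal must be zero")
  rs <- rowSums(embedded)
  if (any(rs > 0 & abs(rs - 1) > 1e-8))
    stop("embedded rows must sum to 1 (or 0 for absorbing states)")
  # Reverse exits only toward Glide
  if ("Reverse" %in% states) {
    bad <- setdiff(states[embedded["Reverse", ] > 1e-12], "Glide")
    if (length(bad) > 0)
      stop("Reverse may only transition to Glide (found: ",
           paste(bad, collapse = ", "), ")")
  }
  mean_dwell <- vapply(dm, dwell_mean, numeric(1))
  Qout <- matrix(NA_real_, k, k, dimnames = list(states, states))
  for (i in seq_len(k)) {
    if (dm[[i]]$family == "exponential") {
      rate <- dm[[i]]$rate
      Qout[i, ] <- rate * embedded[i, ]
      Qout[i, i] <- -rate
    }
  }
  structure(list(states = states, Q = Qout, embedded = embedded,
                 dwell_models = dm, mean_dwell = mean_dwell),
            class = "dg_transition_model")
}

dwell_mean <- function(dm) {
  switch(dm$family,
         exponential = if (dm$rate > 0) 1 / dm$rate else Inf,
         lognormal = exp(dm$meanlog + dm$sdlog^2 / 2),
         instant = 0,
         stop("unknown dwell family: ", dm$family))
}

#' @export
print.dg_transition_model <- function(x, digits = 4, ...) {
  cat("<dg_transition_model>\n  mean dwell (s):",
      paste(sprintf("%s=%.3g", x$states, x$mean_dwell), collapse = ", "),
      "\n  embedded transition probabilities:\n")
  print(round(x$embedded, digits))
  invisible(x)
}

#' Stationary time fractions of a transition model
#'
#' Stationary distribution of the embedded jump chain weighted by mean dwell
#' time (valid for semi-Markov dwell models; instantaneous states get zero
#' time fraction).
#'
#' @param model A `dg_transition_model`.
#' @return Named numeric vector summing to 1.
#' @export
stationary_distribution <- function(model) {
  P <- model$embedded
  k <- nrow(P)
  active <- rowSums(P) > 0
  A <- t(P[active, active, drop = FALSE]) - diag(sum(active))
  A <- rbind(A, rep(1, sum(active)))
  b <- c(rep(0, sum(active)), 1)
  a <- stats::lsfit(A, b, intercept = FALSE)$coefficients
  visit <- rep(0, k)
  visit[active] <- pmax(a, 0)
  tf <- visit * ifelse(is.finite(model$mean_dwell), model$mean_dwell, 1)
  tf <- tf / sum(tf)
  names(tf) <- model$states
  tf
}

#' Simulate a discretely observed state sequence
#'
#' Draws sojourns from the model's dwell distributions and embedded chain,
#' then reports the occupied state at frame times `0, dt, 2 dt, ...`.
#' Instantaneous states fall between frames and are never observed.
#'
#' @param model A `dg_transition_model`.
#' @param n_frames Number of observation frames.
#' @param dt Observation interval in seconds (default 1).
#' @param init Initial state (default: drawn from the stationary time
#'   fractions).
#' @param seed Optional RNG seed.
#' @return Character vector of state labels, length `n_frames`.
#' @export
simulate_state_sequence <- function(model, n_frames, dt = 1, init = NULL,
                                    seed = NULL) {
  with_seed(seed, {
    T_total <- n_frames * dt
    if (is.null(init)) {
      tf <- stationary_distribution(model)
      init <- sample(model$states, 1, prob = tf)
    }
    st <- init
    t_now <- 0
    labels <- character(0)
    times <- numeric(0)
    chunk <- 1024L
    labels <- character(chunk); times <- numeric(chunk)
    m <- 0L
    while (t_now < T_total) {
      d <- draw_dwell(model, st)
      m <- m + 1L
      if (m > length(times)) {  # grow geometrically
        labels <- c(labels, character(length(labels)))
        times <- c(times, numeric(length(times)))
      }
      labels[m] <- st
      times[m] <- t_now
      t_now <- t_now + d$duration
      if (is.null(d$next_state)) break
      st <- d$next_state
    }
    labels <- labels[seq_len(m)]
    times <- times[seq_len(m)]
    frame_t <- (seq_len(n_frames) - 1) * dt
    labels[findInterval(frame_t, times)]
  })
}

## ---- estimation ------------------------------------------------------------

state_counts <- function(seqs, states = DG_STATES) {
  k <- length(states)
  C <- matrix(0, k, k, dimnames = list(states, states))
  for (s in seqs) {
    lab <- if (is.data.frame(s)) as.character(s$label) else as.character(s)
    if (length(lab) < 2) next
    i <- match(lab[-length(lab)], states)
    j <- match(lab[-1], states)
    C <- C + matrix(tabulate((j - 1L) * k + i, nbins = k * k), k, k)
  }
  C
}

#' Extract per-state sojourn durations from labelled sequences
#'
#' Runs touching the start or end of a sequence are right/left-censored and
#' dropped by default.
#'
#' @param seqs List of `dg_states` (or label vectors).
#' @param dt Frame interval (s).
#' @param drop_censored Drop boundary runs (default TRUE).
#' @return Named list of numeric duration vectors per state.
#' @export
state_durations <- function(seqs, dt = 1, drop_censored = TRUE) {
  acc <- stats::setNames(lapply(DG_STATES, function(s) list()), DG_STATES)
  for (s in seqs) {
    lab <- if (is.data.frame(s)) as.character(s$label) else as.character(s)
    r <- rle(lab)
    n_runs <- length(r$values)
    if (drop_censored) {
      if (n_runs <= 2) next
      idx <- 2:(n_runs - 1)
    } else idx <- seq_len(n_runs)
    by_state <- split(r$lengths[idx] * dt, r$values[idx])
    for (st in names(by_state))
      acc[[st]][[length(acc[[st]]) + 1L]] <- by_state[[st]]
  }
  lapply(acc, function(l) unlist(l, use.names = FALSE) %||% numeric(0))
}

## Matrix logarithm via eigendecomposition (real part), for the
## matrix-log generator estimate.
matrix_log <- function(P) {
  e <- eigen(P)
  if (any(Mod(e$values) < 1e-12) || any(Re(e$values) <= 0 & Im(e$values) == 0))
    return(NULL)
  L <- e$vectors %*% diag(log(e$values), nrow = nrow(P)) %*% solve(e$vectors)
  Re(L)
}

## Mask of allowed off-diagonal transitions (Reverse -> Glide only).
allowed_mask <- function(states = DG_STATES) {
  k <- length(states)
  M <- matrix(TRUE, k, k, dimnames = list(states, states))
  diag(M) <- FALSE
  if ("Reverse" %in% states) {
    M["Reverse", ] <- FALSE
    if ("Glide" %in% states) M["Reverse", "Glide"] <- TRUE
  }
  M
}

project_generator <- function(Q, mask) {
  Q[!mask & row(Q) != col(Q)] <- 0
  Q[Q < 0 & row(Q) != col(Q)] <- 0
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Estimate the four-state continuous-time Markov model
#'
#' Maximum-likelihood generator for a CTMC observed at interval `dt`, fitted
#' by EM over the interval-censored transition counts (expected jump counts
#' and holding times computed with Van Loan matrix-exponential integrals).
#' The Reverse row is constrained to exit only toward Glide. Naive
#' count-ratio rates (`n_ij / time_in_i`, the continuous-observation MLE)
#' are always reported as a cross-check; `method = "matrixlog"` instead
#' takes the matrix logarithm of the empirical one-step matrix and projects
#' it onto valid generators (used automatically as a fallback when EM cannot
#' be initialized).
#'
#' @param seqs List of `dg_states` (or label vectors).
#' @param dt Observation interval in seconds (default 1).
#' @param method `"em"`, `"counts"`, or `"matrixlog"`.
#' @param max_iter,tol EM iteration controls.
#' @param dwell_family Family for the Glide dwell-time fit
#'   (`"auto"`, `"exponential"`, `"lognormal"`, or `NULL` to skip).
#' @param reverse_convention `"run"` (default): Reverse is a genuine
#'   short-dwell state, as emitted by the frame classifier. `"instant"`:
#'   each Reverse run is collapsed to a zero-width event and its frames are
#'   folded back into the surrounding state's holding time, matching the
#'   instantaneous-Reverse convention of the simulator; rates then come
#'   from the continuous-observation count estimator with a censoring
#'   correction for sojourns below the classifier's resolution.
#' @param min_run Classifier resolution in frames: shorter label runs are
#'   absorbed before counting (see [absorb_short_runs()]). Defaults to 3
#'   under the `"instant"` convention (classifier output) and 1 (no
#'   absorption) under `"run"`, where sequences are usually direct state
#'   observations whose short runs are genuine.
#' @return A `dg_transition_model` with extra fields `counts`, `naive_Q`,
#'   `method`, `flags`, `glide_dwell_fit`, `durations`.
#' @export
estimate_transition_model <- function(seqs, dt = 1,
                                      method = c("em", "counts", "matrixlog"),
                                      max_iter = 200, tol = 1e-9,
                                      dwell_family = "auto",
                                      reverse_convention = c("run", "instant"),
                                      min_run = NULL) {
  method <- match.arg(method)
  reverse_convention <- match.arg(reverse_convention)
  if (length(seqs) == 0) stop("data error: no state sequences")
  if (reverse_convention == "instant")
    return(estimate_instant_reverse(seqs, dt, dwell_family,
                                    min_run = min_run %||% 3))
  min_run <- min_run %||% 1
  states <- DG_STATES
  k <- length(states)
  seqs <- lapply(seqs, function(s) {
    lab <- if (is.data.frame(s)) as.character(s$label) else as.character(s)
    absorb_short_runs(lab, min_run)
  })
  C <- state_counts(seqs, states)
  N_i <- rowSums(C)
  flags <- character(0)
  absent <- states[N_i == 0]
  if (length(absent) > 0)
    flags <- c(flags, paste0("absent states: ", paste(absent, collapse = ", ")))
  mask <- allowed_mask(states)
  # naive continuous-observation rates
  naive_Q <- matrix(0, k, k, dimnames = list(states, states))
  for (i in seq_len(k)) if (N_i[i] > 0)
    naive_Q[i, -i] <- C[i, -i] / (N_i[i] * dt)
  naive_Q <- project_generator(naive_Q, mask)
  est_Q <- switch(method,
    counts = naive_Q,
    matrixlog = {
      Q <- matrixlog_estimate(C, dt, mask)
      if (is.null(Q)) { flags <- c(flags, "matrix log failed; naive rates used"); naive_Q }
      else Q
    },
    em = {
      init <- naive_Q
      init[mask & init < 1e-8] <- ifelse(C[mask & init < 1e-8] > 0, 1e-4, 0)
      diag(init) <- 0; diag(init) <- -rowSums(init)
      em <- em_generator(C, dt, init, mask, max_iter, tol)
      if (is.null(em)) {
        Q <- matrixlog_estimate(C, dt, mask)
        flags <- c(flags, "EM failed; matrix-log fallback used")
        if (is.null(Q)) Q <- naive_Q
        Q
      } else em
    })
  if (any(!is.finite(est_Q))) { est_Q <- naive_Q; flags <- c(flags, "non-finite estimate; naive rates used") }
  never_exit <- states[diag(est_Q) == 0 & N_i > 0]
  if (length(never_exit) > 0)
    flags <- c(flags, paste0("infinite dwell (never switches): ",
                             paste(never_exit, collapse = ", ")))
  durations <- state_durations(seqs, dt)
  glide_fit <- NULL
  dwell_override <- NULL
  if (!is.null(dwell_family) && length(durations$Glide) >= 10) {
    glide_fit <- fit_dwell_distribution(durations$Glide, dwell_family)
    if (glide_fit$family == "lognormal")
      dwell_override <- list(Glide = list(family = "lognormal",
                                          meanlog = glide_fit$params[["meanlog"]],
                                          sdlog = glide_fit$params[["sdlog"]]))
  }
  model <- transition_model(Q = est_Q, dwell_models = dwell_override,
                            states = states)
  # keep the estimated generator visible even when the dwell override makes
  # the model semi-Markov (rates then read 1/mean-dwell parameterizations)
  model$Q <- est_Q
  model$counts <- C
  model$naive_Q <- naive_Q
  model$method <- method
  model$flags <- flags
  model$glide_dwell_fit <- glide_fit
  model$durations <- durations
  model
}

## Instantaneous-Reverse estimator: collapse Reverse runs to zero-width
## events (their frames return to the preceding state's holding time) and
## estimate the sojourn-level chain over {Glide, Stop, Pivot} with
## reversals as Glide self-transitions. Total exit rates come from
## left-truncated sojourn means (memorylessness makes them immune to the
## classifier's loss of short sojourns), with an un-fusing factor for runs
## silently merged across hidden excursions; exit destinations come from
## the observed transition counts corrected by the path-fusion algebra
## F_obs = D F (I - (I-D) P)^-1 D, where d_i = exp(-lambda_i c) is the
## survival (visibility) probability of an i-sojourn. A reversal is visible
## only when both flanking glides survive (junctions with an even number of
## hidden reversals merge silently), so it gets a direct two-sided
## correction instead of the path algebra.
## Left-truncated dwell-model fit: ML on sojourns >= c_t with the density
## renormalized by the survival at c_t. Exponential has the closed form
## rate = 1/(mean - c_t); lognormal is fitted numerically. Family "auto"
## chooses by AIC on the truncated data.
fit_dwell_truncated <- function(durations, c_t,
                                family = c("auto", "exponential",
                                           "lognormal")) {
  family <- match.arg(family)
  x <- durations[durations >= c_t]
  if (length(x) < 10 || mean(x) <= c_t) return(NULL)
  n <- length(x)
  rate <- 1 / (mean(x) - c_t)
  ll_exp <- n * log(rate) - rate * sum(x - c_t)
  fit <- list(family = "exponential", params = c(rate = rate),
              mean = 1 / rate,
              surv = function(q) exp(-rate * q))
  if (family != "exponential") {
    nll <- function(p) {
      sl <- exp(p[2])
      s_ct <- stats::plnorm(c_t, p[1], sl, lower.tail = FALSE)
      if (s_ct <= 0) return(1e10)
      -sum(stats::dlnorm(x, p[1], sl, log = TRUE)) + n * log(s_ct)
    }
    init <- c(mean(log(x)), log(max(stats::sd(log(x)), 1e-3)))
    opt <- tryCatch(stats::optim(init, nll, method = "BFGS"),
                    error = function(e) NULL)
    if (!is.null(opt)) {
      ml <- opt$par[1]; sl <- exp(opt$par[2])
      ll_ln <- -opt$value
      use_ln <- switch(family, lognormal = TRUE,
                       auto = (2 * 2 - 2 * ll_ln) < (2 * 1 - 2 * ll_exp))
      if (use_ln)
        fit <- list(family = "lognormal",
                    params = c(meanlog = ml, sdlog = sl),
                    mean = exp(ml + sl^2 / 2),
                    surv = function(q)
                      stats::plnorm(q, ml, sl, lower.tail = FALSE))
    }
  }
  fit
}

estimate_instant_reverse <- function(seqs, dt, dwell_family = "auto",
                                     min_run = 3, censor_correction = TRUE) {
  states <- DG_STATES
  k <- length(states)
  n_ev <- matrix(0, k, k, dimnames = list(states, states))
  T_i <- stats::setNames(numeric(k), states)
  flags <- character(0)
  labs <- lapply(seqs, function(s) {
    lab <- if (is.data.frame(s)) as.character(s$label) else as.character(s)
    absorb_short_runs(lab, min_run)
  })
  for (lab in labs) {
    r <- rle(lab)
    vals <- r$values; lens <- r$lengths
    # fold Reverse runs into the preceding (or, at the start, following) run
    m <- length(vals)
    rev_runs <- which(vals == "Reverse")
    for (q in rev_runs) {
      donor <- if (q > 1) q - 1 else if (q < m) q + 1 else NA_integer_
      if (!is.na(donor)) {
        lens[donor] <- lens[donor] + lens[q]
        n_ev[vals[donor], "Reverse"] <- n_ev[vals[donor], "Reverse"] + 1
      }
      lens[q] <- 0
    }
    keep <- lens > 0
    vals <- vals[keep]; lens <- lens[keep]
    # merge adjacent equal states created by the collapse
    if (length(vals) > 1) {
      grp <- cumsum(c(TRUE, vals[-1] != vals[-length(vals)]))
      lens <- as.numeric(tapply(lens, grp, sum))
      vals <- vals[!duplicated(grp)]
    }
    for (j in seq_along(vals)) T_i[vals[j]] <- T_i[vals[j]] + lens[j] * dt
    if (length(vals) > 1) {
      i1 <- match(vals[-length(vals)], states)
      i2 <- match(vals[-1], states)
      n_ev <- n_ev + matrix(tabulate((i2 - 1L) * k + i1, nbins = k * k), k, k)
    }
  }
  # sojourn durations from the absorbed labels (Reverse runs still split
  # glides: a reversal terminates a glide sojourn)
  durations <- state_durations(labs, dt)
  rates_from <- function(n_mat) {
    Q <- matrix(0, k, k, dimnames = list(states, states))
    for (i in seq_len(k)) if (T_i[i] > 0) Q[i, ] <- n_mat[i, ] / T_i[i]
    Q["Reverse", ] <- 0
    Q["Reverse", "Glide"] <- 1  # structural; dwell is instantaneous
    project_generator(Q, allowed_mask(states))
  }
  Q <- rates_from(n_ev)
  gsp <- c("Glide", "Stop", "Pivot")
  dwfit_glide <- NULL
  if (censor_correction && all(T_i[c("Glide", "Stop")] > 0)) {
    c_eff <- min_run * dt
    c_rev <- 2 * dt  # a reversal flank needs ~2 clean frames of sign
    c_t <- 2 * min_run * dt
    # boundary-shift offsets: the reversal/ramp frames at a junction are
    # labelled away from the glide and into the stationary states, so an
    # observed glide run understates its sojourn by about 2.5 frames and
    # stop/pivot runs overstate theirs by about a frame
    delta_run <- c(2.5, -1, -1) * dt
    # visible exit rates and sojourn-visibility probabilities from
    # left-truncated dwell fits on the shift-corrected run lengths: for
    # exponential dwells the truncated mean is unbiased no matter what the
    # classifier does below c_t (memorylessness); the Glide dwell may be
    # lognormal, which is not shift-invariant, hence the explicit offset
    dwfit <- lapply(1:3, function(i)
      fit_dwell_truncated(durations[[gsp[i]]] + delta_run[i],
                          c_t + delta_run[i],
                          if (gsp[i] == "Glide") (dwell_family %||% "auto")
                          else "exponential"))
    names(dwfit) <- gsp
    dwfit_glide <- dwfit$Glide
    lam_vis <- vapply(gsp, function(st) {
      if (!is.null(dwfit[[st]])) 1 / dwfit[[st]]$mean
      else sum(n_ev[st, ]) / max(T_i[st], 1e-12)
    }, numeric(1))
    surv_at <- function(st, q, lam_st) {
      if (!is.null(dwfit[[st]]) && dwfit[[st]]$family == "lognormal")
        dwfit[[st]]$surv(q)
      else exp(-lam_st * q)
    }
    # Total exit rates are pinned by the truncated dwell fits: detection
    # losses and run fusion concentrate below the truncation point, so the
    # tail-based rates are nearly unbiased. Exit destinations come from
    # the chain of LONG runs only (>= c_t): long sojourns are reliably
    # detected and boundary artifacts (spurious sub-resolution interludes
    # at state changes) are confined to the skipped short runs. Skipping
    # is modelled explicitly: with q the true embedded chain (reversals as
    # Glide self-transitions) and s_j the probability that a j-sojourn is
    # long, the observed long-to-long transition fractions are the row-
    # normalized R = q (I - diag(1-s) q)^-1 diag(s); q is recovered by a
    # damped multiplicative fixed point.
    lam <- lam_vis
    # visibility thresholds on the true-dwell scale: a run is long when
    # its dwell exceeds c_t + delta, invisible when below c_eff + delta
    s_long <- pmax(vapply(1:3, function(i)
      surv_at(gsp[i], c_t + delta_run[i], lam[i]), numeric(1)), 0.05)
    h_inv <- pmin(1 - vapply(1:3, function(i)
      surv_at(gsp[i], c_eff + delta_run[i], lam[i]), numeric(1)), 0.9)
    N_LL <- matrix(0, 3, 3, dimnames = list(gsp, gsp))
    min_long <- ceiling(c_t / dt)
    for (lab in labs) {
      r <- rle(lab)
      sel <- r$values %in% gsp & r$lengths >= min_long
      v_long <- r$values[sel]
      if (length(v_long) > 1) {
        i1 <- match(v_long[-length(v_long)], gsp)
        i2 <- match(v_long[-1], gsp)
        N_LL <- N_LL + matrix(tabulate((i2 - 1L) * 3L + i1, nbins = 9L),
                              3, 3)
      }
    }
    Q <- rates_from(n_ev)  # fallback when long runs are too sparse
    if (sum(N_LL) >= 50 && all(rowSums(N_LL)[1:2] > 0)) {
      obs_frac <- N_LL / pmax(rowSums(N_LL), 1e-12)
      qd <- pmax(obs_frac, 1e-4)
      qd[2:3, ] <- qd[2:3, ] * (1 - diag(3)[2:3, ])  # no S/P self-loops
      qd <- qd / rowSums(qd)
      # forward model for the observed long-to-long fractions: skipped
      # short visits contribute paths (the A term); same-state pairs whose
      # intermediates are ALL invisible merge into a single run and leave
      # no pair, hence the all-invisible loop subtraction on the diagonal
      forward_frac <- function(qd) {
        A <- solve(diag(3) - diag(1 - s_long) %*% qd)
        R <- (qd %*% A) %*% diag(s_long)
        Zh <- solve(diag(3) - qd %*% diag(h_inv))
        Inv <- qd %*% diag(h_inv) %*% Zh %*% qd
        diag(R) <- (diag(qd %*% A) - diag(Inv)) * s_long
        R <- pmax(R, 0)
        R / pmax(rowSums(R), 1e-12)
      }
      for (it in 1:200) {
        pred <- forward_frac(qd)
        upd <- (obs_frac + 1e-6) / (pred + 1e-6)
        qd_new <- qd * upd^0.5          # damped multiplicative update
        qd_new[2:3, ] <- qd_new[2:3, ] * (1 - diag(3)[2:3, ])
        qd_new <- qd_new / pmax(rowSums(qd_new), 1e-12)
        delta <- max(abs(qd_new - qd))
        qd <- qd_new
        if (delta < 1e-10) break
      }
      Q <- matrix(0, k, k, dimnames = list(states, states))
      for (i in 1:3) {
        Q[gsp[i], gsp] <- lam[i] * qd[i, ]
        if (i == 1) Q["Glide", "Reverse"] <- lam[1] * qd[1, 1]
      }
      Q[cbind(gsp, gsp)] <- 0
      Q["Reverse", "Glide"] <- 1
      Q <- project_generator(Q, allowed_mask(states))
    }
  }
  if (any(T_i == 0))
    flags <- c(flags, paste0("absent states: ",
                             paste(states[T_i == 0], collapse = ", ")))
  glide_fit <- NULL
  dwell_override <- list(Reverse = list(family = "instant"))
  if (!is.null(dwell_family) && length(durations$Glide) >= 10) {
    glide_fit <- fit_dwell_distribution(durations$Glide, dwell_family)
    # prefer the truncation-aware fit for the model's dwell law
    src <- if (!is.null(dwfit_glide)) dwfit_glide else glide_fit
    if (src$family == "lognormal")
      dwell_override$Glide <- list(family = "lognormal",
                                   meanlog = src$params[["meanlog"]],
                                   sdlog = src$params[["sdlog"]])
  }
  model <- transition_model(Q = Q, dwell_models = dwell_override)
  model$Q <- Q
  model$counts <- n_ev
  model$naive_Q <- rates_from(n_ev)
  model$method <- "counts-instant"
  model$flags <- flags
  model$glide_dwell_fit <- glide_fit
  # truncation-aware family fit (immune to the classifier's censoring of
  # short sojourns); preferred for reporting the dwell family
  model$glide_dwell_fit_truncated <- dwfit_glide
  model$durations <- durations
  model$time_in_state <- T_i
  model
}

matrixlog_estimate <- function(C, dt, mask) {
  k <- nrow(C)
  P <- C / pmax(rowSums(C), 1)
  P[rowSums(C) == 0, ] <- diag(k)[rowSums(C) == 0, ]
  L <- matrix_log(P)
  if (is.null(L)) return(NULL)
  project_generator(L / dt, mask)
}

## EM for a CTMC observed at interval dt, via Van Loan integrals:
## expm([[Q, E],[0, Q]] dt) has upper-right block int_0^dt e^{Qu} E e^{Q(dt-u)} du.
em_generator <- function(C, dt, Q, mask, max_iter, tol) {
  k <- nrow(Q)
  observed <- which(C > 0, arr.ind = TRUE)
  for (iter in seq_len(max_iter)) {
    P <- as.matrix(Matrix::expm(Q * dt))
    if (any(P[C > 0] <= 0)) return(NULL)
    EN <- matrix(0, k, k)  # expected jump counts
    ER <- numeric(k)       # expected holding times
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a != b && (!mask[a, b] || Q[a, b] == 0)) next
      E <- matrix(0, k, k); E[a, b] <- 1
      big <- rbind(cbind(Q, E), cbind(matrix(0, k, k), Q))
      I_ab <- as.matrix(Matrix::expm(big * dt))[1:k, (k + 1):(2 * k)]
      w <- I_ab[cbind(observed[, 1], observed[, 2])] /
           P[cbind(observed[, 1], observed[, 2])]
      tot <- sum(C[observed] * w)
      if (a == b) ER[a] <- tot else EN[a, b] <- Q[a, b] * tot
    }
    Q_new <- matrix(0, k, k)
    for (a in seq_len(k)) if (ER[a] > 0) Q_new[a, ] <- EN[a, ] / ER[a]
    Q_new <- project_generator(Q_new, mask)
    delta <- max(abs(Q_new - Q))
    Q <- Q_new
    if (delta < tol) break
  }
  dimnames(Q) <- dimnames(C)
  Q
}

#' Fit a dwell-time distribution
#'
#' Closed-form maximum-likelihood fits of the exponential and lognormal
#' families; under `family = "auto"` the model with the lower AIC is
#' selected. A Kolmogorov-Smirnov goodness-of-fit p-value (computed at the
#' fitted parameters, hence approximate) is attached.
#'
#' @param durations Positive sojourn durations in seconds (>= 10 values).
#' @param family `"auto"`, `"exponential"`, or `"lognormal"`.
#' @return List with `family`, `params`, `aic` (named vector for both
#'   families), `ks_p`, `n`.
#' @export
fit_dwell_distribution <- function(durations,
                                   family = c("auto", "exponential",
                                              "lognormal")) {
  family <- match.arg(family)
  x <- as.numeric(durations)
  if (any(x <= 0)) stop("data error: nonpositive duration")
  if (length(x) < 10) stop("data error: need at least 10 durations")
  n <- length(x)
  rate <- 1 / mean(x)
  ll_exp <- n * log(rate) - rate * sum(x)
  ml <- mean(log(x))
  sl <- sqrt(mean((log(x) - ml)^2))
  sl_safe <- max(sl, 1e-12)
  ll_lnorm <- sum(stats::dlnorm(x, ml, sl_safe, log = TRUE))
  aic <- c(exponential = 2 * 1 - 2 * ll_exp,
           lognormal = 2 * 2 - 2 * ll_lnorm)
  chosen <- switch(family,
                   auto = names(which.min(aic)),
                   exponential = "exponential",
                   lognormal = "lognormal")
  if (chosen == "exponential") {
    params <- c(rate = rate)
    ks <- suppressWarnings(stats::ks.test(x, stats::pexp, rate))
  } else {
    params <- c(meanlog = ml, sdlog = sl)
    ks <- suppressWarnings(stats::ks.test(x, stats::plnorm, ml, sl_safe))
  }
  list(family = chosen, params = params, aic = aic,
       ks_p = ks$p.value, n = n)
}

#' Prune weak edges of a transition network for display
#'
#' Removes edges with embedded transition probability at or below
#' `min_prob` from the rendered network; the underlying model is untouched.
#'
#' @param model A `dg_transition_model`.
#' @param min_prob Pruning threshold (default 0.2; edges with probability
#'   `<= min_prob` are dropped).
#' @return data.frame with columns `from`, `to`, `prob`.
#' @export
prune_transition_network <- function(model, min_prob = 0.2) {
  P <- model$embedded
  idx <- which(P > min_prob, arr.ind = TRUE)
  data.frame(from = model$states[idx[, 1]],
             to = model$states[idx[, 2]],
             prob = P[idx])
}

#' Detect a dominant oscillation period
#'
#' Autocorrelation-based period detection, e.g. for the quasi-periodic
#' reversals of species with lognormal glide dwells (acf of the tangential
#' velocity) or loop periods (acf of heading components). The first local
#' maximum of the averaged autocorrelation at lag >= 2 exceeding the
#' white-noise significance band is reported.
#'
#' @param x Numeric series or list of series (e.g. `v_par` per track).
#' @param dt Frame interval (s).
#' @param max_lag Maximum lag in frames (default: half the series length,
#'   capped at 300).
#' @param conf Significance level for the white-noise band (default 0.95).
#' @return Dominant period in seconds, or `NA_real_` when no significant
#'   peak exists.
#' @export
detect_periodicity <- function(x, dt = 1, max_lag = NULL, conf = 0.95) {
  if (!is.list(x)) x <- list(x)
  n_min <- min(vapply(x, length, integer(1)))
  max_lag <- max_lag %||% min(floor(n_min / 2), 300L)
  if (max_lag < 4) stop("series too short for period detection")
  acfs <- vapply(x, function(v)
    as.numeric(stats::acf(v, lag.max = max_lag, plot = FALSE,
                          demean = TRUE)$acf), numeric(max_lag + 1))
  a <- rowMeans(acfs)
  n_eff <- sum(vapply(x, length, integer(1)))
  # white-noise band corrected for scanning max_lag lags
  band <- stats::qnorm(1 - (1 - conf) / 2 / max_lag) / sqrt(n_eff)
  # an oscillation must first decorrelate (dip below zero) and then
  # recohere: report the first significant local maximum after the dip
  dip <- which(a < 0)[1]
  if (is.na(dip) || dip + 1 >= max_lag) return(NA_real_)
  for (k in (dip + 1):max_lag) {
    if (a[k] > a[k - 1] && a[k] >= a[k + 1] && a[k] > band)
      return((k - 1) * dt)
  }
  NA_real_
}
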