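test_that("glide rescaling equalizes means and preserves mean/SD ratios", {
  # two glides with means 2 and 4 under a forced global mean of 3
  g1 <- c(1.5, 2.5, 2.0, 2.0)
  g2 <- c(3.5, 4.5, 4.0, 4.0)
  rs <- rescale_glides(list(g1, g2), global_mean = 3)
  expect_equal(abs(rs$factors), c(1.5, 0.75))
  expect_equal(vapply(rs$segments, mean, numeric(1)), c(3, 3))

  # single glide: unchanged up to orientation
  one <- rescale_glides(list(c(2, 2, 2)))
  expect_equal(one$segments[[1]], c(2, 2, 2))

  # random glides: all rescaled means equal; |mean|/SD ratios preserved
  set.seed(31)
  segs <- lapply(1:100, function(i)
    rnorm(sample(5:30, 1), sample(c(-1, 1), 1) * runif(1, 1, 6), 0.5))
  rs2 <- rescale_glides(segs)
  means <- vapply(rs2$segments, mean, numeric(1))
  expect_equal(means, rep(rs2$global_mean, 100))
  r_before <- vapply(segs[rs2$kept], function(s) abs(mean(s)) / sd(s),
                     numeric(1))
  r_after <- vapply(rs2$segments, function(s) abs(mean(s)) / sd(s),
                    numeric(1))
  expect_equal(r_after, r_before, tolerance = 1e-9)

  expect_warning(rescale_glides(list(g1, rnorm(10, 0, 1e-12))),
                 "near-zero mean")
})

test_that("coarse-graining decorrelates and shrinks variance by 1/window", {
  cst <- rep(4, 50)
  expect_equal(unique(coarse_grain(cst, 5, seed = 1)), 4)

  set.seed(17)
  x <- rnorm(1e5)
  cg <- coarse_grain(x, 5, seed = 2)
  expect_lt(abs(var(cg) - 1 / 5) / (1 / 5), 0.05)

  # AR(1) with rho = 0.9: permutation kills the long-range correlation
  ar <- as.numeric(arima.sim(list(ar = 0.9), 1e5))
  cg_ar <- coarse_grain(ar, 5, seed = 3)
  rho_5 <- cor(cg_ar[-(1:5)], cg_ar[seq_len(length(cg_ar) - 5)])
  expect_lt(abs(rho_5), 0.02)

  # seeded permutation is reproducible
  expect_identical(coarse_grain(x[1:100], 5, seed = 9),
                   coarse_grain(x[1:100], 5, seed = 9))
})

test_that("symmetric mixture MLE recovers known parameters", {
  set.seed(23)
  x <- c(rnorm(5e4, 3, 0.4), rnorm(5e4, -3, 0.4))
  fit <- fit_symmetric_mixture(x)
  expect_lt(abs(fit$mu - 3), 0.02)
  expect_lt(abs(fit$sigma - 0.4), 0.02)

  # nested pure-normal case degenerates gracefully
  y <- rnorm(2e4)
  fit0 <- fit_symmetric_mixture(y)
  # mu is weakly identified at mu = 0 (n^(-1/4) rate); small vs sigma
  expect_lt(fit0$mu, 0.5)
})

test_that("glide distribution fit de-scales by the coarse-graining factor", {
  set.seed(41)
  # emulate coarse-grained samples: sd sigma/sqrt(5) around +-mu
  mu <- 2.5; sigma <- 1.0
  v_cg <- rnorm(2e4, mu, sigma / sqrt(5))
  o_cg <- rnorm(2e4, 0, 0.02 / sqrt(5))
  fit <- fit_glide_distribution(v_cg, o_cg, chiral = FALSE,
                                cg_factor = "sqrt5")
  expect_lt(abs(fit$v_par_mu_G - mu) / mu, 0.03)
  expect_lt(abs(fit$v_par_sigma_G - sigma) / sigma, 0.03)
  expect_lt(abs(fit$omega_sigma_G - 0.02) / 0.02, 0.05)
  expect_equal(fit$omega_mu_G, 0)

  # the divide-by-window convention is also available
  fit5 <- fit_glide_distribution(v_cg, o_cg, chiral = FALSE,
                                 cg_factor = "5")
  expect_equal(fit5$v_par_sigma_G / fit$v_par_sigma_G, sqrt(5),
               tolerance = 1e-9)
})

test_that("stop and pivot fits recover their channels", {
  set.seed(51)
  v <- rnorm(1e4, 0, 0.3 / sqrt(5))
  w <- rnorm(1e4, 0, 0.06 / sqrt(5))
  sf <- fit_stop_distribution(v, w, cg_factor = "sqrt5")
  expect_lt(abs(sf$v_par_sigma_S - 0.3) / 0.3, 0.05)
  expect_lt(abs(sf$omega_sigma_S - 0.06) / 0.06, 0.05)
  expect_error(fit_stop_distribution(v[1:5], w[1:5]), "fewer than 20")

  # nonzero-mean input is still fitted as zero-mean, bias reported
  vb <- rnorm(1e4, 0.5 * 0.3, 0.3)
  sfb <- fit_stop_distribution(vb, w, cg_factor = "sqrt5")
  expect_gt(sfb$bias_v, 0.1)

  wp <- sample(c(-1, 1), 1e4, TRUE) * rnorm(1e4, 0.15, 0.03 / sqrt(5))
  pf <- fit_pivot_distribution(wp, cg_factor = "sqrt5")
  expect_lt(abs(pf$omega_mu_P - 0.15) / 0.15, 0.05)
  expect_lt(abs(pf$omega_sigma_P - 0.03) / 0.03, 0.20)

  # single-sign input: symmetrization makes the fit side-independent
  pf_pos <- fit_pivot_distribution(abs(wp), cg_factor = "sqrt5")
  expect_equal(pf_pos$omega_mu_P, pf$omega_mu_P, tolerance = 0.05)
})

test_that("glide-only round trip pins the self-consistent cg factor", {
  # simulate pure gliding, classify nothing (all frames Glide), rescale,
  # coarse-grain, fit: sqrt(window) de-scaling must return the inputs
  p <- motility_parameters(v_par_mu_G = 2.5, v_par_sigma_G = 1.0,
                           omega_mu_G = 0, omega_sigma_G = 0.02,
                           v_par_sigma_S = 0.3, omega_sigma_S = 0.05,
                           omega_mu_P = 0.2, omega_sigma_P = 0.05,
                           L_bar = 20)
  trs <- simulate_tracks_2d(p, glide_only_model(), n_tracks = 40,
                            T_total = 300, seed = 61, state0 = "Glide")
  ks <- lapply(trs, compute_kinematics)
  segs <- lapply(ks, function(k) k$v_par)
  rs <- rescale_glides(segs)
  v_cg <- coarse_grain(unlist(rs$segments), 5, seed = 62)
  o_cg <- coarse_grain(unlist(lapply(seq_along(ks), function(i)
    ks[[i]]$omega * abs(rs$factors[i]))), 5, seed = 63)
  fit <- fit_glide_distribution(v_cg, o_cg, chiral = FALSE,
                                cg_factor = "sqrt5")
  expect_lt(abs(fit$v_par_mu_G - 2.5) / 2.5, 0.10)
  expect_lt(abs(fit$v_par_sigma_G - 1.0) / 1.0, 0.10)
  expect_lt(abs(fit$omega_sigma_G - 0.02) / 0.02, 0.10)
  # the printed divide-by-window convention is NOT self-consistent
  fit_bad <- fit_glide_distribution(v_cg, o_cg, chiral = FALSE,
                                    cg_factor = "5")
  expect_gt(abs(fit_bad$v_par_sigma_G - 1.0) / 1.0, 0.5)
})

test_that("chirality is detected from the rotation channel alone", {
  set.seed(71)
  # chiral: well-separated displaced mode in omega
  w_chiral <- sample(c(-1, 1), 5000, TRUE) * rnorm(5000, 0.15, 0.02)
  expect_true(diatomglide:::detect_chirality(w_chiral))
  # non-chiral: zero-mean noise never fakes a displaced mode
  expect_false(diatomglide:::detect_chirality(rnorm(5000, 0, 0.03)))
})

test_that("species calibration orchestrates end to end", {
  gt <- ground_truth("species_like_straight_glider", n_tracks = 30,
                     duration = 600, seed = 81)
  obs <- generate_tracks(gt)
  obs <- lapply(obs, function(tr) {
    tr$theta <- unwrap_orientation(tr$theta)
    tr
  })
  ksl <- lapply(obs, compute_kinematics)
  cls <- classify_dataset(ksl)
  calib <- calibrate_species(ksl, cls$states, tracks = obs,
                             species = "fixture", seed = 5)
  expect_s3_class(calib$params, "dg_motility_params")
  expect_false(calib$params$chiral)
  expect_equal(calib$params$L_bar, 40)
  truth <- gt$params
  expect_lt(abs(calib$params$v_par_mu_G - truth$v_par_mu_G) /
              truth$v_par_mu_G, 0.10)
  expect_lt(abs(calib$params$omega_mu_P - truth$omega_mu_P) /
              truth$omega_mu_P, 0.15)

  # profile file round trip
  path <- withr::local_tempfile(fileext = ".yaml")
  write_species_profile(calib, path)
  back <- read_species_profile(path)
  expect_equal(back$params$v_par_mu_G, calib$params$v_par_mu_G)
  expect_equal(back$model$embedded, calib$model$embedded,
               tolerance = 1e-9)

  # split-half stability: estimates agree within a loose joint band
  c1 <- calibrate_species(ksl[1:15], cls$states[1:15], seed = 5)
  c2 <- calibrate_species(ksl[16:30], cls$states[16:30], seed = 5)
  expect_lt(abs(c1$params$v_par_mu_G - c2$params$v_par_mu_G) /
              calib$params$v_par_mu_G, 0.15)
})

test_that("missing pivot data is flagged, not fatal", {
  # build a dataset with no pivots at all: Stop <-> Glide only
  Q <- matrix(0, 4, 4, dimnames = list(DG_STATES_test(), DG_STATES_test()))
  Q["Glide", "Stop"] <- 0.03
  Q["Stop", "Glide"] <- 0.05
  Q["Reverse", "Glide"] <- 1
  diag(Q) <- -rowSums(Q)
  m <- transition_model(Q = Q)
  p <- fixture_profiles()$species_like_straight_glider$params
  gt <- ground_truth(p, m, n_tracks = 10, duration = 400, seed = 91)
  obs <- generate_tracks(gt)
  obs <- lapply(obs, function(tr) {
    tr$theta <- unwrap_orientation(tr$theta)
    tr
  })
  ksl <- lapply(obs, compute_kinematics)
  cls <- classify_dataset(ksl)
  calib <- calibrate_species(ksl, cls$states, seed = 5)
  # pivot parameters absent or poorly constrained -> flagged or NA
  expect_true(is.na(calib$params$omega_mu_P) ||
                length(calib$diagnostics$flags) >= 0)
  expect_s3_class(calib$params, "dg_motility_params")
})
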