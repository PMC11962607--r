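test_that("arclength resampling produces uniform spacing", {
  line <- dg_polyline(cbind(c(0, 3, 10), c(0, 0, 0)))
  rs <- resample_polyline(line, 1)
  expect_equal(nrow(rs$points), 11)
  expect_equal(rs$points[, 1], 0:10)
  expect_equal(rs$points[, 2], rep(0, 11))

  # irregularly sampled unit circle
  set.seed(5)
  phi <- sort(runif(400, 0, 2 * pi))
  circ <- dg_polyline(cbind(cos(phi), sin(phi)))
  rs2 <- resample_polyline(circ, 2 * pi / 100)
  seg <- sqrt(rowSums(diff(rs2$points)^2))
  expect_lt(diff(range(seg)) / mean(seg), 0.2)  # near-uniform chords
  expect_equal(sqrt(rowSums(rs2$points^2)), rep(1, nrow(rs2$points)),
               tolerance = 1e-3)

  expect_error(resample_polyline(line, 20), "shorter than 2 steps")
})

test_that("three-point circle fits recover curvature exactly", {
  phi <- seq(0, pi, length.out = 50)
  circ <- dg_polyline(cbind(5 * cos(phi), 5 * sin(phi)))
  prof <- curvature_profile(circ, 5)
  expect_equal(prof$kappa, rep(0.2, length(prof$kappa)), tolerance = 1e-9)

  line <- dg_polyline(cbind(seq(0, 10, length.out = 20), rep(0, 20)))
  expect_equal(curvature_profile(line, 5)$kappa,
               rep(0, 16))

  # noisy circle: median curvature within 10% over seeds
  meds <- vapply(1:100, function(s) {
    set.seed(s)
    phi <- seq(0, 2 * pi, length.out = 120)[-120]
    pts <- cbind(10 * cos(phi), 10 * sin(phi)) +
      matrix(rnorm(238, 0, 0.05), ncol = 2)
    median(curvature_profile(dg_polyline(pts), 5)$kappa)
  }, numeric(1))
  expect_lt(abs(median(meds) - 0.1) / 0.1, 0.10)
})

test_that("curvature is rigid-motion invariant and scale covariant", {
  set.seed(11)
  pts <- cbind(cumsum(runif(40, 0.5, 1.5)), cumsum(rnorm(40, 0, 0.4)))
  k0 <- curvature_profile(dg_polyline(pts), 5)$kappa
  a <- 0.7
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  k1 <- curvature_profile(dg_polyline(sweep(pts %*% t(Rm), 2, c(3, -2),
                                            "+")), 5)$kappa
  expect_equal(k0, k1, tolerance = 1e-9)
  k2 <- curvature_profile(dg_polyline(2 * pts), 5)$kappa
  expect_equal(k2, k0 / 2, tolerance = 1e-9)
})

test_that("synthetic raphes carry their analytic curvature", {
  arc <- generate_raphe("arc", length = 30, radius = 20, n_points = 80)
  prof <- curvature_profile(arc, 5)
  expect_equal(prof$kappa, rep(0.05, length(prof$kappa)), tolerance = 1e-6)

  line <- generate_raphe("line", length = 50)
  expect_equal(curvature_profile(line, 5)$kappa,
               rep(0, 96))

  sig <- generate_raphe("sigmoid", length = 60, n_points = 400,
                        amplitude = 8, wavelength = 15)
  prof_s <- curvature_profile(sig, 3)
  truth <- attr(sig, "kappa_true")[2:399]
  # pointwise within 5% away from the (zero-curvature) inflection
  sel <- truth > 0.2 * max(truth)
  expect_lt(max(abs(prof_s$kappa[sel] - truth[sel]) / truth[sel]), 0.05)
})

test_that("glide segmentation splits tracks at high-curvature arcs", {
  # two straight runs joined by a tight quarter arc
  straight1 <- cbind(seq(0, 20, by = 1), rep(0, 21))
  phi <- seq(-pi / 2, 0, length.out = 7)[-c(1, 7)]
  arc <- cbind(20 + 2 * cos(phi), 2 + 2 * sin(phi))
  straight2 <- cbind(rep(22, 21), seq(2, 22, by = 1))
  pts <- rbind(straight1, arc, straight2)
  n <- nrow(pts)
  tr <- dg_track("z", seq_len(n) - 1, pts, theta = rep(0, n),
                 body_length = 5, unwrap = FALSE)
  kap <- track_curvature(tr, 5)
  ks <- compute_kinematics(tr)
  segs <- segment_glides(kap, ks, kappa_threshold = 0.2)
  expect_equal(nrow(segs), 2)
  # boundaries at the arc within one window
  expect_lt(abs(segs$end[1] - 21), 6)
  expect_lt(abs(segs$start[2] - 26), 6)
  expect_true(all(segs$mean_speed >= 0))

  # all below threshold -> single segment
  lin <- make_line_track(n = 30, v = 1)
  kl <- track_curvature(lin, 5)
  segs1 <- segment_glides(kl, compute_kinematics(lin), 0.5)
  expect_equal(nrow(segs1), 1)

  # alternating curvature above/below per frame: nothing survives min length
  kap_alt <- rep(c(0.01, 10), length.out = 30)
  ks30 <- compute_kinematics(make_line_track(n = 30, v = 1))
  expect_equal(nrow(segment_glides(c(kap_alt[1:29], NA), ks30, 0.5)), 0)

  expect_error(segment_glides(kap[-1], ks, 0.2), "misaligned")
})

test_that("median-speed selection follows type-7 percentiles", {
  segs <- data.frame(start = 1, end = 10, mean_kappa = 0,
                     mean_speed = 1:100, n_frames = 10)
  sel <- median_speed_selection(segs)
  lo <- type7_quantile(1:100, 0.45)
  hi <- type7_quantile(1:100, 0.55)
  expect_setequal(sel$mean_speed,
                  (1:100)[1:100 >= lo & 1:100 <= hi])
  # degenerate distribution: all retained
  same <- transform(segs, mean_speed = 7)
  expect_equal(nrow(median_speed_selection(same)), 100)
  expect_equal(nrow(median_speed_selection(segs[1, ])), 1)
  expect_error(median_speed_selection(segs[0, ]), "no glide segments")
})

test_that("curvature distribution comparison is calibrated", {
  set.seed(21)
  pool <- rlnorm(400, -2, 0.5)
  same <- compare_curvature_distributions(pool, pool, n_perm = 0)
  expect_equal(same$ks_distance, 0)
  expect_equal(same$overlap, 1)

  a <- runif(300, 0.001, 0.01)
  b <- runif(300, 0.1, 1)
  disj <- compare_curvature_distributions(a, b, n_perm = 0)
  expect_lt(disj$overlap, 0.05)

  # null calibration: p-values roughly uniform for same-distribution pools
  ps <- vapply(1:60, function(s) {
    set.seed(s + 100)
    compare_curvature_distributions(rlnorm(200, -2, 0.4),
                                    rlnorm(200, -2, 0.4),
                                    n_perm = 99, seed = s)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_gt(mean(ps < 0.5), 0.3)
})

test_that("chiral glide curvature links geometry to the simulator", {
  # zero-noise chiral glide: radius v/omega, <kappa> = omega/v
  p <- motility_parameters(v_par_mu_G = 2, v_par_sigma_G = 0,
                           omega_mu_G = 0.1, omega_sigma_G = 0,
                           v_par_sigma_S = 0, omega_sigma_S = 0,
                           omega_mu_P = 0.1, omega_sigma_P = 0,
                           L_bar = 10, chiral = TRUE)
  tr <- simulate_track_2d(p, glide_only_model(), T_total = 120, dt = 0.01,
                          seed = 4, theta0 = 0, state0 = "Glide")
  kap <- track_curvature(tr, 5)
  expect_equal(mean(kap, na.rm = TRUE), 0.1 / 2, tolerance = 1e-6)
})
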