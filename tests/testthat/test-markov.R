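test_that("transition model enforces structure", {
  Q <- matrix(0, 4, 4, dimnames = list(DG_STATES_test(), DG_STATES_test()))
  Q["Glide", "Stop"] <- 0.02
  Q["Stop", "Glide"] <- 0.05
  Q["Reverse", "Glide"] <- 1
  diag(Q) <- -rowSums(Q)
  m <- transition_model(Q = Q)
  expect_s3_class(m, "dg_transition_model")
  expect_equal(rowSums(m$embedded)[c("Glide", "Stop")], c(Glide = 1, Stop = 1))
  expect_equal(m$mean_dwell[["Glide"]], 50)

  # Reverse toward anything but Glide is rejected
  Qbad <- Q
  Qbad["Reverse", "Stop"] <- 0.1
  Qbad["Reverse", "Reverse"] <- -1.1
  expect_error(transition_model(Q = Qbad), "Reverse may only")
  Qneg <- Q; Qneg["Glide", "Pivot"] <- -0.01
  expect_error(transition_model(Q = Qneg), "negative")

  # embedded + mean dwell reconstruct the generator (round trip)
  m2 <- transition_model(embedded = m$embedded,
                         dwell_models = m$dwell_models)
  expect_equal(m2$Q, m$Q)
})

test_that("stationary distribution weights visits by dwell", {
  prof <- fixture_profiles()$species_like_straight_glider
  tf <- stationary_distribution(prof$model)
  expect_equal(sum(tf), 1)
  expect_equal(unname(tf["Reverse"]), 0)  # instantaneous state
  expect_gt(tf[["Glide"]], 0.55)
  expect_lt(tf[["Glide"]], 0.75)
})

test_that("two-state generator is recovered from discrete observations", {
  Q <- matrix(0, 4, 4, dimnames = list(DG_STATES_test(), DG_STATES_test()))
  Q["Glide", "Stop"] <- 0.1
  Q["Stop", "Glide"] <- 0.1
  Q["Reverse", "Glide"] <- 1
  diag(Q) <- -rowSums(Q)
  m <- transition_model(Q = Q)
  seqs <- lapply(1:5, function(i)
    simulate_state_sequence(m, 20000, seed = i, init = "Glide"))
  est <- estimate_transition_model(seqs, dt = 1, method = "em")
  expect_lt(abs(est$Q["Glide", "Stop"] - 0.1) / 0.1, 0.05)
  expect_lt(abs(est$Q["Stop", "Glide"] - 0.1) / 0.1, 0.05)
  # naive counts agree to leading order
  expect_lt(abs(est$naive_Q["Glide", "Stop"] - 0.1) / 0.1, 0.12)
})

test_that("four-state generator with the Reverse constraint is recovered", {
  Q <- matrix(0, 4, 4, dimnames = list(DG_STATES_test(), DG_STATES_test()))
  Q["Glide", c("Stop", "Pivot", "Reverse")] <- c(0.02, 0.01, 0.03)
  Q["Stop", c("Glide", "Pivot")] <- c(0.05, 0.01)
  Q["Pivot", c("Glide", "Stop")] <- c(0.08, 0.02)
  Q["Reverse", "Glide"] <- 0.2
  diag(Q) <- -rowSums(Q)
  m <- transition_model(Q = Q)
  seqs <- lapply(1:10, function(i)
    simulate_state_sequence(m, 1e5, seed = 50 + i))
  est <- estimate_transition_model(seqs, dt = 1, method = "em")
  free <- which(Q > 0 & row(Q) != col(Q))
  expect_lt(max(abs(est$Q[free] - Q[free]) / Q[free]), 0.10)
  # the constraint survives regardless of input
  expect_equal(unname(est$Q["Reverse", c("Stop", "Pivot")]), c(0, 0))
})

test_that("dwell-time fits select the right family with accurate MLEs", {
  set.seed(14)
  x <- rexp(1e4, 1 / 20)
  f <- fit_dwell_distribution(x, "auto")
  expect_equal(f$family, "exponential")
  expect_lt(abs(1 / f$params[["rate"]] - 20) / 20, 0.03)

  y <- rlnorm(1e4, 3, 0.3)
  g <- fit_dwell_distribution(y, "auto")
  expect_equal(g$family, "lognormal")
  expect_lt(abs(g$params[["meanlog"]] - 3) / 3, 0.03)
  expect_lt(abs(g$params[["sdlog"]] - 0.3) / 0.3, 0.03)

  # degenerate: identical durations handled without overflow
  same <- rep(5, 20)
  h <- fit_dwell_distribution(same, "lognormal")
  expect_true(is.finite(h$params[["meanlog"]]))
  h2 <- fit_dwell_distribution(same, "exponential")
  expect_equal(unname(1 / h2$params[["rate"]]), 5)

  expect_error(fit_dwell_distribution(c(x[1:20], -1)), "nonpositive")
  expect_error(fit_dwell_distribution(x[1:5]), "at least 10")
})

test_that("network pruning removes weak edges without touching the model", {
  emb <- matrix(0, 4, 4, dimnames = list(DG_STATES_test(), DG_STATES_test()))
  emb["Glide", c("Stop", "Pivot", "Reverse")] <- 1 / 3
  emb["Stop", c("Glide", "Pivot")] <- c(0.8, 0.2)
  emb["Pivot", c("Glide", "Stop")] <- c(0.5, 0.5)
  emb["Reverse", "Glide"] <- 1
  m <- transition_model(embedded = emb,
                        dwell_models = list(
                          Glide = list(family = "exponential", rate = 0.05),
                          Stop = list(family = "exponential", rate = 0.05),
                          Pivot = list(family = "exponential", rate = 0.1),
                          Reverse = list(family = "instant")))
  net <- prune_transition_network(m, 0.2)
  expect_true(all(net$prob > 0.2))
  # the 1/3 edges survive at the default threshold
  expect_equal(sum(net$from == "Glide"), 3)
  # an edge at exactly the threshold is pruned
  expect_false(any(net$from == "Stop" & net$to == "Pivot"))
  expect_equal(nrow(prune_transition_network(m, 1)), 0)
  expect_equal(m$embedded, emb)  # untouched
})

test_that("periodicity detection finds oscillations and rejects noise", {
  t <- 0:599
  sine <- sin(2 * pi * t / 23)
  expect_lt(abs(detect_periodicity(sine, dt = 1) - 23), 1.01)

  set.seed(4)
  expect_true(is.na(detect_periodicity(rnorm(600), dt = 1)))

  # reversal periodicity of the lognormal-dwell profile: acf period matches
  # a brute-force reversal-interval histogram (~2x median dwell)
  gt <- ground_truth("species_like_periodic_reverser", n_tracks = 20,
                     duration = 600, seed = 77, sigma_loc = 0,
                     sigma_or = 0, pi_ambiguity = FALSE)
  trs <- generate_tracks(gt)
  v_list <- lapply(trs, function(tr) compute_kinematics(tr)$v_par)
  per <- detect_periodicity(v_list, dt = 1, max_lag = 100)
  intervals <- unlist(lapply(trs, function(tr) {
    soj <- attr(tr, "hidden")$sojourns
    diff(soj$t[soj$state == "Reverse"])
  }))
  # one full velocity cycle spans two reversals
  brute <- 2 * median(intervals)
  expect_false(is.na(per))
  expect_lt(abs(per - brute) / brute, 0.35)
  expect_gt(per, 15)
  expect_lt(per, 35)
})

test_that("rate estimation error decreases with sample size", {
  Q <- matrix(0, 4, 4, dimnames = list(DG_STATES_test(), DG_STATES_test()))
  Q["Glide", c("Stop", "Pivot", "Reverse")] <- c(0.02, 0.01, 0.03)
  Q["Stop", c("Glide", "Pivot")] <- c(0.05, 0.01)
  Q["Pivot", c("Glide", "Stop")] <- c(0.08, 0.02)
  Q["Reverse", "Glide"] <- 0.2
  diag(Q) <- -rowSums(Q)
  m <- transition_model(Q = Q)
  free <- which(Q > 0 & row(Q) != col(Q))
  err_at <- function(n_frames) {
    med <- vapply(1:5, function(s) {
      seqs <- list(simulate_state_sequence(m, n_frames, seed = 7000 + s))
      est <- estimate_transition_model(seqs, dt = 1, method = "counts")
      median(abs(est$Q[free] - Q[free]) / Q[free])
    }, numeric(1))
    median(med)
  }
  errs <- vapply(c(1e3, 1e4, 1e5, 1e6), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})
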