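test_that("velocity preprocessing denoises while preserving sign changes", {
  cst <- rep(3, 50)
  expect_equal(preprocess_velocity(cst), cst)

  spike <- rep(2, 31); spike[15] <- 40
  expect_lt(max(abs(preprocess_velocity(spike) - 2)), 1e-9 + 40 * 0)

  # square wave: zero crossings preserved within +-2 frames
  sq <- rep(rep(c(2, -2), each = 20), 4)
  vt <- preprocess_velocity(sq)
  true_cross <- which(diff(sign(sq)) != 0)
  est_cross <- which(diff(sign(vt)) != 0)
  for (tc in true_cross)
    expect_true(any(abs(est_cross - tc) <= 2))

  expect_error(preprocess_velocity(rep(1, 4)), "shorter than 5")
  expect_error(preprocess_velocity(rep(1, 6), median_window = 7),
               "window larger")
})

test_that("state labels partition frames exhaustively and exclusively", {
  n <- 60
  st <- classify_states(rep(5, n), rep(0, n), v_stop = 1, omega_pivot = 0.1)
  expect_true(all(st$label == "Glide"))
  expect_true(all(st$polarity == 1))

  st2 <- classify_states(rep(0, n), rep(0.4, n), v_stop = 1,
                         omega_pivot = 0.2)
  expect_true(all(st2$label == "Pivot"))

  st3 <- classify_states(rep(0, n), rep(0.01, n), v_stop = 1,
                         omega_pivot = 0.2)
  expect_true(all(st3$label == "Stop"))

  expect_error(classify_states(c(rep(1, 10), NA), rep(0, 11), 1, 0.1),
               "non-finite")
})

test_that("reversals are detected as persistent sign flips and flip polarity", {
  v <- c(rep(4, 20), rep(-4, 20), rep(4, 20))
  st <- classify_states(v, rep(0, 60), v_stop = 1, omega_pivot = 0.1)
  rev_frames <- which(st$label == "Reverse")
  expect_length(rle(st$label[rev_frames] == "Reverse")$lengths, 1 * 2 - 1)
  expect_true(all(abs(rev_frames - c(21, 41)) <= 2))
  expect_equal(unique(st$polarity[1:19]), 1L)
  expect_equal(unique(st$polarity[25:39]), -1L)
  expect_equal(unique(st$polarity[45:60]), 1L)
  # polarity reconstructible from Reverse frames alone
  expect_equal(polarity_from_labels(st$label), st$polarity)

  # sign flips inside a stop are not reversals
  v2 <- c(rep(4, 10), rep(0.01 * c(1, -1), 15), rep(4, 10))
  st2 <- classify_states(v2, rep(0, 50), v_stop = 1, omega_pivot = 0.1)
  expect_false(any(st2$label == "Reverse"))
})

test_that("classification recovers a known state schedule at high SNR", {
  gt <- ground_truth("species_like_straight_glider", n_tracks = 25,
                     duration = 600, seed = 33)
  obs <- generate_tracks(gt)
  obs <- lapply(obs, function(tr) {
    tr$theta <- unwrap_orientation(tr$theta)
    tr
  })
  ksl <- lapply(obs, compute_kinematics)
  cls <- classify_dataset(ksl)
  agree <- vapply(seq_along(obs), function(i) {
    h <- attr(obs[[i]], "hidden")$label
    h <- h[-length(h)]
    sel <- h != "Reverse"
    mean((as.character(cls$states[[i]]$label) == h)[sel])
  }, numeric(1))
  expect_gte(median(agree), 0.90)

  # every true reversal flanked by >= 6 s glides is found within +-2 frames
  found <- total <- 0
  for (i in seq_along(obs)) {
    soj <- attr(obs[[i]], "hidden")$sojourns
    lab <- as.character(cls$states[[i]]$label)
    runs <- rle(lab)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    det <- starts[runs$values == "Reverse"]
    ridx <- which(soj$state == "Reverse")
    for (q in ridx) {
      if (q > 1 && q < nrow(soj) &&
          soj$duration[q - 1] >= 6 && soj$duration[q + 1] >= 6) {
        total <- total + 1
        if (length(det) > 0 && any(abs(det - 1 - soj$t[q]) <= 2))
          found <- found + 1
      }
    }
  }
  expect_gte(found / total, 0.95)
})

test_that("occupancy fractions sum to one and match stationary values", {
  lab <- function(x) factor(x, levels = c("Glide", "Stop", "Pivot",
                                          "Reverse"))
  all_glide <- data.frame(label = lab(rep("Glide", 10)),
                          polarity = 1L, v_tilde = 1)
  of <- occupancy_fractions(all_glide)
  expect_equal(unname(of["Glide"]), 1)
  quarters <- data.frame(label = lab(rep(c("Glide", "Stop", "Pivot",
                                           "Reverse"), each = 5)),
                         polarity = 1L, v_tilde = 1)
  expect_equal(unname(occupancy_fractions(quarters)), rep(0.25, 4))
  expect_equal(sum(occupancy_fractions(quarters)), 1, tolerance = 1e-12)

  # CTMC stationary oracle: simulated sequences match within binomial CI
  profs <- fixture_profiles()$species_like_straight_glider
  tf <- stationary_distribution(profs$model)
  seqs <- lapply(1:20, function(i)
    simulate_state_sequence(profs$model, 2000, seed = 100 + i))
  occ <- occupancy_fractions(seqs)
  n_fr <- 20 * 2000
  for (st in c("Glide", "Stop", "Pivot"))
    expect_lt(abs(occ[st] - tf[st]),
              4 * sqrt(tf[st] * (1 - tf[st]) / n_fr) + 0.02)
})

test_that("state region hulls behave over concentration and degeneracy", {
  lab <- function(x) factor(x, levels = c("Glide", "Stop", "Pivot",
                                          "Reverse"))
  mk <- function(n, v_centre, w_centre, spread = 0.05) {
    ks <- data.frame(t = seq_len(n), v_par = rnorm(n, v_centre, spread),
                     v_perp = 0, omega = rnorm(n, w_centre, spread / 5),
                     speed = abs(v_centre), heading = 0)
    ks
  }
  set.seed(8)
  n <- 300
  states <- data.frame(
    label = lab(rep(c("Glide", "Stop", "Pivot", "Reverse"), each = n)),
    polarity = 1L, v_tilde = 0)
  ks <- rbind(mk(n, 8, 0.01), mk(n, 0.05, 0.01), mk(n, 0.05, 2),
              mk(n, 0.5, 0.2))
  hulls <- state_region_hull(list(states), list(ks))
  expect_named(hulls, c("Glide", "Stop", "Pivot", "Reverse"))
  # disjoint supports -> disjoint hull x-ranges for Glide vs Stop
  expect_gt(min(hulls$Glide$hull[, 1]), max(hulls$Stop$hull[, 1]))
  expect_true(all(hulls$Glide$histogram$z >= 0))

  # hull area shrinks with concentration (1/n trend, monotone)
  hull_area <- function(h) {
    xy <- h$hull
    if (nrow(xy) < 3) return(0)
    abs(sum(xy[, 1] * c(xy[-1, 2], xy[1, 2]) -
            xy[, 2] * c(xy[-1, 1], xy[1, 1]))) / 2
  }
  areas <- vapply(c(50, 500, 5000), function(m) {
    med <- vapply(1:10, function(s) {
      set.seed(1000 + s)
      st <- data.frame(label = lab(rep(c("Glide", "Stop", "Pivot",
                                         "Reverse"), each = m)),
                       polarity = 1L, v_tilde = 0)
      kk <- rbind(mk(m, 5, 0.01, spread = 2 / sqrt(m)),
                  mk(m, 0.05, 0.01), mk(m, 0.05, 2), mk(m, 0.5, 0.2))
      hull_area(state_region_hull(list(st), list(kk))$Glide)
    }, numeric(1))
    median(med)
  }, numeric(1))
  expect_true(all(diff(areas) < 0))

  # all points identical -> degenerate hull, no crash
  stc <- data.frame(label = lab(rep(c("Glide", "Stop", "Pivot", "Reverse"),
                                    each = 30)),
                    polarity = 1L, v_tilde = 0)
  ksc <- data.frame(t = 1:120, v_par = rep(c(5, 0, 0, 0.5), each = 30),
                    v_perp = 0, omega = rep(c(0, 0, 2, 0.1), each = 30),
                    speed = 1, heading = 0)
  expect_no_error(state_region_hull(list(stc), list(ksc)))

  expect_error(state_region_hull(list(stc[1:10, , drop = FALSE]),
                                 list(ksc[1:10, ])), "fewer than")
})
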