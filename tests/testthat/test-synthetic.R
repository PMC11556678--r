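test_that("make_anchors reproduces the prescribed correlation structure", {
  # independent structure at large V: off-diagonals shrink
  id <- make_anchors(3, 10000, target_corr = diag(3), seed = 1)
  off <- id$achieved_corr[upper.tri(id$achieved_corr)]
  expect_lt(max(abs(off)), 0.05)
  # a strong prescribed correlation is achieved closely
  c2 <- matrix(c(1, 0.9, 0.9, 1), 2)
  strong <- make_anchors(2, 10000, target_corr = c2, seed = 2)
  expect_lt(abs(strong$achieved_corr[1, 2] - 0.9), 0.03)
  # single condition degenerates cleanly
  one <- make_anchors(1, 50, target_corr = matrix(1, 1, 1), seed = 3)
  expect_equal(one$achieved_corr, matrix(1, 1, 1), ignore_attr = TRUE)
  # achieved_corr really is the sample correlation of the patterns
  made <- make_anchors(4, 200, seed = 4)
  expect_equal(made$achieved_corr, stats::cor(t(made$anchors$patterns)),
               ignore_attr = TRUE)
  expect_error(make_anchors(2, 100, target_corr = matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})

test_that("generators are pure functions of parameters and seed", {
  a1 <- make_anchors(4, 100, seed = 9)
  a2 <- make_anchors(4, 100, seed = 9)
  expect_identical(a1$anchors$patterns, a2$anchors$patterns)
  t1 <- make_trials(a1$anchors, rep(a1$anchors$labels, 3), seed = 5)
  t2 <- make_trials(a1$anchors, rep(a1$anchors$labels, 3), seed = 5)
  expect_identical(t1$patterns, t2$patterns)
  bd <- data.frame(condition = "happy", onset_s = 10, duration_s = 20)
  s1 <- make_timeseries(a1$anchors, bd, n_volumes = 40, seed = 6)
  s2 <- make_timeseries(a1$anchors, bd, n_volumes = 40, seed = 6)
  expect_identical(s1$volumes, s2$volumes)
  blocks <- data.frame(target = "happy", n_steps = 10)
  g1 <- simulate_agent(a1$anchors, blocks, agent_config(seed = 7))
  g2 <- simulate_agent(a1$anchors, blocks, agent_config(seed = 7))
  expect_identical(g1$patterns, g2$patterns)
})

test_that("trials recover anchors in the noise-free and intensity-scaled cases", {
  made <- make_anchors(4, 150, seed = 11)
  a <- made$anchors
  clean <- make_trials(a, a$labels, intensity_schedule = 1, noise_sigma = 0,
                       seed = 1)
  expect_equal(unname(clean$patterns), unname(a$patterns))
  # intensity 2, no noise: perfect correlation, strength 2 vs the anchor
  twice <- make_trials(a, "happy", intensity_schedule = 2, noise_sigma = 0,
                       seed = 1)
  expect_equal(stats::cor(twice$patterns[1, ], a$patterns["happy", ]), 1)
  s <- pattern_strength(twice$patterns[1, ],
                        voxel_pattern(a$patterns["happy", ], "happy"))
  expect_equal(s$strength, 2, tolerance = 1e-10)
  # noisy condition means converge back to the anchors
  noisy <- make_trials(a, rep(a$labels, each = 20), noise_sigma = 0.5,
                       seed = 2)
  for (lab in a$labels) {
    m <- colMeans(noisy$patterns[noisy$labels == lab, ])
    expect_gt(stats::cor(m, a$patterns[lab, ]), 0.95)
  }
  expect_error(make_trials(a, "joyful"), "unknown condition")
})

test_that("the double-gamma HRF has the canonical shape", {
  t <- seq(0, 32, by = 0.1)
  h <- hrf_double_gamma(t)
  expect_equal(max(h), 1, tolerance = 1e-12)
  expect_equal(t[which.max(h)], 5, tolerance = 0.5)   # peak near 5-6 s
  expect_lt(min(h[t > 10 & t < 25]), 0)               # late undershoot
  expect_equal(h[1], 0)
})

test_that("block time series carry the anchor pattern at the HRF peak", {
  made <- make_anchors(3, 120, seed = 13)
  a <- made$anchors
  bd <- data.frame(condition = "happy", onset_s = 20, duration_s = 16)
  ts <- make_timeseries(a, bd, n_volumes = 60, tr_seconds = 2,
                        noise_sigma = 0, seed = 1)
  cfg <- session_config(window_volumes = 4, hemodynamic_delay_volumes = 2,
                        smoothing_alpha = 1)
  # window centred in the block, delay-shifted: volumes 15..18 (0-based 14)
  peak_window <- ts$volumes[15:18, ]
  cms <- estimate_cms(peak_window, ts$baseline_mean, cfg)
  expect_gt(stats::cor(cms$values, a$patterns["happy", ]), 0.999)
  # no blocks: PSC flat at zero without noise
  quiet <- make_timeseries(a, bd[0, ], n_volumes = 20, noise_sigma = 0,
                           seed = 1)
  expect_equal(max(abs(quiet$volumes - 100)), 0)
  expect_error(
    make_timeseries(a, data.frame(condition = c("happy", "sad"),
                                  onset_s = c(0, 10), duration_s = c(16, 8)),
                    n_volumes = 30),
    "overlapping blocks")
})

test_that("the agent navigates toward the instructed anchor", {
  made <- make_anchors(4, 100, seed = 17)
  a <- made$anchors
  # learning_rate 1, no noise: the target anchor from step 1
  blk <- data.frame(target = "sad", n_steps = 5)
  hard <- simulate_agent(a, blk, agent_config(learning_rate = 1,
                                              state_noise_sigma = 0,
                                              emission_sigma = 0))
  expect_equal(unname(hard$patterns[1, ]), unname(a$patterns["sad", ]))
  # learning_rate 0: mixture stationary
  frozen <- simulate_agent(a, blk, agent_config(learning_rate = 0,
                                                state_noise_sigma = 0,
                                                emission_sigma = 0))
  expect_equal(unname(frozen$mixtures),
               matrix(0.25, 5, 4), ignore_attr = TRUE)
  # learning_rate 0.2, no noise: distance to target strictly decreasing
  walk <- simulate_agent(a, data.frame(target = "happy", n_steps = 15),
                         agent_config(learning_rate = 0.2,
                                      state_noise_sigma = 0,
                                      emission_sigma = 0))
  d <- apply(walk$patterns, 1, correlation_distance, a$patterns["happy", ])
  expect_true(all(diff(d) < 0))
  # mixtures stay on the simplex under jitter
  noisy <- simulate_agent(a, data.frame(target = "angry", n_steps = 30),
                          agent_config(state_noise_sigma = 0.1))
  expect_true(all(noisy$mixtures >= -1e-12))
  expect_equal(unname(rowSums(noisy$mixtures)), rep(1, 30), tolerance = 1e-8)
  expect_error(simulate_agent(a, data.frame(target = "joyful", n_steps = 2)),
               "unknown instruction")
})

test_that("condition-mean RDMs recover the true anchor RDM structure", {
  # the parameter-recovery contract at the study conditions, a few seeds
  # (the full 100-seed sweep lives in the acceptance suite)
  for (seed in 1:5) {
    made <- make_anchors(4, 500, seed = seed)
    a <- made$anchors
    true_rdm <- build_rdm(a, "correlation")
    noisy <- make_trials(a, rep(a$labels, each = 20), noise_sigma = 0.5,
                         seed = seed + 100)
    means <- do.call(rbind, lapply(a$labels, function(l) {
      colMeans(noisy$patterns[noisy$labels == l, ])
    }))
    rownames(means) <- a$labels
    est_rdm <- build_rdm(anchor_set(means), "correlation")
    r <- stats::cor(true_rdm$matrix[upper.tri(diag(4))],
                    est_rdm$matrix[upper.tri(diag(4))])
    expect_gt(r, 0.9)
  }
  # and exactly as noise -> 0
  made <- make_anchors(4, 500, seed = 1)
  clean <- make_trials(made$anchors, rep(made$anchors$labels, each = 2),
                       noise_sigma = 0, seed = 1)
  means <- do.call(rbind, lapply(made$anchors$labels, function(l) {
    colMeans(clean$patterns[clean$labels == l, ])
  }))
  rownames(means) <- made$anchors$labels
  expect_equal(build_rdm(anchor_set(means), "correlation")$matrix,
               build_rdm(made$anchors, "correlation")$matrix,
               tolerance = 1e-10)
})
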