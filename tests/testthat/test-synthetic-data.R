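test_that("spike generator is deterministic and respects its contracts", {
  a <- generate_spike_train(10, shape = 4, duration = 100, seed = 123)
  b <- generate_spike_train(10, shape = 4, duration = 100, seed = 123)
  expect_identical(a, b)
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 0 & a <= 100))
  # near-regular train: count near rate x duration, sample CV near 1/sqrt(shape)
  s <- generate_spike_train(10, shape = 1000, duration = 100, seed = 1)
  expect_lt(abs(length(s) - 1000) / 1000, 0.05)
  cv <- stats::sd(diff(s)) / mean(diff(s))
  expect_lt(abs(cv - 1 / sqrt(1000)) / (1 / sqrt(1000)), 0.25)
  # Poisson limit: CV of exponential ISIs is 1
  p <- generate_spike_train(10, shape = 1, duration = 100, seed = 2)
  cv1 <- stats::sd(diff(p)) / mean(diff(p))
  expect_lt(abs(cv1 - 1), 0.1)
  expect_error(generate_spike_train(0.05, 1, duration = 10),
               class = "mazephys_config_error")
})

test_that("gamma renewal statistics converge at long duration", {
  for (shape in c(1, 16)) {
    s <- generate_spike_train(10, shape = shape, duration = 1000,
                              seed = 1000 + shape)
    isis <- diff(s)
    expect_lt(abs(mean(isis) - 0.1) / 0.1, 0.05)
    cv <- stats::sd(isis) / mean(isis)
    expect_lt(abs(cv - 1 / sqrt(shape)) / (1 / sqrt(shape)), 0.05)
  }
})

test_that("refractory period is enforced without biasing the rate", {
  s <- generate_spike_train(20, shape = 1, duration = 200,
                            refractory = 0.005, seed = 9)
  expect_true(all(diff(s) >= 0.005))
  fr <- length(s) / 200
  expect_lt(abs(fr - 20) / 20, 0.1)
})

test_that("LFP pair generator is deterministic with controlled band content", {
  amps <- c(theta = 10, alpha = 1, beta = 1, gamma = 1)
  p1 <- generate_lfp_pair(amps, coupling = 0.5, duration = 10,
                          sampling_rate = 1000, seed = 77)
  p2 <- generate_lfp_pair(amps, coupling = 0.5, duration = 10,
                          sampling_rate = 1000, seed = 77)
  expect_identical(p1$x, p2$x)
  expect_identical(p1$y, p2$y)
  expect_length(p1$x, 10000)
  # dominant theta carrier -> theta has the largest relative power
  clean <- generate_lfp_pair(amps, coupling = 0, duration = 30,
                             sampling_rate = 1000, noise_amplitude = 0.5,
                             line_amplitude = 0, seed = 78)
  bp <- band_power(welch_psd(clean$x, 1000))
  expect_equal(bp$band[which.max(bp$relative_power_pct)], "theta")
  # full coupling with no noise: shared components sample-identical
  full <- generate_lfp_pair(amps, coupling = 1, duration = 5,
                            sampling_rate = 1000, noise_amplitude = 0,
                            line_amplitude = 0, seed = 79)
  expect_equal(full$x, full$y)
  expect_error(
    generate_lfp_pair(amps, coupling = 0, duration = 1, sampling_rate = 1000),
    class = "mazephys_config_error"
  )
  expect_error(
    generate_lfp_pair(amps, coupling = 1.2, duration = 10,
                      sampling_rate = 1000),
    class = "mazephys_config_error"
  )
})

test_that("band carrier amplitudes set component RMS in microvolts", {
  amps <- c(theta = 8, alpha = 0, beta = 0, gamma = 0)
  p <- generate_lfp_pair(amps, coupling = 0, duration = 20,
                         sampling_rate = 1000, noise_amplitude = 0,
                         line_amplitude = 0, seed = 5)
  expect_lt(abs(stats::sd(p$x) - 8) / 8, 0.15)
})

test_that("maze session generator honors the error-probability limits", {
  cfg <- maze_config(c(1, 3, 5, 7))
  # no errors: every run is a permutation of the baited arms
  perfect <- generate_maze_session(6, p_rme = 0, p_wme = 0,
                                   baited = c(1, 3, 5, 7), seed = 1)
  sc <- score_runs(perfect, cfg, run_cols = "run")
  expect_true(all(sc$total == 0))
  expect_true(all(sc$n_entries == 4))
  expect_true(all(sort(perfect$arm[perfect$run == 1]) == c(1, 3, 5, 7)))
  # p_rme = 1: the first entry of every run is unbaited
  forced <- generate_maze_session(10, p_rme = 1, p_wme = 0,
                                  baited = c(1, 3, 5, 7), seed = 2)
  firsts <- forced$arm[forced$entry_index == 1]
  expect_true(all(!(firsts %in% c(1, 3, 5, 7))))
  expect_identical(
    generate_maze_session(5, 0.3, 0.3, c(1, 3, 5, 7), seed = 3),
    generate_maze_session(5, 0.3, 0.3, c(1, 3, 5, 7), seed = 3)
  )
  expect_error(generate_maze_session(5, 0.3, 0.3, baited = c(1, 2, 3, 5)),
               class = "mazephys_config_error")
})

test_that("learning decay produces a non-increasing error trend", {
  cfg <- maze_config(c(1, 3, 5, 7))
  block_means <- matrix(NA_real_, 200, 4)
  for (r in 1:200) {
    ses <- generate_maze_session(12, p_rme = 0.6, p_wme = 0.4,
                                 baited = c(1, 3, 5, 7),
                                 learning_decay = 0.5, seed = 3000 + r)
    sc <- score_runs(ses, cfg, run_cols = "run")
    bl <- block_summaries(sc)
    block_means[r, ] <- bl$total
  }
  m <- colMeans(block_means)
  expect_true(all(diff(m) <= 0))
})

test_that("cohort generation is reproducible with the designed group effects", {
  cfg <- tiny_cohort_config(seed = 17)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$spikes, c2$spikes)
  expect_identical(c1$signals$samples, c2$signals$samples)
  expect_identical(c1$maze, c2$maze)
  expect_identical(c1$manifest, c2$manifest)
  # deaf mPFC firing below control by construction
  u <- summarize_units(c1$spikes[c1$spikes$region == "mpfc", ],
                       min_spikes = 20)
  fr <- u$per_group$firing_rate_mean
  names(fr) <- u$per_group$group
  expect_lt(fr[["deaf"]], fr[["control"]])
  expect_error(cohort_config(n_deaf = 0), class = "mazephys_config_error")
})
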