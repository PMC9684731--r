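test_that("ISIs are consecutive differences and inputs are validated", {
  expect_equal(compute_isis(c(0, 0.1, 0.3)), c(0.1, 0.2))
  train <- seq(0, 100, by = 0.1) # 1001 spikes at 0.1 s spacing
  expect_equal(compute_isis(train), rep(0.1, 1000))
  expect_error(compute_isis(c(0.3, 0.1, 0.5)), class = "mazephys_data_error")
  expect_error(compute_isis(0.5), class = "mazephys_insufficient_data_error")
  expect_error(compute_isis(numeric(0)),
               class = "mazephys_insufficient_data_error")
})

test_that("firing rate is the reciprocal mean ISI", {
  expect_equal(firing_rate(rep(0.1, 50)), 10)
  expect_equal(firing_rate(c(0.1, 0.3)), 5)
  expect_error(firing_rate(numeric(0)),
               class = "mazephys_insufficient_data_error")
  # renewal simulation: exponential ISIs with mean 0.05 s over 100 s
  st <- generate_spike_train(rate = 20, shape = 1, duration = 100, seed = 7)
  fr <- firing_rate(compute_isis(st))
  expect_lt(abs(fr - 20) / 20, 0.1)
})

test_that("dispersion index matches its moment definition and limits", {
  expect_equal(dispersion_index(rep(0.2, 100)), 0)
  # population sd convention: ISIs (0.1, 0.3) -> 0.1^2 / 0.2
  expect_equal(dispersion_index(c(0.1, 0.3)), 0.05)
  # exponential ISIs: sd = mean, so DI = mean
  set.seed(11)
  isis <- stats::rexp(1e4, rate = 5) # mean 0.2 s
  expect_lt(abs(dispersion_index(isis) - mean(isis)) / mean(isis), 0.05)
  expect_error(dispersion_index(0.1),
               class = "mazephys_insufficient_data_error")
})

test_that("dispersion index is permutation-invariant and scales with time", {
  set.seed(3)
  isis <- stats::rgamma(500, 3, 10)
  di <- dispersion_index(isis)
  expect_equal(dispersion_index(sample(isis)), di)
  expect_equal(dispersion_index(isis * 2.5), di * 2.5)
})

test_that("dispersion index approaches mean/shape for gamma ISI trains", {
  for (shape in c(1, 4, 16)) {
    set.seed(100 + shape)
    isis <- stats::rgamma(1e4, shape = shape, rate = shape * 10) # mean 0.1
    expected <- mean(isis) / shape
    expect_lt(abs(dispersion_index(isis) - expected) / expected, 0.1)
  }
})

test_that("asymmetry index separates regular from irregular firing", {
  # all ISIs equal: mode = mean
  expect_equal(asymmetry_index(rep(0.1, 100)), 1)
  # near-regular gamma train: AI close to 1 (mode may fall just above the
  # mean, which is flagged with a warning rather than clamped)
  set.seed(21)
  isis_reg <- stats::rgamma(5e3, shape = 1000, rate = 1000 / 0.1)
  expect_gt(suppressWarnings(asymmetry_index(isis_reg)), 0.9)
  # exponential ISIs: mode at 0, AI of order bin_width/(2 * mean) -> small
  set.seed(22)
  isis_exp <- stats::rexp(2e4, 10) # mean 0.1
  ai <- asymmetry_index(isis_exp, bin_width = 0.002)
  expect_lt(ai, 0.05)
  ai_fine <- asymmetry_index(isis_exp, bin_width = 5e-4)
  expect_lt(ai_fine, 0.03) # within a few bins of the theoretical 0.0025
  expect_error(asymmetry_index(c(0.1, 0.2), bin_width = 0.5),
               class = "mazephys_data_error")
})

test_that("asymmetry index is scale-invariant and increases with regularity", {
  set.seed(31)
  isis <- stats::rgamma(5e3, shape = 4, rate = 40)
  expect_equal(asymmetry_index(isis * 3, bin_width = 0.003),
               asymmetry_index(isis, bin_width = 0.001))
  ais <- vapply(c(1, 4, 16, 64), function(shape) {
    set.seed(500 + shape)
    asymmetry_index(stats::rgamma(5e3, shape = shape, rate = shape * 10))
  }, numeric(1))
  expect_true(all(diff(ais) > 0))
  expect_true(all(ais >= 0 & ais <= 1.05))
})

test_that("unit summaries aggregate per animal and group with exclusions", {
  train <- seq(0.1, 99.9, by = 0.1)
  spikes <- dplyr::bind_rows(
    tibble::tibble(animal_id = "a1", group = "control", region = "mpfc",
                   unit_id = "u1", spike_time_s = train),
    tibble::tibble(animal_id = "a1", group = "control", region = "mpfc",
                   unit_id = "u2", spike_time_s = train),
    tibble::tibble(animal_id = "a2", group = "deaf", region = "mpfc",
                   unit_id = "u3", spike_time_s = train[1:20]) # excluded
  )
  expect_no_warning(s <- summarize_units(spikes))
  expect_equal(nrow(s$excluded), 1)
  expect_equal(s$excluded$unit_id, "u3")
  ctrl <- s$per_group[s$per_group$group == "control", ]
  # two identical units: SEM 0, mean equals the unit statistic
  expect_equal(ctrl$firing_rate_sem, 0)
  expect_equal(ctrl$firing_rate_mean, 10)
  expect_equal(ctrl$n_units, 2L)
  # deaf group disappears entirely (its only unit excluded)
  expect_false("deaf" %in% s$per_group$group)
  # a single-unit group yields an undefined (NA) SEM, not an error
  one <- summarize_units(spikes[spikes$unit_id == "u1", ])
  expect_true(is.na(one$per_group$firing_rate_sem))
})

test_that("isi_stats matches the individual statistic functions", {
  st <- generate_spike_train(8, shape = 3, duration = 60, seed = 5)
  row <- isi_stats(st)
  isis <- compute_isis(st)
  expect_equal(row$firing_rate, firing_rate(isis))
  expect_equal(row$dispersion_index, dispersion_index(isis))
  expect_equal(row$asymmetry_index, asymmetry_index(isis))
  expect_equal(row$n_isi, length(isis))
})
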