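test_that("maze configs enforce arm count and circular adjacency", {
  cfg <- maze_config(c(1, 3, 5, 7))
  expect_equal(cfg$baited, c(1L, 3L, 5L, 7L))
  expect_error(maze_config(c(1, 2, 3, 5)), class = "mazephys_config_error")
  expect_error(maze_config(c(7, 8, 1, 4)), class = "mazephys_config_error")
  expect_silent(maze_config(c(1, 2, 4, 5))) # two adjacent pairs are allowed
  expect_error(maze_config(c(1, 3, 5)), class = "mazephys_config_error")
  expect_error(maze_config(c(1, 3, 5, 9)), class = "mazephys_config_error")
  expect_error(maze_config(c(1, 1, 3, 5)), class = "mazephys_config_error")
})

test_that("run scoring follows the first-visit/revisit rules", {
  cfg <- maze_config(c(1, 3, 5, 7))
  perfect <- score_run(c(1, 3, 5, 7), cfg)
  expect_equal(perfect[c("rme", "wme")], tibble::tibble(rme = 0L, wme = 0L))
  r1 <- score_run(c(2, 1, 1, 3, 5, 7), cfg)
  expect_equal(c(r1$rme, r1$wme), c(1L, 1L))
  # a revisit of an unbaited arm is a WME, not a second RME
  r2 <- score_run(c(2, 2, 1, 3, 5, 7), cfg)
  expect_equal(c(r2$rme, r2$wme), c(1L, 1L))
  expect_error(score_run(c(1, 9), cfg), class = "mazephys_data_error")
  expect_error(score_run(integer(0), cfg), class = "mazephys_data_error")
})

test_that("the baited-only WME reading reassigns unbaited revisits", {
  cfg_b <- maze_config(c(1, 3, 5, 7), wme_scope = "baited")
  r <- score_run(c(2, 2, 1, 1, 3, 5, 7), cfg_b)
  expect_equal(c(r$rme, r$wme), c(2L, 1L)) # both entries of arm 2 are RME
})

test_that("vectorized log scoring agrees with single-run scoring", {
  cfg <- maze_config(c(2, 4, 6, 8))
  set.seed(13)
  logs <- lapply(1:25, function(r) {
    len <- sample(3:10, 1)
    tibble::tibble(animal_id = "a", run = r, entry_index = seq_len(len),
                   arm = sample(8, len, replace = TRUE))
  })
  log <- dplyr::bind_rows(logs)
  vec <- score_runs(log, cfg, run_cols = c("animal_id", "run"))
  for (r in unique(log$run)) {
    single <- score_run(log$arm[log$run == r], cfg)
    expect_equal(vec$rme[vec$run == r], single$rme)
    expect_equal(vec$wme[vec$run == r], single$wme)
  }
})

test_that("block summaries sum runs and flag partial blocks", {
  runs <- tibble::tibble(rme = c(0, 1, 0, 1, 2, 2), wme = c(1, 0, 4, 2, 3, 5),
                         total = c(1, 1, 4, 3, 5, 7))
  bl <- block_summaries(runs)
  expect_equal(bl$total, c(6, 15))
  expect_false(any(bl$partial))
  bl7 <- block_summaries(dplyr::bind_rows(runs, runs[1, ]))
  expect_equal(nrow(bl7), 3)
  expect_true(bl7$partial[3])
  # six perfect runs
  zero <- block_summaries(tibble::tibble(rme = rep(0L, 6), wme = rep(0L, 6),
                                         total = rep(0L, 6)))
  expect_equal(zero$total, c(0, 0))
})

test_that("completion criterion fires at the boundary values", {
  mk <- function(wme, rme) tibble::tibble(wme = wme, rme = rme)
  # 'less than three WME' and 'less than two RME': 2 and 1 qualify
  expect_true(completion_criterion(mk(c(2, 2, 2), c(1, 1, 1)))$met)
  expect_equal(completion_criterion(mk(c(2, 2, 2), c(1, 1, 1)))$at_block, 3)
  expect_false(completion_criterion(mk(c(3, 2, 2), c(1, 1, 1)))$met)
  expect_false(completion_criterion(mk(c(2, 2, 2), c(1, 2, 1)))$met)
  expect_false(completion_criterion(mk(c(2, 2), c(1, 1)))$met)
  # later qualification is found after a failed window
  late <- completion_criterion(mk(c(5, 2, 2, 2), c(0, 0, 0, 0)))
  expect_true(late$met)
  expect_equal(late$at_block, 4)
})

test_that("adding errors can only delay or remove criterion attainment", {
  set.seed(14)
  for (i in 1:50) {
    wme <- sample(0:4, 6, replace = TRUE)
    rme <- sample(0:2, 6, replace = TRUE)
    base <- completion_criterion(tibble::tibble(wme = wme, rme = rme))
    j <- sample(6, 1)
    worse <- tibble::tibble(wme = wme + (seq_len(6) == j), rme = rme)
    after <- completion_criterion(worse)
    if (base$met && after$met) expect_gte(after$at_block, base$at_block)
    if (!base$met) expect_false(after$met)
  }
})

test_that("reversal swaps to the complement and is an involution", {
  cfg <- maze_config(c(1, 3, 5, 7))
  rev1 <- reversal_config(cfg)
  expect_equal(rev1$baited, c(2L, 4L, 6L, 8L))
  expect_equal(rev1$phase, "reversal")
  expect_equal(reversal_config(rev1)$baited, cfg$baited)
  # over all valid training sets: reversal always works, and some reversal
  # sets legitimately violate the training-time adjacency constraint
  sets <- all_valid_baited_sets()
  expect_equal(ncol(sets), 38)
  complement_valid <- apply(sets, 2, function(s) {
    r <- reversal_config(maze_config(s))
    expect_equal(sort(c(r$baited, s)), 1:8)
    mazephys:::valid_baited_set(r$baited)
  })
  expect_true(any(complement_valid))
  expect_false(all(complement_valid))
})

test_that("session tables are tidy, consistent, and reject duplicates", {
  cohort <- generate_cohort(tiny_cohort_config(seed = 23))
  scored <- score_runs(cohort$maze, cohort$baited_sets,
                       run_cols = c("animal_id", "run"))
  scored <- dplyr::left_join(scored, cohort$animals, by = "animal_id")
  tab <- session_table(scored)
  expect_equal(tab$total, tab$rme + tab$wme)
  expect_true(all(tab$total >= 0))
  expect_equal(nrow(tab), dplyr::n_distinct(tab$animal_id) * 4) # 12 runs / 3
  # a run's errors can never exceed its entry count
  expect_true(all(scored$total <= scored$n_entries))
  dup <- dplyr::bind_rows(scored, scored[1, ])
  expect_error(session_table(dup), class = "mazephys_data_error")
})
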