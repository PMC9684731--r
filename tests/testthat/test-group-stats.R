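test_that("Mann-Whitney reproduces exact small-sample results", {
  m <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$u_x, 0)
  expect_equal(m$p_value, 0.1) # 2 of the C(6,3) = 20 labelings are as extreme
  expect_equal(m$method, "exact")
  # identical samples: maximal p, central U
  m2 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(m2$p_value, 1)
  expect_equal(m2$u_x, 8) # n^2 / 2
  expect_error(mann_whitney(numeric(0), 1:3), class = "mazephys_data_error")
  td <- tidy(m)
  expect_true(td$significant == FALSE)
  expect_equal(td$u_statistic + td$u_other, 9)
})

test_that("U statistics conserve and are rank-based", {
  set.seed(19)
  for (i in 1:20) {
    x <- rnorm(sample(3:15, 1))
    y <- rnorm(sample(3:15, 1))
    m <- mann_whitney(x, y)
    expect_equal(m$u_x + m$u_y, length(x) * length(y))
    # invariance under a strictly monotone transform of the pooled data
    mt <- mann_whitney(exp(x), exp(y))
    expect_equal(mt$u_x, m$u_x)
    expect_equal(mt$p_value, m$p_value)
  }
})

test_that("large or tied samples switch to the corrected approximation", {
  set.seed(20)
  big <- mann_whitney(rnorm(50), rnorm(60))
  expect_equal(big$method, "normal_approximation_ties")
  tied <- mann_whitney(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_equal(tied$method, "normal_approximation_ties")
  expect_true(tied$p_value >= 0 && tied$p_value <= 1)
})

test_that("exact p-values agree with a permutation oracle", {
  set.seed(77)
  for (i in 1:6) {
    x <- rnorm(8)
    y <- rnorm(8)
    m <- mann_whitney(x, y)
    expect_equal(m$method, "exact")
    p_mc <- perm_mwu_p(x, y, n_resample = 2e4)
    mc_err <- 4 * sqrt(max(p_mc, 0.01) * (1 - max(p_mc, 0.01)) / 2e4)
    expect_lt(abs(m$p_value - p_mc), mc_err + 0.005)
  }
})

test_that("repeated-measures ANOVA separates group, week, and interaction", {
  set.seed(30)
  weeks <- 1:5
  mk <- function(n, g, offset) {
    tidyr::expand_grid(animal_id = paste0(g, seq_len(n)), week = weeks) |>
      dplyr::mutate(group = g,
                    value = offset + stats::rnorm(dplyr::n(), sd = 0.5))
  }
  d <- dplyr::bind_rows(mk(8, "a", 0), mk(8, "b", 5))
  fit <- rm_anova(d)
  eff <- fit$effects
  expect_setequal(eff$effect, c("group", "week", "group:week"))
  expect_lt(eff$p_value[eff$effect == "group"], 1e-6)
  expect_gt(eff$p_value[eff$effect == "week"], 0.01)
  expect_equal(eff$df_num[eff$effect == "group"], 1)
  expect_equal(eff$df_den[eff$effect == "group"], 14) # animals - groups
  expect_equal(eff$df_num[eff$effect == "week"], 4)
  # post-hoc fires on the significant group effect, Bonferroni inflates p
  expect_false(is.null(fit$posthoc))
  expect_true(all(fit$posthoc$p_adjusted >= fit$posthoc$p_raw - 1e-12))
  expect_true(all(fit$posthoc$significant))
})

test_that("degenerate constant data yields zero F statistics", {
  d <- tidyr::expand_grid(animal_id = paste0("r", 1:6), week = 1:3) |>
    dplyr::mutate(group = rep(c("a", "b"), each = 9), value = 2.5)
  fit <- rm_anova(d)
  expect_equal(fit$effects$statistic, rep(0, 3))
  expect_equal(fit$effects$p_value, rep(1, 3))
})

test_that("one-group designs collapse to one-way RM-ANOVA", {
  set.seed(31)
  mat <- matrix(rnorm(12, mean = rep(c(0, 1, 0.5, 2), each = 3)), nrow = 3)
  d <- tibble::tibble(
    animal_id = rep(paste0("r", 1:3), 4),
    week = rep(1:4, each = 3),
    group = "only",
    value = as.vector(mat)
  )
  fit <- rm_anova(d)
  oracle <- oracle_rm_oneway(mat)
  week <- fit$effects[fit$effects$effect == "week", ]
  expect_equal(week$statistic, oracle$f)
  expect_equal(week$p_value, oracle$p)
  expect_equal(week$df_num, oracle$df1)
  expect_equal(week$df_den, oracle$df2)
})

test_that("unbalanced or incomplete designs are refused", {
  d <- tidyr::expand_grid(animal_id = paste0("r", 1:4), week = 1:3) |>
    dplyr::mutate(group = rep(c("a", "b"), each = 6), value = rnorm(12))
  expect_error(rm_anova(d[-1, ]), class = "mazephys_data_error")
  d2 <- d
  d2$value[3] <- NA
  expect_error(rm_anova(d2), class = "mazephys_data_error")
})

test_that("group-mean imputation fills, logs, and preserves the mean", {
  d <- tibble::tibble(
    animal_id = rep(c("r1", "r2", "r3"), each = 2),
    group = "a",
    week = rep(1:2, 3),
    value = c(2, 5, 4, NA, NA, 7)
  )
  out <- impute_missing_by_group_mean(d)
  log <- imputation_log(out)
  expect_equal(nrow(log), 2)
  expect_equal(out$value[4], 6) # mean of 5 and 7 at week 2
  expect_equal(out$value[5], 3) # mean of 2 and 4 at week 1
  # the group-week means are untouched by imputation
  expect_equal(mean(out$value[out$week == 1]),
               mean(d$value[d$week == 1], na.rm = TRUE))
  # no missing data: unchanged table, empty log
  clean <- impute_missing_by_group_mean(d[1:2, ])
  expect_equal(clean$value, d$value[1:2])
  expect_equal(nrow(imputation_log(clean)), 0)
  # an empty (group, week) cell cannot be imputed
  bad <- tibble::tibble(animal_id = c("r1", "r2"), group = "a",
                        week = c(1, 1), value = c(NA, NA))
  expect_error(impute_missing_by_group_mean(bad),
               class = "mazephys_data_error")
})

test_that("imputation makes attrition-affected cohorts analyzable", {
  cohort <- generate_cohort(tiny_cohort_config(seed = 29))
  rr <- cohort$behavior[cohort$behavior$measure == "rotarod_latency_s", ]
  expect_true(anyNA(rr$value)) # attrition simulated
  filled <- impute_missing_by_group_mean(rr)
  expect_false(anyNA(filled$value))
  expect_gt(nrow(imputation_log(filled)), 0)
  fit <- rm_anova(filled)
  expect_s3_class(fit, "rm_anova")
})
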