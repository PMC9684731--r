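#' Two-sided Mann-Whitney U test
#'
#' Compares two independent samples with the two-sided Mann-Whitney U
#' (Wilcoxon rank-sum) test: the exact null distribution is used when the
#' combined sample size is at most 20 and there are no ties, otherwise the
#' normal approximation with tie correction and continuity correction. The
#' U statistic is reported for both orientations (`u_x + u_y = n_x * n_y`).
#'
#' @param x,y Numeric samples for the two groups (e.g. deaf vs control).
#' @param measure Optional label for the compared measure.
#' @param exact_max_n Combined sample size up to which the exact p-value is
#'   used in the absence of ties (default 20).
#' @return An object of class `mwu` with fields `measure`, `u_x`, `u_y`,
#'   `statistic` (= `u_x`), `p_value`, `method`, `medians`, `n`. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value # exact two-sided 0.1
#' @export
mann_whitney <- function(x, y, measure = NULL, exact_max_n = 20) {
  if (!is.numeric(x) || !is.numeric(y)) abort_data("samples must be numeric")
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) {
    abort_data("both samples must be non-empty")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= exact_max_n && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  u_x <- unname(wt$statistic)
  structure(
    list(measure = measure,
         u_x = u_x, u_y = length(x) * length(y) - u_x,
         statistic = u_x,
         p_value = min(1, unname(wt$p.value)),
         method = if (use_exact) "exact" else "normal_approximation_ties",
         medians = c(x = stats::median(x), y = stats::median(y)),
         n = c(x = length(x), y = length(y))),
    class = "mwu"
  )
}

#' @export
print.mwu <- function(x, ...) {
  cat("Mann-Whitney U", if (!is.null(x$measure)) paste0("[", x$measure, "]"),
      sprintf("\n  U = %g (n = %d vs %d), two-sided p = %.4g [%s]\n",
              x$u_x, x$n[["x"]], x$n[["y"]], x$p_value, x$method),
      sprintf("  medians: %.4g vs %.4g\n",
              x$medians[["x"]], x$medians[["y"]]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mwu <- function(x, ...) {
  tibble::tibble(
    measure = x$measure %||% NA_character_,
    u_statistic = x$u_x, u_other = x$u_y,
    p_value = x$p_value, method = x$method,
    median_x = x$medians[["x"]], median_y = x$medians[["y"]],
    n_x = x$n[["x"]], n_y = x$n[["y"]],
    significant = x$p_value < 0.05
  )
}

#' @export
glance.mwu <- function(x, ...) tidy(x)[c("u_statistic", "p_value", "method")]

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-way repeated-measures ANOVA with Bonferroni post-hoc tests
#'
#' Split-plot ANOVA with one between-subject factor (`group`) and one
#' within-subject factor (`week`): the group effect is tested against the
#' between-animal stratum and the week and group x week effects against the
#' within-animal residual (uncorrected degrees of freedom; a
#' Greenhouse-Geisser-style correction is deliberately not applied by
#' default). When the group or interaction effect reaches p < 0.05 —
#' or `posthoc = "always"` is set, the explicit override mirroring post-hoc
#' testing after a mere trend — pairwise group comparisons are run per week
#' as pooled-variance t-tests with Bonferroni adjustment across weeks.
#'
#' The design must be balanced: every animal needs exactly one value per
#' week (impute first, see [impute_missing_by_group_mean()]). With a single
#' group the model collapses to a one-way repeated-measures ANOVA (week
#' effect only).
#'
#' @param data A long-format data frame.
#' @param value,group,week,animal Column specifications (tidy-eval; default
#'   to columns named `value`, `group`, `week`, `animal_id`).
#' @param posthoc `"auto"` (default: only after a significant group or
#'   interaction effect) or `"always"`.
#' @return An object of class `rm_anova` with `effects` (tibble: `effect`,
#'   `df_num`, `df_den`, `statistic`, `p_value`) and `posthoc` (tibble or
#'   `NULL`). Supports [generics::tidy()] and [generics::glance()].
#' @export
rm_anova <- function(data, value = value, group = group, week = week,
                     animal = animal_id, posthoc = c("auto", "always")) {
  posthoc <- match.arg(posthoc)
  d <- dplyr::transmute(
    data,
    value = {{ value }},
    group = as.factor({{ group }}),
    week = as.factor({{ week }}),
    animal = as.factor({{ animal }})
  )
  if (anyNA(d$value)) {
    abort_data("missing values present; impute first (impute_missing_by_group_mean)")
  }
  tab <- table(d$animal, d$week)
  if (any(tab != 1L)) {
    abort_data("unbalanced design: each animal needs exactly one value per week")
  }
  one_group <- nlevels(d$group) < 2L
  if (stats::var(d$value) == 0) { # degenerate constant data: no effects
    n_animal <- nlevels(d$animal)
    n_week <- nlevels(d$week)
    n_group <- nlevels(d$group)
    effects <- tibble::tibble(
      effect = if (one_group) "week" else c("group", "week", "group:week"),
      df_num = if (one_group) n_week - 1 else
        c(n_group - 1, n_week - 1, (n_group - 1) * (n_week - 1)),
      df_den = if (one_group) (n_animal - 1) * (n_week - 1) else
        c(n_animal - n_group, rep((n_animal - n_group) * (n_week - 1), 2)),
      statistic = 0, p_value = 1
    )
    return(structure(list(effects = effects, posthoc = NULL,
                          one_group = one_group), class = "rm_anova"))
  }
  fit <- if (one_group) {
    stats::aov(value ~ week + Error(animal), data = d)
  } else {
    stats::aov(value ~ group * week + Error(animal), data = d)
  }
  effects <- extract_aov_effects(fit)

  ph <- NULL
  run_ph <- !one_group && (posthoc == "always" || any(
    effects$p_value[effects$effect %in% c("group", "group:week")] < 0.05,
    na.rm = TRUE
  ))
  if (run_ph) {
    weeks <- levels(d$week)
    gl <- levels(d$group)
    rows <- lapply(weeks, function(w) {
      a <- d$value[d$week == w & d$group == gl[1]]
      b <- d$value[d$week == w & d$group == gl[2]]
      tt <- stats::t.test(a, b, var.equal = TRUE)
      tibble::tibble(week = w, groups = paste(gl[1], "vs", gl[2]),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p_raw = tt$p.value)
    })
    ph <- dplyr::bind_rows(rows)
    ph$p_adjusted <- pmin(1, stats::p.adjust(ph$p_raw, method = "bonferroni"))
    ph$significant <- ph$p_adjusted < 0.05
  }
  structure(list(effects = effects, posthoc = ph, one_group = one_group),
            class = "rm_anova")
}

extract_aov_effects <- function(fit) {
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    t <- stratum[[1]]
    terms <- trimws(rownames(t))
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") next
      f <- t[i, "F value"]
      p <- t[i, "Pr(>F)"]
      if (t[i, "Sum Sq"] == 0) { # degenerate zero-variance data: no effect
        f <- 0
        p <- 1
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        effect = terms[i],
        df_num = t[i, "Df"],
        df_den = t[nrow(t), "Df"],
        statistic = f,
        p_value = p
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA\n")
  print(x$effects)
  if (!is.null(x$posthoc)) {
    cat("\nBonferroni post-hoc (per week):\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) x$effects

#' @export
glance.rm_anova <- function(x, ...) {
  g <- x$effects[x$effects$effect == "group", ]
  i <- x$effects[x$effects$effect == "group:week", ]
  tibble::tibble(
    f_group = if (nrow(g)) g$statistic else NA_real_,
    p_group = if (nrow(g)) g$p_value else NA_real_,
    f_interaction = if (nrow(i)) i$statistic else NA_real_,
    p_interaction = if (nrow(i)) i$p_value else NA_real_,
    n_posthoc_significant = if (is.null(x$posthoc)) 0L else
      sum(x$posthoc$significant)
  )
}

#' Replace missing values by the group mean
#'
#' The study's missing-data rule for repeated behavioral measures: a missing
#' cell (animal lost from a given week onward) is replaced by the mean of
#' the observed values of the same group at that week. Every imputed cell is
#' logged; the log is attached as attribute `"imputation_log"` and
#' retrievable with [imputation_log()]. Imputation leaves each (group, week)
#' mean unchanged.
#'
#' @inheritParams rm_anova
#' @return The completed tibble (same columns as `data`, `value` filled).
#' @export
impute_missing_by_group_mean <- function(data, value = value, group = group,
                                         week = week, animal = animal_id) {
  val_q <- rlang::enquo(value)
  val_name <- rlang::as_name(val_q)
  d <- dplyr::mutate(
    data,
    .value = {{ value }}, .group = {{ group }}, .week = {{ week }},
    .animal = {{ animal }}
  )
  d <- dplyr::group_by(d, .data$.group, .data$.week)
  d <- dplyr::mutate(d, .gw_mean = mean(.data$.value, na.rm = TRUE),
                     .n_obs = sum(!is.na(.data$.value)))
  d <- dplyr::ungroup(d)
  miss <- is.na(d$.value)
  if (any(miss & d$.n_obs == 0L)) {
    abort_data("a (group, week) cell has no observed values to impute from")
  }
  log <- tibble::tibble(
    animal_id = d$.animal[miss], group = d$.group[miss],
    week = d$.week[miss], imputed_value = d$.gw_mean[miss]
  )
  d$.value[miss] <- d$.gw_mean[miss]
  out <- data
  out[[val_name]] <- d$.value
  out <- tibble::as_tibble(out)
  attr(out, "imputation_log") <- log
  out
}

#' @rdname impute_missing_by_group_mean
#' @param x A tibble returned by [impute_missing_by_group_mean()].
#' @export
imputation_log <- function(x) {
  attr(x, "imputation_log") %||%
    tibble::tibble(animal_id = character(), group = character(),
                   week = numeric(), imputed_value = numeric())
}
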