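#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end orchestration: generate (or accept) a cohort, compute per-unit
#' spike statistics with per-region deaf-vs-control Mann-Whitney tests,
#' artifact-screen/filter/Welch-analyze every field-potential trace into
#' relative band powers with per-channel-and-band group tests, estimate
#' band coherence for both region pairs with group tests, score the maze
#' logs into block totals with a group x block repeated-measures ANOVA, and
#' run the weekly behavioral ANOVAs (with group-mean imputation when animals
#' drop out). Returns every table; optionally writes them as CSV together
#' with a JSON run manifest.
#'
#' @param config A [cohort_config()], a path to a YAML config, or a `cohort`
#'   object already generated.
#' @param out_dir Optional output directory for CSV tables and
#'   `manifest.json`.
#' @param artifact_threshold_uv Amplitude threshold for artifact rejection,
#'   microvolts (default 400; generously above the synthetic signal range so
#'   clean traces survive whole).
#' @param denominator_range Reference interval for relative power, Hz.
#' @return A list of class `cohort_analysis` with elements `unit_stats`
#'   (`unit_summary`), `unit_tests`, `band_power`, `band_power_tests`,
#'   `coherence`, `coherence_tests`, `maze_blocks`, `maze_anova`,
#'   `behavior_anovas`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         artifact_threshold_uv = 400,
                         denominator_range = c(1, 100)) {
  cohort <- if (inherits(config, "cohort")) config else {
    if (is.character(config)) config <- read_cohort_config(config)
    generate_cohort(config)
  }

  # --- single units -------------------------------------------------------
  units <- summarize_units(cohort$spikes)
  unit_tests <- unit_group_tests(units$per_unit)

  # --- spectral preprocessing (each trace filtered once) ------------------
  sig <- cohort$signals
  sig$filtered <- lapply(seq_len(nrow(sig)), function(i) {
    apply_filters(sig$samples[[i]], sig$sampling_rate[i])
  })

  # --- spectral band power ------------------------------------------------
  bp <- analyze_band_power(sig, artifact_threshold_uv, denominator_range)
  bp_tests <- measure_group_tests(bp, c("channel", "band"),
                                  "relative_power_pct")

  # --- coherence ----------------------------------------------------------
  coh <- analyze_coherence(sig)
  coh_tests <- measure_group_tests(coh, c("pair", "band"), "mean_coherence")

  # --- maze ---------------------------------------------------------------
  scored <- score_runs(cohort$maze, cohort$baited_sets,
                       run_cols = c("animal_id", "run"))
  scored <- dplyr::left_join(scored, cohort$animals, by = "animal_id")
  maze_blocks <- session_table(scored)
  maze_anova <- rm_anova(maze_blocks, value = total, group = group,
                         week = block, animal = animal_id,
                         posthoc = "always")

  # --- weekly behavior ----------------------------------------------------
  behavior_anovas <- lapply(
    split(cohort$behavior, cohort$behavior$measure),
    function(b) {
      b <- impute_missing_by_group_mean(b)
      rm_anova(b)
    }
  )

  result <- structure(
    list(unit_stats = units, unit_tests = unit_tests,
         band_power = bp, band_power_tests = bp_tests,
         coherence = coh, coherence_tests = coh_tests,
         maze_blocks = maze_blocks, maze_anova = maze_anova,
         behavior_anovas = behavior_anovas,
         manifest = cohort$manifest),
    class = "cohort_analysis"
  )
  if (!is.null(out_dir)) write_analysis(result, out_dir)
  result
}

# deaf-vs-control Mann-Whitney per region for FR, DI, AI (pooled units)
unit_group_tests <- function(per_unit) {
  stats_long <- tidyr::pivot_longer(
    per_unit,
    cols = c("firing_rate", "dispersion_index", "asymmetry_index"),
    names_to = "measure", values_to = "value"
  )
  measure_group_tests(stats_long, c("region", "measure"), "value")
}

# Mann-Whitney deaf vs control within every combination of `keys`
measure_group_tests <- function(data, keys, value_col) {
  keys <- intersect(keys, names(data))
  combos <- dplyr::distinct(data[keys])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- rep(TRUE, nrow(data))
    for (k in keys) sel <- sel & data[[k]] == combos[[k]][i]
    d <- data[sel, ]
    m <- mann_whitney(d[[value_col]][d$group == "deaf"],
                      d[[value_col]][d$group == "control"],
                      measure = paste(unlist(combos[i, ]), collapse = "/"))
    out <- tidy(m)
    out$measure <- NULL # the key columns already identify the contrast
    out$direction <- ifelse(out$median_x < out$median_y, "deaf_lower",
                            "deaf_higher")
    dplyr::bind_cols(combos[i, ], out)
  })
  dplyr::bind_rows(rows)
}

# per-animal, per-channel relative band power table (filtered traces in)
analyze_band_power <- function(sig, threshold_uv, denominator_range,
                               bands = canonical_bands()) {
  # SMCtx is recorded once per pair; analyze its power from the mPFC pair
  keep <- sig$channel != "smctx_ecog" | sig$pair == "mpfc_smctx"
  sig <- sig[keep, ]
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    screen <- reject_artifacts(sig$filtered[[i]], sig$sampling_rate[i],
                               threshold_uv)
    psd <- welch_psd(screen)
    bp <- band_power(psd, bands = bands,
                     denominator_range = denominator_range)
    dplyr::bind_cols(
      tibble::tibble(animal_id = sig$animal_id[i], group = sig$group[i],
                     channel = sig$channel[i])[rep(1, nrow(bp)), ],
      bp
    )
  })
  dplyr::bind_rows(rows)
}

# per-animal, per-pair band coherence table (filtered traces in)
analyze_coherence <- function(sig, bands = canonical_bands()) {
  pairs <- dplyr::distinct(sig[c("animal_id", "group", "pair")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sel <- sig$animal_id == pairs$animal_id[i] & sig$pair == pairs$pair[i]
    d <- sig[sel, ]
    lfp <- d$filtered[[which(d$channel != "smctx_ecog")]]
    ecog <- d$filtered[[which(d$channel == "smctx_ecog")]]
    cs <- msc(lfp, ecog, sampling_rate = d$sampling_rate[1])
    bc <- band_coherence(cs, bands = bands)
    dplyr::bind_cols(pairs[rep(i, nrow(bc)), ], bc)
  })
  dplyr::bind_rows(rows)
}

#' Key deaf-vs-control contrasts of a cohort
#'
#' Computes, from a generated cohort, the deaf-vs-control contrasts the
#' study reports as significant — mPFC firing rate (down) and dispersion
#' index (up); theta relative power in mPFC, IC and SMCtx (down); mPFC-SMCtx
#' theta coherence (down) and gamma coherence (up) — each with its two-sided
#' Mann-Whitney p-value and observed direction. Used for parameter-recovery
#' checks: with the generator's default effect sizes every contrast should
#' come out in the stated direction and significant.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param artifact_threshold_uv Amplitude threshold for artifact screening.
#' @return A tibble with columns `contrast`, `expected_direction`,
#'   `direction`, `p_value`, `recovered`.
#' @export
cohort_contrasts <- function(cohort, artifact_threshold_uv = 400) {
  if (!inherits(cohort, "cohort")) {
    abort_config("`cohort` must come from generate_cohort()")
  }
  units <- summarize_units(cohort$spikes[cohort$spikes$region == "mpfc", ])
  ut <- unit_group_tests(units$per_unit)

  sig <- cohort$signals
  # only the mPFC-pair traces and the IC LFP enter these contrasts
  sig <- sig[sig$pair == "mpfc_smctx" | sig$channel == "ic_lfp", ]
  sig$filtered <- lapply(seq_len(nrow(sig)), function(i) {
    apply_filters(sig$samples[[i]], sig$sampling_rate[i])
  })
  bp <- analyze_band_power(sig, artifact_threshold_uv, c(1, 100))
  bpt <- measure_group_tests(bp[bp$band == "theta", ], "channel",
                             "relative_power_pct")
  coh <- analyze_coherence(sig[sig$pair == "mpfc_smctx", ])
  cht <- measure_group_tests(coh[coh$band %in% c("theta", "gamma"), ],
                             "band", "mean_coherence")

  pick <- function(df, sel, name, expected) {
    row <- df[sel, ]
    tibble::tibble(contrast = name, expected_direction = expected,
                   direction = row$direction, p_value = row$p_value)
  }
  out <- dplyr::bind_rows(
    pick(ut, ut$measure == "firing_rate", "mpfc_firing_rate", "deaf_lower"),
    pick(ut, ut$measure == "dispersion_index", "mpfc_dispersion_index",
         "deaf_higher"),
    pick(bpt, bpt$channel == "mpfc_lfp", "mpfc_theta_rel_power", "deaf_lower"),
    pick(bpt, bpt$channel == "ic_lfp", "ic_theta_rel_power", "deaf_lower"),
    pick(bpt, bpt$channel == "smctx_ecog", "smctx_theta_rel_power",
         "deaf_lower"),
    pick(cht, cht$band == "theta", "mpfc_smctx_theta_coherence", "deaf_lower"),
    pick(cht, cht$band == "gamma", "mpfc_smctx_gamma_coherence", "deaf_higher")
  )
  out$recovered <- out$direction == out$expected_direction & out$p_value < 0.05
  out
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>\n")
  cat("  unit tests:\n")
  print(x$unit_tests[c("region", "measure", "u_statistic", "p_value",
                       "direction")])
  cat("  band power tests (p < 0.05):\n")
  sig <- x$band_power_tests[x$band_power_tests$significant, ]
  print(sig[c("channel", "band", "p_value", "direction")])
  cat("  coherence tests (p < 0.05):\n")
  sig <- x$coherence_tests[x$coherence_tests$significant, ]
  print(sig[c("pair", "band", "p_value", "direction")])
  invisible(x)
}

# write all result tables + manifest to a directory
write_analysis <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wr(result$unit_stats$per_unit, "unit_stats")
  wr(result$unit_stats$per_group, "unit_group_summary")
  wr(result$unit_tests, "unit_tests")
  wr(result$band_power, "band_power")
  wr(result$band_power_tests, "band_power_tests")
  wr(result$coherence, "band_coherence")
  wr(result$coherence_tests, "band_coherence_tests")
  wr(result$maze_blocks, "maze_blocks")
  wr(tidy(result$maze_anova), "maze_anova")
  behav <- dplyr::bind_rows(
    lapply(names(result$behavior_anovas), function(m) {
      dplyr::bind_cols(tibble::tibble(measure = m),
                       tidy(result$behavior_anovas[[m]]))
    })
  )
  wr(behav, "behavior_anovas")
  manifest <- result$manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
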