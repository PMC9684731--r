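#' Configuration for a synthetic deafened-rat cohort
#'
#' Bundles every parameter of the synthetic cohort: group sizes, recording
#' epoch, per-region spike-train parameters, per-channel field-potential band
#' amplitudes, per-pair band coupling, maze error probabilities and the
#' weekly behavioral summary measures. Defaults encode the study conditions:
#' 10 deaf vs 13 control animals, 100 s epochs at 1 kHz, unit counts per
#' animal near the reported per-rat averages, and group effects pointing in
#' the directions reported for deaf animals (lower mPFC firing rate, higher
#' dispersion, lower theta power in all channels, lower gamma power in IC and
#' SMCtx, lower mPFC-SMCtx theta coupling, higher gamma coupling, higher
#' IC-SMCtx alpha/beta/gamma coupling, more maze errors early in training).
#' Effect magnitudes are generator choices, not estimates from data.
#'
#' @param n_deaf,n_control Group sizes (>= 1).
#' @param seed Integer seed for the whole cohort.
#' @param epoch_duration Recording epoch length, seconds.
#' @param sampling_rate Field-potential sampling rate, Hz.
#' @param units_per_animal Named list `region -> c(control =, deaf =)` mean
#'   unit counts per animal (realized counts are Poisson around these).
#' @param spike_params Named list `region -> group -> list(rate, shape)`.
#' @param refractory Absolute refractory period for spike generation, s.
#' @param lfp_params Named list `channel -> group -> named amplitude vector`
#'   (microvolt RMS per band).
#' @param coupling Named list `pair -> group -> named per-band coupling`.
#' @param noise_amplitude,noise_exponent,line_amplitude Background noise and
#'   50 Hz line parameters shared by all channels.
#' @param maze Named list `group -> list(n_runs, p_rme, p_wme,
#'   learning_decay)`.
#' @param behavior_weeks Weeks of behavioral testing (0 = pre-surgery).
#' @param attrition Simulate the study's drop-out pattern (two deaf animals
#'   and one control lose behavioral data from a mid-study week onward);
#'   downstream analysis then exercises group-mean imputation.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_deaf = 10, n_control = 13, seed = 1,
                          epoch_duration = 100, sampling_rate = 1000,
                          units_per_animal = list(
                            mpfc = c(control = 47, deaf = 66),
                            ic   = c(control = 33, deaf = 44)
                          ),
                          spike_params = list(
                            mpfc = list(control = list(rate = 7.5, shape = 4),
                                        deaf    = list(rate = 4.5, shape = 2)),
                            ic   = list(control = list(rate = 10,  shape = 3),
                                        deaf    = list(rate = 9.8, shape = 3))
                          ),
                          refractory = 0.002,
                          lfp_params = list(
                            mpfc_lfp = list(
                              control = c(theta = 12, alpha = 8, beta = 7, gamma = 5),
                              deaf    = c(theta = 7,  alpha = 8, beta = 7, gamma = 5)),
                            ic_lfp = list(
                              control = c(theta = 12, alpha = 8, beta = 7, gamma = 5),
                              deaf    = c(theta = 7,  alpha = 8, beta = 7, gamma = 3)),
                            smctx_ecog = list(
                              control = c(theta = 12, alpha = 8, beta = 7, gamma = 5),
                              deaf    = c(theta = 7,  alpha = 10, beta = 5, gamma = 3.5))
                          ),
                          coupling = list(
                            mpfc_smctx = list(
                              control = c(theta = 0.7, alpha = 0.35, beta = 0.35, gamma = 0.25),
                              deaf    = c(theta = 0.35, alpha = 0.35, beta = 0.35, gamma = 0.55)),
                            ic_smctx = list(
                              control = c(theta = 0.5, alpha = 0.3, beta = 0.3, gamma = 0.25),
                              deaf    = c(theta = 0.5, alpha = 0.55, beta = 0.55, gamma = 0.55))
                          ),
                          noise_amplitude = 6, noise_exponent = 1,
                          line_amplitude = 2,
                          maze = list(
                            control = list(n_runs = 24, p_rme = 0.45,
                                           p_wme = 0.25, learning_decay = 0.75),
                            deaf    = list(n_runs = 24, p_rme = 0.60,
                                           p_wme = 0.40, learning_decay = 0.80)
                          ),
                          behavior_weeks = c(0, 1, 2, 4, 8, 16, 24, 32, 40, 48, 56),
                          attrition = TRUE) {
  check_number(n_deaf, "n_deaf", 1)
  check_number(n_control, "n_control", 1)
  check_number(epoch_duration, "epoch_duration", 0, strict_lower = TRUE)
  check_number(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  check_number(seed, "seed")
  structure(
    list(n_deaf = n_deaf, n_control = n_control, seed = as.integer(seed),
         epoch_duration = epoch_duration, sampling_rate = sampling_rate,
         units_per_animal = units_per_animal, spike_params = spike_params,
         refractory = refractory, lfp_params = lfp_params,
         coupling = coupling, noise_amplitude = noise_amplitude,
         noise_exponent = noise_exponent, line_amplitude = line_amplitude,
         maze = maze, behavior_weeks = behavior_weeks,
         attrition = isTRUE(attrition)),
    class = "cohort_config"
  )
}

#' Read a cohort configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [cohort_config()]; absent keys keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort_config(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  # yaml reads named numeric vectors as lists; coerce such leaves back
  # (below the top level, so the argument list itself stays a list)
  renumber <- function(x) {
    if (is.list(x) && length(x) && all(vapply(x, is.numeric, TRUE)) &&
        all(lengths(x) == 1L) && !is.null(names(x))) {
      unlist(x)
    } else if (is.list(x)) lapply(x, renumber) else x
  }
  do.call(cohort_config, lapply(raw, renumber))
}

#' Generate a complete synthetic cohort
#'
#' Draws, for every synthetic animal, per-region spike trains, the two
#' simultaneously recorded field-potential pairs (mPFC-LFP with SMCtx-ECoG
#' and IC-LFP with SMCtx-ECoG; the two pairs are independent recordings, as
#' in a sequential recording protocol), a radial-maze training session, and
#' weekly behavioral summary measures. All group-level parameters and the
#' seed are recorded in the returned manifest, so a cohort is reproducible
#' bit-for-bit from its manifest.
#'
#' Per-animal heterogeneity: firing rates and band amplitudes are jittered
#' across animals by a lognormal factor (sd 0.12 on the log scale) so that
#' animals, not only units, vary.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort` with elements `animals` (tibble:
#'   `animal_id`, `group`), `spikes` (tibble: `animal_id`, `group`, `region`,
#'   `unit_id`, `spike_time_s`), `signals` (tibble: `animal_id`, `group`,
#'   `pair`, `channel`, with list-column `samples`), `maze` (long entry log
#'   with baited sets in `baited` list-column per animal), `behavior` (tibble:
#'   `animal_id`, `group`, `week`, `measure`, `value`) and `manifest` (list).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort_config("`config` must be a cohort_config object")
  }
  groups <- c(rep("deaf", config$n_deaf), rep("control", config$n_control))
  animals <- tibble::tibble(
    animal_id = sprintf("%s_%02d", groups,
                        c(seq_len(config$n_deaf), seq_len(config$n_control))),
    group = groups
  )

  spikes <- list()
  signals <- list()
  maze <- list()
  baited_sets <- list()

  for (i in seq_len(nrow(animals))) {
    id <- animals$animal_id[i]
    grp <- animals$group[i]
    aseed <- derive_seed(config$seed, i)
    jitter <- withr::with_seed(aseed, exp(stats::rnorm(2, 0, 0.12)))

    # --- spike trains per region
    k <- 0
    for (region in names(config$spike_params)) {
      k <- k + 1
      pars <- config$spike_params[[region]][[grp]]
      trains <- withr::with_seed(derive_seed(aseed, 1000 * k), {
        n_units <- max(1L, stats::rpois(1, config$units_per_animal[[region]][[grp]]))
        lapply(seq_len(n_units), function(u) {
          urate <- pars[["rate"]] * jitter[1] * exp(stats::rnorm(1, 0, 0.2))
          generate_spike_train(
            rate = urate, shape = pars[["shape"]],
            duration = config$epoch_duration,
            refractory = config$refractory, seed = NULL
          )
        })
      })
      lens <- lengths(trains)
      spikes[[length(spikes) + 1]] <- tibble::tibble(
        animal_id = id, group = grp, region = region,
        unit_id = rep(sprintf("%s_%s_u%03d", id, region, seq_along(trains)),
                      lens),
        spike_time_s = unlist(trains, use.names = FALSE)
      )
    }

    # --- field-potential pairs
    chan_of <- list(mpfc_smctx = "mpfc_lfp", ic_smctx = "ic_lfp")
    j <- 0
    for (pair in names(config$coupling)) {
      j <- j + 1
      lfp_chan <- chan_of[[pair]]
      # per-animal, per-band amplitude heterogeneity (lognormal, sd 0.1)
      band_jit <- withr::with_seed(derive_seed(aseed, 5100 + j),
                                   exp(stats::rnorm(8, 0, 0.1)))
      amps_lfp <- config$lfp_params[[lfp_chan]][[grp]] * jitter[2] * band_jit[1:4]
      amps_ecog <- config$lfp_params[["smctx_ecog"]][[grp]] * jitter[2] * band_jit[5:8]
      sig <- generate_lfp_pair(
        band_amplitudes = amps_lfp,
        band_amplitudes_y = amps_ecog,
        coupling = config$coupling[[pair]][[grp]],
        duration = config$epoch_duration,
        sampling_rate = config$sampling_rate,
        noise_exponent = config$noise_exponent,
        noise_amplitude = config$noise_amplitude,
        line_amplitude = config$line_amplitude,
        seed = derive_seed(aseed, 5000 + j)
      )
      signals[[length(signals) + 1]] <- tibble::tibble(
        animal_id = id, group = grp, pair = pair,
        channel = c(lfp_chan, "smctx_ecog"),
        samples = list(sig$x, sig$y),
        sampling_rate = config$sampling_rate
      )
    }

    # --- maze session
    baited <- withr::with_seed(derive_seed(aseed, 9000), random_baited_set())
    mz <- config$maze[[grp]]
    session <- generate_maze_session(
      n_runs = mz[["n_runs"]], p_rme = mz[["p_rme"]], p_wme = mz[["p_wme"]],
      baited = baited, learning_decay = mz[["learning_decay"]],
      seed = derive_seed(aseed, 9001)
    )
    maze[[length(maze) + 1]] <- dplyr::bind_cols(
      tibble::tibble(animal_id = id, group = grp)[rep(1, nrow(session)), ],
      session
    )
    baited_sets[[id]] <- baited
  }

  behavior <- generate_behavior_table(animals, config)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mazephys")),
    config = unclass(config),
    n_animals = nrow(animals),
    baited_sets = baited_sets
  )

  structure(
    list(animals = animals,
         spikes = dplyr::bind_rows(spikes),
         signals = dplyr::bind_rows(signals),
         maze = dplyr::bind_rows(maze),
         baited_sets = baited_sets,
         behavior = behavior,
         manifest = manifest),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<synthetic cohort>\n")
  cat("  animals:", nrow(x$animals),
      sprintf("(%d deaf / %d control)\n",
              sum(x$animals$group == "deaf"),
              sum(x$animals$group == "control")))
  cat("  units:", dplyr::n_distinct(x$spikes$unit_id),
      " signal traces:", nrow(x$signals),
      " maze entries:", nrow(x$maze), "\n")
  invisible(x)
}

# draw a valid baited set (4 of 8 arms, no three circularly adjacent)
random_baited_set <- function() {
  repeat {
    cand <- sort(sample(1:8, 4))
    if (valid_baited_set(cand)) return(cand)
  }
}

# weekly behavioral summary measures (schema-level emulation)
generate_behavior_table <- function(animals, config) {
  weeks <- config$behavior_weeks
  rows <- list()
  for (i in seq_len(nrow(animals))) {
    id <- animals$animal_id[i]
    grp <- animals$group[i]
    bseed <- derive_seed(config$seed, 70000 + i)
    vals <- withr::with_seed(bseed, {
      # open field distance (m): no group effect
      of <- stats::rnorm(length(weeks), mean = 28, sd = 4)
      # rotarod latency (s): deaf deficit weeks 1-16, recovering afterwards
      rr_mean <- ifelse(
        grp == "deaf" & weeks >= 1 & weeks <= 16, 70, 90
      )
      rr <- stats::rnorm(length(weeks), mean = rr_mean, sd = 12)
      # social interaction time (s): no group effect
      si <- stats::rnorm(length(weeks), mean = 120, sd = 20)
      list(of = of, rr = rr, si = si)
    })
    rows[[i]] <- tibble::tibble(
      animal_id = id, group = grp,
      week = rep(weeks, 3),
      measure = rep(c("open_field_distance_m", "rotarod_latency_s",
                      "social_interaction_s"), each = length(weeks)),
      value = c(vals$of, vals$rr, vals$si)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (config$attrition) {
    out <- apply_attrition(out, config)
  }
  out
}

# reproduce the study's drop-out pattern: data missing from a week onward
apply_attrition <- function(behavior, config) {
  drops <- list()
  deaf_ids <- unique(behavior$animal_id[behavior$group == "deaf"])
  ctrl_ids <- unique(behavior$animal_id[behavior$group == "control"])
  if (length(deaf_ids) >= 3) {
    drops <- c(drops, list(c(deaf_ids[2], 24), c(deaf_ids[3], 40)))
  }
  if (length(ctrl_ids) >= 2) {
    drops <- c(drops, list(c(ctrl_ids[2], 32)))
  }
  for (d in drops) {
    sel <- behavior$animal_id == d[1] & behavior$week > as.numeric(d[2])
    behavior$value[sel] <- NA_real_
  }
  behavior
}
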