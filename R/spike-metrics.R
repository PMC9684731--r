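#' Inter-spike intervals of a sorted spike train
#'
#' @param spike_times Numeric vector of spike times in seconds, strictly
#'   increasing.
#' @return Numeric vector of ISIs (seconds), length `length(spike_times) - 1`.
#' @examples
#' compute_isis(c(0, 0.1, 0.3))
#' @export
compute_isis <- function(spike_times) {
  if (!is.numeric(spike_times) || anyNA(spike_times)) {
    abort_data("`spike_times` must be a numeric vector without NA")
  }
  if (length(spike_times) < 2L) {
    abort_insufficient("at least 2 spikes are required to form ISIs")
  }
  isis <- diff(spike_times)
  if (any(isis <= 0)) {
    abort_data("`spike_times` must be strictly increasing")
  }
  isis
}

#' Firing rate from inter-spike intervals
#'
#' The reciprocal of the mean ISI over the recording epoch, in Hz.
#'
#' @param isis Numeric vector of ISIs in seconds.
#' @return Firing rate in Hz.
#' @examples
#' firing_rate(rep(0.1, 10)) # 10 Hz
#' @export
firing_rate <- function(isis) {
  if (length(isis) < 1L) abort_insufficient("need at least one ISI")
  if (any(isis <= 0)) abort_data("ISIs must be positive")
  1 / mean(isis)
}

#' Dispersion index of firing
#'
#' Variance of the ISI distribution divided by its mean (units of seconds):
#' `DI = sd(ISI)^2 / mean(ISI)`, with the population (divide-by-n) standard
#' deviation. Higher values indicate more irregular firing; a perfectly
#' regular train has DI = 0.
#'
#' @inheritParams firing_rate
#' @return Dispersion index in seconds.
#' @examples
#' dispersion_index(c(0.1, 0.3)) # 0.05
#' @export
dispersion_index <- function(isis) {
  if (length(isis) < 2L) abort_insufficient("need at least 2 ISIs")
  if (any(isis <= 0)) abort_data("ISIs must be positive")
  pop_sd(isis)^2 / mean(isis)
}

#' Asymmetry index of firing
#'
#' Ratio of the mode to the mean of the ISI distribution. The mode of the
#' continuous ISI distribution is estimated as the center of the most occupied
#' histogram bin (ties broken toward the smallest bin center), with bins of
#' `bin_width` seconds spanning `[0, q99]` where `q99` is the 99th percentile
#' of the ISIs (a guard against a single long interval stretching the grid).
#' Values near 1 indicate regular firing, values near 0 irregular firing. An
#' estimated mode above the mean yields AI > 1; such values are returned
#' as-is with a warning rather than clamped.
#'
#' @inheritParams firing_rate
#' @param bin_width Histogram bin width in seconds (default 1 ms). AI depends
#'   on this choice, which is why it is surfaced.
#' @return Asymmetry index (dimensionless).
#' @examples
#' asymmetry_index(rep(0.1, 100)) # 1: mode equals mean
#' @export
asymmetry_index <- function(isis, bin_width = 0.001) {
  if (length(isis) < 2L) abort_insufficient("need at least 2 ISIs")
  if (any(isis <= 0)) abort_data("ISIs must be positive")
  check_number(bin_width, "bin_width", 0, strict_lower = TRUE)
  rng <- diff(range(isis))
  if (rng == 0) {
    return(1) # single occupied bin: mode equals mean up to half a bin
  }
  if (bin_width >= rng) {
    abort_data("degenerate histogram: `bin_width` is not smaller than the ISI range")
  }
  upper <- stats::quantile(isis, 0.99, names = FALSE)
  kept <- isis[isis <= upper]
  idx <- pmin(floor(kept / bin_width), ceiling(upper / bin_width) - 1) + 1L
  counts <- tabulate(idx)
  mode_isi <- (which.max(counts) - 0.5) * bin_width
  ai <- mode_isi / mean(isis)
  if (ai > 1) {
    rlang::warn("estimated ISI mode exceeds the mean; asymmetry index > 1")
  }
  ai
}

#' Per-unit ISI statistics
#'
#' All single-unit statistics for one spike train: ISI count, mean, population
#' standard deviation, histogram mode, firing rate, dispersion index,
#' asymmetry index and coefficient of variation.
#'
#' @inheritParams compute_isis
#' @inheritParams asymmetry_index
#' @return A one-row tibble.
#' @export
isi_stats <- function(spike_times, bin_width = 0.001) {
  v <- isi_stat_vec(spike_times, bin_width)
  out <- tibble::as_tibble(as.list(v))
  out$n_isi <- as.integer(out$n_isi)
  out$ai_flag <- out$asymmetry_index > 1
  out
}

# numeric-vector core shared by isi_stats() and summarize_units()
isi_stat_vec <- function(spike_times, bin_width) {
  isis <- compute_isis(spike_times)
  m <- mean(isis)
  s <- pop_sd(isis)
  mode_isi <- if (diff(range(isis)) == 0) m else {
    upper <- stats::quantile(isis, 0.99, names = FALSE)
    kept <- isis[isis <= upper]
    idx <- pmin(floor(kept / bin_width), ceiling(upper / bin_width) - 1) + 1L
    (which.max(tabulate(idx)) - 0.5) * bin_width
  }
  c(n_isi = length(isis), mean_isi = m, std_isi = s, mode_isi = mode_isi,
    firing_rate = 1 / m, dispersion_index = s^2 / m,
    asymmetry_index = mode_isi / m, cv = s / m)
}

#' Summarize single units per animal and per group
#'
#' Computes per-unit ISI statistics for every unit in a tidy spike table,
#' excludes units with too few spikes, and aggregates to per-animal means and
#' group mean +/- SEM (units pooled across animals within group, matching the
#' study-level convention of treating units as the unit of analysis).
#'
#' @param spikes A data frame with columns `animal_id`, `unit_id`,
#'   `spike_time_s`, a `group` column, and optionally `region` (any further
#'   grouping column, carried through).
#' @param min_spikes Minimum spikes for a unit to enter the summary
#'   (default 50, i.e. 0.5 Hz over a 100 s epoch). Excluded units are counted
#'   and returned, not silently dropped.
#' @param bin_width Histogram bin width for the asymmetry index, seconds.
#' @return A list of class `unit_summary` with tibbles `per_unit`,
#'   `per_animal`, `per_group` and `excluded`.
#' @export
summarize_units <- function(spikes, min_spikes = 50, bin_width = 0.001) {
  need <- c("animal_id", "unit_id", "spike_time_s", "group")
  if (!is.data.frame(spikes) || !all(need %in% names(spikes))) {
    abort_data("`spikes` must have columns animal_id, unit_id, spike_time_s, group")
  }
  keys <- intersect(c("group", "region", "animal_id", "unit_id"), names(spikes))
  counts <- dplyr::summarise(
    dplyr::group_by(spikes, dplyr::across(dplyr::all_of(keys))),
    n_spikes = dplyr::n(), .groups = "drop"
  )
  excluded <- dplyr::filter(counts, .data$n_spikes < min_spikes)
  kept <- dplyr::filter(counts, .data$n_spikes >= min_spikes)
  if (nrow(kept) == 0L) abort_insufficient("no unit has enough spikes")

  kept_spikes <- spikes |>
    dplyr::semi_join(kept, by = keys) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "spike_time_s"))))
  key_id <- do.call(paste, c(kept_spikes[keys], sep = "\r"))
  trains <- split(kept_spikes$spike_time_s,
                  factor(key_id, levels = unique(key_id)))
  stat_mat <- t(vapply(trains, isi_stat_vec, numeric(8),
                       bin_width = bin_width))
  per_unit <- kept_spikes |>
    dplyr::distinct(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::bind_cols(tibble::as_tibble(stat_mat)) |>
    dplyr::mutate(n_isi = as.integer(.data$n_isi),
                  ai_flag = .data$asymmetry_index > 1)

  stat_cols <- c("firing_rate", "dispersion_index", "asymmetry_index")
  animal_keys <- setdiff(keys, "unit_id")
  per_animal <- per_unit |>
    dplyr::group_by(dplyr::across(dplyr::all_of(animal_keys))) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      dplyr::across(dplyr::all_of(stat_cols), mean),
      .groups = "drop"
    )

  group_keys <- setdiff(animal_keys, "animal_id")
  sem <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
  per_group <- per_unit |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_keys))) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      n_animals = dplyr::n_distinct(.data$animal_id),
      dplyr::across(dplyr::all_of(stat_cols),
                    list(mean = mean, sem = sem)),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      per_animal |>
        dplyr::group_by(dplyr::across(dplyr::all_of(group_keys))) |>
        dplyr::summarise(units_per_animal_mean = mean(.data$n_units),
                         units_per_animal_sem = sem(.data$n_units),
                         .groups = "drop"),
      by = group_keys
    )

  structure(
    list(per_unit = per_unit, per_animal = per_animal,
         per_group = per_group, excluded = excluded),
    class = "unit_summary"
  )
}

#' @export
print.unit_summary <- function(x, ...) {
  cat("<unit_summary>\n")
  cat("  units:", nrow(x$per_unit), " excluded:", nrow(x$excluded), "\n\n")
  print(x$per_group)
  invisible(x)
}
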