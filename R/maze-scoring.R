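#' Radial-maze configuration
#'
#' Validates a 4-arm baited set on the 8-arm maze. Baited sets must contain
#' four distinct arms with not more than two adjacent arms; adjacency is
#' circular (arm 8 neighbours arm 1), so no three circularly consecutive
#' arms may all be baited.
#'
#' @param baited Integer vector of 4 distinct arm indices in `1..n_arms`.
#' @param n_arms Number of arms (default 8).
#' @param phase Session phase: `"training"`, `"retest"` or `"reversal"`.
#' @param wme_scope Which re-entries count as working-memory errors:
#'   `"all"` (default, the literal reading: re-entry into any previously
#'   entered arm) or `"baited"` (only re-entries into baited arms count as
#'   WME; every entry into an unbaited arm then counts as RME).
#' @param check_adjacency Enforce the adjacency constraint (default `TRUE`).
#'   The constraint governs the random choice of training sets; a reversal
#'   set is the complement of the training set and may legitimately violate
#'   it, so [reversal_config()] disables the check.
#' @return A list of class `maze_config`.
#' @examples
#' maze_config(c(1, 3, 5, 7))
#' @export
maze_config <- function(baited, n_arms = 8,
                        phase = c("training", "retest", "reversal"),
                        wme_scope = c("all", "baited"),
                        check_adjacency = TRUE) {
  phase <- match.arg(phase)
  wme_scope <- match.arg(wme_scope)
  check_number(n_arms, "n_arms", 3)
  baited <- as.integer(baited)
  if (length(baited) != 4L || anyDuplicated(baited) ||
      any(baited < 1L | baited > n_arms)) {
    abort_config("`baited` must be 4 distinct arm indices in 1..n_arms")
  }
  if (check_adjacency && !valid_baited_set(baited, n_arms)) {
    abort_config("invalid baited set: three circularly adjacent arms are all baited")
  }
  structure(list(baited = sort(baited), n_arms = as.integer(n_arms),
                 phase = phase, wme_scope = wme_scope),
            class = "maze_config")
}

# TRUE unless some three circularly consecutive arms are all baited
valid_baited_set <- function(baited, n_arms = 8) {
  m <- logical(n_arms)
  m[baited] <- TRUE
  nxt <- function(i) (i %% n_arms) + 1L
  for (i in seq_len(n_arms)) {
    if (m[i] && m[nxt(i)] && m[nxt(nxt(i))]) return(FALSE)
  }
  TRUE
}

#' Score one maze run
#'
#' Reference-memory errors (RME) are first-visit entries into unbaited arms;
#' working-memory errors (WME) are re-entries into any arm already visited
#' earlier in the same run. Each entry contributes to at most one error
#' category: a revisit of an unbaited arm counts as WME, not RME (under the
#' default `wme_scope = "all"`).
#'
#' @param entries Integer vector of arm entries in order.
#' @param config A [maze_config()].
#' @return A one-row tibble with `rme`, `wme`, `total`, `n_entries`.
#' @examples
#' score_run(c(2, 1, 1, 3, 5, 7), maze_config(c(1, 3, 5, 7)))
#' @export
score_run <- function(entries, config) {
  if (!inherits(config, "maze_config")) {
    abort_config("`config` must be a maze_config object")
  }
  entries <- as.integer(entries)
  if (length(entries) == 0L || anyNA(entries) ||
      any(entries < 1L | entries > config$n_arms)) {
    abort_data("`entries` must be non-empty arm indices in 1..n_arms")
  }
  revisit <- duplicated(entries)
  unbaited <- !(entries %in% config$baited)
  if (config$wme_scope == "all") {
    rme <- sum(!revisit & unbaited)
    wme <- sum(revisit)
  } else {
    rme <- sum(unbaited)
    wme <- sum(revisit & !unbaited)
  }
  tibble::tibble(rme = rme, wme = wme, total = rme + wme,
                 n_entries = length(entries))
}

#' Score many maze runs from a long-format entry log
#'
#' Vectorized scorer for tidy maze logs; one output row per run. Runs are
#' identified by the combination of `run_cols` and entries ordered by
#' `entry_index` within run.
#'
#' @param log A data frame with columns `entry_index`, `arm` and the run
#'   identifier columns.
#' @param config A [maze_config()], or a named list
#'   `animal_id -> maze_config` / baited vector when baited sets differ per
#'   animal (the study randomizes them per rat).
#' @param run_cols Columns identifying a run (default
#'   `c("animal_id", "run")`, intersected with the available columns).
#' @return A tibble with the run identifier columns plus `rme`, `wme`,
#'   `total`, `n_entries`.
#' @export
score_runs <- function(log, config, run_cols = c("animal_id", "session", "run")) {
  if (!is.data.frame(log) || !all(c("entry_index", "arm") %in% names(log))) {
    abort_data("`log` must have columns entry_index and arm")
  }
  run_cols <- intersect(run_cols, names(log))
  if (length(run_cols) == 0L) abort_data("no run identifier columns found")

  per_animal <- is.list(config) && !inherits(config, "maze_config")
  if (per_animal && !("animal_id" %in% names(log))) {
    abort_data("per-animal configs require an `animal_id` column")
  }
  as_cfg <- function(x) if (inherits(x, "maze_config")) x else maze_config(x)

  log <- dplyr::arrange(log, dplyr::across(dplyr::all_of(c(run_cols, "entry_index"))))
  gid <- dplyr::group_indices(dplyr::group_by(log, dplyr::across(dplyr::all_of(run_cols))))
  arm <- as.integer(log$arm)

  if (per_animal) {
    cfgs <- lapply(config, as_cfg)
    n_arms <- unique(vapply(cfgs, function(c) c$n_arms, 1L))
    if (length(n_arms) != 1L) abort_config("configs disagree on n_arms")
    scopes <- unique(vapply(cfgs, function(c) c$wme_scope, ""))
    if (length(scopes) != 1L) abort_config("configs disagree on wme_scope")
    wme_scope <- scopes
    missing_ids <- setdiff(unique(log$animal_id), names(cfgs))
    if (length(missing_ids)) {
      abort_data(paste("no baited set for animal(s):",
                       paste(missing_ids, collapse = ", ")))
    }
    baited_mat <- vapply(cfgs, function(c) {
      m <- logical(n_arms); m[c$baited] <- TRUE; m
    }, logical(n_arms))
    unbaited <- !baited_mat[cbind(arm, match(log$animal_id, colnames(baited_mat)))]
  } else {
    cfg <- as_cfg(config)
    n_arms <- cfg$n_arms
    wme_scope <- cfg$wme_scope
    unbaited <- !(arm %in% cfg$baited)
  }
  if (anyNA(arm) || any(arm < 1L | arm > n_arms)) {
    abort_data("arm indices must lie in 1..n_arms")
  }

  revisit <- duplicated(gid * (n_arms + 1) + arm)
  if (wme_scope == "all") {
    rme_flag <- !revisit & unbaited
    wme_flag <- revisit
  } else {
    rme_flag <- unbaited
    wme_flag <- revisit & !unbaited
  }
  keys <- dplyr::distinct(log[run_cols])
  keys$rme <- as.integer(rowsum(as.integer(rme_flag), gid))
  keys$wme <- as.integer(rowsum(as.integer(wme_flag), gid))
  keys$total <- keys$rme + keys$wme
  keys$n_entries <- as.integer(rowsum(rep(1L, length(gid)), gid))
  tibble::as_tibble(keys)
}

#' Aggregate scored runs into blocks
#'
#' Sums errors over consecutive blocks of `runs_per_block` runs (3 for all
#' study analyses). A trailing partial block is kept but flagged so it can be
#' excluded from criterion checks.
#'
#' @param run_errors A tibble of scored runs (from [score_run()] /
#'   [score_runs()]), in run order, optionally grouped by id columns given in
#'   `by`.
#' @param runs_per_block Runs per block (default 3).
#' @param by Character vector of grouping columns (e.g. `"animal_id"`),
#'   blocks are formed within each group.
#' @return A tibble with the grouping columns plus `block`, `rme`, `wme`,
#'   `total`, `n_runs`, `partial`.
#' @export
block_summaries <- function(run_errors, runs_per_block = 3, by = NULL) {
  check_number(runs_per_block, "runs_per_block", 1)
  need <- c("rme", "wme", "total")
  if (!is.data.frame(run_errors) || !all(need %in% names(run_errors))) {
    abort_data("`run_errors` must have columns rme, wme, total")
  }
  grouped <- if (is.null(by)) run_errors else {
    dplyr::group_by(run_errors, dplyr::across(dplyr::all_of(by)))
  }
  out <- grouped |>
    dplyr::mutate(block = (dplyr::row_number() - 1L) %/% runs_per_block + 1L) |>
    dplyr::group_by(.data$block, .add = TRUE) |>
    dplyr::summarise(rme = sum(.data$rme), wme = sum(.data$wme),
                     total = sum(.data$total), n_runs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(partial = .data$n_runs < runs_per_block)
  tibble::as_tibble(out)
}

#' Training completion criterion
#'
#' The training stop rule: met at the first block index `b` such that blocks
#' `b-2 .. b` each have fewer than three WME and fewer than two RME. Partial
#' blocks never qualify.
#'
#' @param blocks A tibble of ordered block summaries for one animal (from
#'   [block_summaries()]).
#' @return A list with `met` (logical) and `at_block` (integer index or
#'   `NA`).
#' @export
completion_criterion <- function(blocks) {
  need <- c("rme", "wme")
  if (!is.data.frame(blocks) || !all(need %in% names(blocks))) {
    abort_data("`blocks` must have columns rme and wme")
  }
  n <- nrow(blocks)
  partial <- if ("partial" %in% names(blocks)) blocks$partial else rep(FALSE, n)
  ok <- blocks$wme < 3 & blocks$rme < 2 & !partial
  if (n >= 3) {
    for (b in 3:n) {
      if (all(ok[(b - 2):b])) {
        return(list(met = TRUE, at_block = b))
      }
    }
  }
  list(met = FALSE, at_block = NA_integer_)
}

#' Reversal configuration
#'
#' Swaps the baited set to its complement within the 8 arms (the previously
#' unrewarded arms become baited), marking the phase as `"reversal"`.
#' Applying reversal twice restores the original set. The complement of a
#' valid training set can itself violate the adjacency constraint (e.g.
#' baited 1,2,4,5 leaves 3,6,7,8 with three adjacent arms); since the
#' constraint only governs the randomized training choice, no adjacency
#' check is applied to the reversal set.
#'
#' @param config A [maze_config()] with phase `"training"` or `"retest"`.
#' @return A `maze_config` for the reversal phase.
#' @examples
#' reversal_config(maze_config(c(1, 3, 5, 7)))$baited
#' @export
reversal_config <- function(config) {
  if (!inherits(config, "maze_config")) {
    abort_config("`config` must be a maze_config object")
  }
  # reversing a reversal restores the training set (involution)
  new_phase <- if (config$phase == "reversal") "training" else "reversal"
  maze_config(setdiff(seq_len(config$n_arms), config$baited),
              n_arms = config$n_arms, phase = new_phase,
              wme_scope = config$wme_scope, check_adjacency = FALSE)
}

#' Long-format session error table
#'
#' Builds the tidy per-block totals table used by the group statistics:
#' one row per animal x phase x block with summed RME, WME and total errors.
#'
#' @param scored Scored runs (from [score_runs()]) with an `animal_id`
#'   column, a `group` column, and optionally `phase`/`week`.
#' @param runs_per_block Runs per block (default 3).
#' @return A tibble `animal_id, group[, phase/week], block, rme, wme, total`.
#' @export
session_table <- function(scored, runs_per_block = 3) {
  need <- c("animal_id", "group", "rme", "wme", "total")
  if (!is.data.frame(scored) || !all(need %in% names(scored))) {
    abort_data("`scored` must have columns animal_id, group, rme, wme, total")
  }
  by <- intersect(c("animal_id", "group", "phase", "week", "session"),
                  names(scored))
  run_key <- intersect(c(by, "run"), names(scored))
  if ("run" %in% run_key && anyDuplicated(scored[run_key])) {
    abort_data("duplicate (animal, phase, run) rows in the scored runs")
  }
  block_summaries(scored, runs_per_block = runs_per_block, by = by)
}
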