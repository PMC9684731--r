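#' Simulate a radial-maze session
#'
#' Generates ordered arm-entry sequences for `n_runs` runs on the 4-arm
#' baited 8-arm maze. At each choice the simulated animal first (with
#' probability `p_wme`, and only once at least one arm has been visited)
#' re-enters an already-visited arm (a working-memory error), otherwise with
#' probability `p_rme` enters a not-yet-visited unbaited arm (a
#' reference-memory error), and otherwise enters a not-yet-visited baited
#' arm. A run ends when all four baited arms have been visited or after
#' `entry_cap` entries (the synthetic stand-in for the session timeout).
#' Both error probabilities are multiplied by `learning_decay^(block - 1)`
#' where blocks are consecutive groups of `runs_per_block` runs, producing a
#' learning curve in total errors.
#'
#' @param n_runs Number of runs.
#' @param p_rme Probability per choice of a first-visit entry into an
#'   unbaited arm, in `[0, 1]`.
#' @param p_wme Probability per choice of re-entering a visited arm,
#'   in `[0, 1]`.
#' @param baited Integer vector of the 4 baited arms (validated as a
#'   [maze_config()]).
#' @param learning_decay Per-block multiplicative decay of both error
#'   probabilities (>= 0; values below 1 produce learning, 1 = no learning).
#' @param runs_per_block Runs per block for the decay schedule (default 3).
#' @param n_arms Number of maze arms (default 8).
#' @param entry_cap Maximum entries per run (default 50).
#' @param seed Optional integer seed.
#' @return A tibble with columns `run`, `entry_index`, `arm`,
#'   `terminated_by` (`"all_rewards"` or `"cap"`); the baited set is attached
#'   as attribute `baited`.
#' @examples
#' generate_maze_session(3, p_rme = 0, p_wme = 0, baited = c(1, 3, 5, 7),
#'                       seed = 1)
#' @export
generate_maze_session <- function(n_runs, p_rme, p_wme, baited,
                                  learning_decay = 1, runs_per_block = 3,
                                  n_arms = 8, entry_cap = 50, seed = NULL) {
  check_number(n_runs, "n_runs", 1)
  check_number(p_rme, "p_rme", 0, 1)
  check_number(p_wme, "p_wme", 0, 1)
  check_number(learning_decay, "learning_decay", 0)
  config <- maze_config(baited, n_arms = n_arms)
  baited <- config$baited

  with_seed_if(seed, {
    runs <- lapply(seq_len(n_runs), function(r) {
      block <- (r - 1) %/% runs_per_block + 1
      decay <- learning_decay^(block - 1)
      pr <- min(1, p_rme * decay)
      pw <- min(1, p_wme * decay)
      entries <- integer(0)
      visited <- integer(0)
      terminated <- "cap"
      while (length(entries) < entry_cap) {
        unvisited_baited <- setdiff(baited, visited)
        if (length(unvisited_baited) == 0L) {
          terminated <- "all_rewards"
          break
        }
        unvisited_unbaited <- setdiff(setdiff(seq_len(n_arms), baited), visited)
        arm <- if (length(visited) > 0L && stats::runif(1) < pw) {
          sample_one(visited)
        } else if (length(unvisited_unbaited) > 0L && stats::runif(1) < pr) {
          sample_one(unvisited_unbaited)
        } else {
          sample_one(unvisited_baited)
        }
        entries <- c(entries, arm)
        visited <- union(visited, arm)
      }
      if (length(setdiff(baited, visited)) == 0L) terminated <- "all_rewards"
      tibble::tibble(run = r, entry_index = seq_along(entries), arm = entries,
                     terminated_by = terminated)
    })
    out <- dplyr::bind_rows(runs)
    attr(out, "baited") <- baited
    out
  })
}

# sample(x, 1) resamples from 1:x when x is scalar; avoid that trap
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)
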