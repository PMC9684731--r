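#' Simulate a spike train from a gamma renewal process
#'
#' ISIs are drawn i.i.d. from a gamma distribution with mean `1/rate` and
#' shape `shape`, so the ISI coefficient of variation is `1/sqrt(shape)`:
#' `shape = 1` gives Poisson (exponential ISIs, irregular) firing and large
#' shapes give near-regular clock-like firing. An absolute refractory period
#' is enforced by dead-time deletion (spikes closer than `refractory` to the
#' previous surviving spike are removed) after generating at a renormalized
#' rate `rate / (1 - rate * refractory)`, which keeps the mean output rate
#' interpretable as `rate`.
#'
#' @param rate Target mean firing rate, Hz (> 0).
#' @param shape Gamma shape parameter (> 0); regularity dial.
#' @param duration Epoch length, seconds (> 0).
#' @param refractory Absolute refractory period, seconds (>= 0). Must satisfy
#'   `rate * refractory < 1`.
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards. Same arguments + same seed give identical spike times.
#' @return Numeric vector of strictly increasing spike times in
#'   `(0, duration]`.
#' @examples
#' s <- generate_spike_train(10, shape = 4, duration = 100, seed = 1)
#' 1 / mean(diff(s)) # close to 10 Hz
#' @export
generate_spike_train <- function(rate, shape = 1, duration,
                                 refractory = 0, seed = NULL) {
  check_number(rate, "rate", 0, strict_lower = TRUE)
  check_number(shape, "shape", 0, strict_lower = TRUE)
  check_number(duration, "duration", 0, strict_lower = TRUE)
  check_number(refractory, "refractory", 0)
  if (rate * duration < 10) {
    abort_config("expected spike count rate * duration must be >= 10")
  }
  if (rate * refractory >= 1) {
    abort_config("`refractory` is incompatible with `rate` (rate * refractory >= 1)")
  }
  rate_gen <- rate / (1 - rate * refractory)

  with_seed_if(seed, {
    times <- numeric(0)
    t_last <- 0
    repeat {
      n_draw <- ceiling((duration - t_last) * rate_gen * 1.25) + 25L
      isis <- stats::rgamma(n_draw, shape = shape, rate = shape * rate_gen)
      new_times <- t_last + cumsum(isis)
      times <- c(times, new_times)
      t_last <- times[length(times)]
      if (t_last > duration) break
    }
    times <- times[times <= duration]
    if (refractory > 0 && length(times) > 1L) {
      keep <- logical(length(times))
      keep[1] <- TRUE
      last <- times[1]
      for (i in 2:length(times)) {
        if (times[i] - last >= refractory) {
          keep[i] <- TRUE
          last <- times[i]
        }
      }
      times <- times[keep]
    }
    times
  })
}
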