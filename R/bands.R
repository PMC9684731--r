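#' Canonical frequency bands
#'
#' The four oscillatory bands used throughout the field-potential analyses:
#' theta 4-8 Hz, alpha 8-12 Hz, beta 12-30 Hz, gamma 30-100 Hz. Band intervals
#' are half-open `[low, high)` so a grid frequency sitting exactly on a
#' boundary (e.g. 8 Hz) belongs to the higher band.
#'
#' @param include_delta Also include a delta (1-4 Hz) row, used by the optional
#'   slow-wave exclusion rule. Default `FALSE`.
#' @return A tibble with columns `band`, `low_hz`, `high_hz`.
#' @examples
#' canonical_bands()
#' @export
canonical_bands <- function(include_delta = FALSE) {
  bands <- tibble::tibble(
    band    = c("theta", "alpha", "beta", "gamma"),
    low_hz  = c(4, 8, 12, 30),
    high_hz = c(8, 12, 30, 100)
  )
  if (include_delta) {
    bands <- dplyr::bind_rows(
      tibble::tibble(band = "delta", low_hz = 1, high_hz = 4), bands
    )
  }
  bands
}

check_bands <- function(bands) {
  need <- c("band", "low_hz", "high_hz")
  if (!is.data.frame(bands) || !all(need %in% names(bands))) {
    abort_config("`bands` must be a data frame with columns band, low_hz, high_hz")
  }
  if (any(bands$low_hz >= bands$high_hz)) {
    abort_config("each band must have low_hz < high_hz")
  }
  invisible(bands)
}
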