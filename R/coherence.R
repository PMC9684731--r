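#' Magnitude-squared coherence between two signals
#'
#' Welch-averaged magnitude-squared coherence
#' `C(f) = |Sxy(f)|^2 / (Sxx(f) * Syy(f))` over the same Hann-windowed,
#' 50%-overlapping `block_length`-sample blocks as [welch_psd()], so PSD and
#' coherence share one spectral grid. C(f) lies in `[0, 1]`: 0 means no
#' linear association at that frequency, 1 a perfect linear association.
#' The 95% confidence threshold for zero coherence,
#' `1 - 0.05^(1/(L - 1))` with `L` the number of averaged segments, is
#' attached; with overlapping blocks the raw segment count is used for `L`,
#' which is the conservative direction for detecting nonzero coherence.
#'
#' @param x,y Equal-length numeric vectors sampled simultaneously at
#'   `sampling_rate`.
#' @param sampling_rate Sampling rate, Hz.
#' @param block_length Samples per block (default 1024).
#' @param overlap Fractional block overlap (default 0.5).
#' @return A tibble of class `coherence_tbl` with columns `frequency`,
#'   `coherence` and attributes `n_segments`, `confidence_level_095`,
#'   `resolution`.
#' @examples
#' t <- seq(0, 10, by = 1e-3)
#' x <- sin(2 * pi * 6 * t) + rnorm(length(t))
#' cs <- msc(x, x, sampling_rate = 1000)
#' all(cs$coherence == 1)
#' @export
msc <- function(x, y, sampling_rate, block_length = 1024, overlap = 0.5) {
  if (!is.numeric(x) || !is.numeric(y)) abort_data("signals must be numeric")
  if (length(x) != length(y)) {
    abort_data("signals must have equal length (time-aligned pair)")
  }
  check_number(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  bx <- welch_block_matrix(list(x), block_length, overlap)
  by <- welch_block_matrix(list(y), block_length, overlap)
  if (is.null(bx) || ncol(bx) < 2L) {
    abort_insufficient("coherence needs at least 2 blocks; the single-block estimator is degenerate (identically 1)")
  }
  w <- hann_window(block_length)
  fx <- stats::mvfft(bx * w)
  fy <- stats::mvfft(by * w)
  half <- block_length %/% 2 + 1L
  sxx <- rowMeans(Matrix_mod2(fx))[seq_len(half)]
  syy <- rowMeans(Matrix_mod2(fy))[seq_len(half)]
  sxy <- rowMeans(fx * Conj(fy))[seq_len(half)]
  denom <- sxx * syy
  coh <- ifelse(denom > 0, Matrix_mod2(sxy) / denom, 0)
  coh <- pmin(pmax(coh, 0), 1) # guard floating-point roundoff at the bounds
  n_seg <- ncol(bx)
  out <- tibble::tibble(
    frequency = (seq_len(half) - 1L) * sampling_rate / block_length,
    coherence = coh
  )
  structure(out, class = c("coherence_tbl", class(out)),
            n_segments = n_seg,
            confidence_level_095 = 1 - 0.05^(1 / (n_seg - 1)),
            resolution = sampling_rate / block_length)
}

#' Band-mean coherence
#'
#' Unweighted mean of the coherence over the grid frequencies inside each
#' band, with the same half-open `[low, high)` band convention as the power
#' analysis.
#'
#' @param cspec A `coherence_tbl` from [msc()].
#' @param bands Band definition table, see [canonical_bands()].
#' @return A tibble with columns `band`, `low_hz`, `high_hz`,
#'   `mean_coherence`, `n_bins`.
#' @export
band_coherence <- function(cspec, bands = canonical_bands()) {
  if (!is.data.frame(cspec) ||
      !all(c("frequency", "coherence") %in% names(cspec))) {
    abort_data("`cspec` must have columns frequency and coherence")
  }
  check_bands(bands)
  if (any(bands$high_hz > max(cspec$frequency) + 1e-9)) {
    abort_config("bands must lie within the coherence grid support")
  }
  res <- purrr::pmap(list(bands$band, bands$low_hz, bands$high_hz),
    function(b, lo, hi) {
      sel <- cspec$frequency >= lo & cspec$frequency < hi
      if (!any(sel)) abort_config(sprintf("band %s contains no grid frequencies", b))
      tibble::tibble(band = b, low_hz = lo, high_hz = hi,
                     mean_coherence = mean(cspec$coherence[sel]),
                     n_bins = sum(sel))
    })
  dplyr::bind_rows(res)
}
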