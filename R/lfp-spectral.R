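#' Amplitude-threshold artifact rejection
#'
#' Splits a trace into contiguous clean segments whose absolute amplitude
#' never exceeds `threshold_uv`; spans containing threshold crossings are
#' rejected, and surviving segments shorter than one Welch block are
#' discarded (they cannot contribute a spectral block). This automates the
#' study's visual overshoot screening.
#'
#' @param samples Numeric vector, microvolts.
#' @param sampling_rate Sampling rate, Hz.
#' @param threshold_uv Rejection threshold, microvolts (> 0).
#' @param min_segment Minimum surviving segment length in samples (default
#'   1024, one Welch block).
#' @return A list of class `artifact_screen` with `segments` (list of
#'   numeric vectors), `report` (tibble of rejected/short spans with
#'   `start_s`, `end_s`, `reason`) and `sampling_rate`.
#' @export
reject_artifacts <- function(samples, sampling_rate, threshold_uv,
                             min_segment = 1024) {
  check_number(threshold_uv, "threshold_uv", 0, strict_lower = TRUE)
  check_number(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  if (!is.numeric(samples) || length(samples) == 0L) {
    abort_data("`samples` must be a non-empty numeric vector")
  }
  clean <- is.finite(samples) & abs(samples) <= threshold_uv
  r <- rle(clean)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  segments <- list()
  report <- list()
  for (j in seq_along(r$values)) {
    span_s <- c((starts[j] - 1L) / sampling_rate, ends[j] / sampling_rate)
    if (!r$values[j]) {
      report[[length(report) + 1]] <- tibble::tibble(
        start_s = span_s[1], end_s = span_s[2], reason = "amplitude_overshoot")
    } else if (r$lengths[j] < min_segment) {
      report[[length(report) + 1]] <- tibble::tibble(
        start_s = span_s[1], end_s = span_s[2], reason = "segment_too_short")
    } else {
      segments[[length(segments) + 1]] <- samples[starts[j]:ends[j]]
    }
  }
  if (length(segments) == 0L) {
    abort_data("no clean data: every span was rejected or too short")
  }
  structure(
    list(segments = segments,
         report = if (length(report)) dplyr::bind_rows(report) else
           tibble::tibble(start_s = numeric(), end_s = numeric(),
                          reason = character()),
         sampling_rate = sampling_rate),
    class = "artifact_screen"
  )
}

#' Zero-phase notch and low-pass filtering
#'
#' Applies a FIR 50 Hz notch (band-stop) filter and a FIR 100 Hz low-pass
#' filter, both zero-phase (forward-backward), matching the study's
#' preprocessing. Filter orders are chosen so the forward-backward cascade
#' attenuates the notch frequency and frequencies above 120 Hz by well over
#' 30 dB while keeping passband ripple below 1% (Hamming-window designs).
#'
#' @param samples Numeric vector, microvolts.
#' @param sampling_rate Sampling rate, Hz; must exceed 200 Hz so both
#'   filters are designable.
#' @param notch_hz Center of the band-stop filter (default 50).
#' @param lowpass_hz Low-pass band edge (default 100).
#' @return Filtered numeric vector, same length.
#' @export
apply_filters <- function(samples, sampling_rate, notch_hz = 50,
                          lowpass_hz = 100) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    abort_data("`samples` must be a non-empty numeric vector")
  }
  if (sampling_rate <= 200) {
    abort_config("`sampling_rate` must exceed 200 Hz for the filter designs")
  }
  nyq <- sampling_rate / 2
  if (lowpass_hz * 1.2 >= nyq || notch_hz + 5 >= nyq) {
    abort_config("filter edges do not fit below the Nyquist frequency")
  }
  b <- filter_kernel(sampling_rate, notch_hz, lowpass_hz)
  key <- paste(sampling_rate, notch_hz, lowpass_hz)
  filtfilt_fft(b, samples, cache_key = key)
}

# combined notch x low-pass FIR kernel, memoized per design
filter_kernel <- local({
  cache <- new.env(parent = emptyenv())
  function(sampling_rate, notch_hz, lowpass_hz) {
    key <- paste(sampling_rate, notch_hz, lowpass_hz)
    if (is.null(cache[[key]])) {
      nyq <- sampling_rate / 2
      b_notch <- as.numeric(signal::fir1(400, c(notch_hz - 4, notch_hz + 4) / nyq,
                                         type = "stop"))
      b_low <- as.numeric(signal::fir1(220, (lowpass_hz * 1.08) / nyq,
                                       type = "low"))
      cache[[key]] <- fft_conv(b_notch, b_low) # cascade = kernel convolution
    }
    cache[[key]]
  }
})

# zero-phase (forward-backward) FIR filtering via FFT convolution;
# equivalent to filtering twice with time reversal, O(n log n)
filtfilt_fft <- function(b, x, cache_key = NULL) {
  n <- length(x)
  l <- length(b)
  y <- fft_conv(x, b, cache_key)       # forward pass, length n + l - 1
  y <- rev(fft_conv(rev(y), b, cache_key)) # backward pass cancels the phase
  y[l:(l + n - 1L)]
}

fft_conv <- function(x, b, cache_key = NULL) {
  n_out <- length(x) + length(b) - 1L
  nfft <- stats::nextn(n_out, 2)
  xx <- c(x, numeric(nfft - length(x)))
  bb_fft <- kernel_fft(b, nfft, cache_key)
  y <- Re(stats::fft(stats::fft(xx) * bb_fft, inverse = TRUE)) / nfft
  y[seq_len(n_out)]
}

# FFT of the zero-padded kernel, memoized per (design, nfft)
kernel_fft <- local({
  cache <- new.env(parent = emptyenv())
  function(b, nfft, cache_key) {
    if (is.null(cache_key)) {
      return(stats::fft(c(b, numeric(nfft - length(b)))))
    }
    key <- paste(cache_key, nfft)
    if (is.null(cache[[key]])) {
      cache[[key]] <- stats::fft(c(b, numeric(nfft - length(b))))
    }
    cache[[key]]
  }
})

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-windowed blocks of `block_length` samples
#' with 50% overlap (per-block mean removal before windowing). When a list
#' of segments is supplied (e.g. from [reject_artifacts()]), blocks are
#' collected from every segment and averaged together. The one-sided density
#' is scaled so that `sum(power) * resolution` equals the windowed signal
#' variance (Parseval); frequency resolution is
#' `sampling_rate / block_length` (0.9766 Hz at 1 kHz with 1024-sample
#' blocks).
#'
#' @param x Numeric vector, a list of numeric segments, or an
#'   `artifact_screen`.
#' @param sampling_rate Sampling rate, Hz (taken from the screen object when
#'   one is supplied).
#' @param block_length Samples per block (default 1024).
#' @param overlap Fractional block overlap in `[0, 1)` (default 0.5).
#' @return A tibble of class `psd_tbl` with columns `frequency`, `power`
#'   and attributes `resolution`, `n_blocks`, `window`, `sampling_rate`,
#'   `block_length`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 1e-3))
#' psd <- welch_psd(x, sampling_rate = 1000)
#' attr(psd, "resolution")
#' @export
welch_psd <- function(x, sampling_rate = NULL, block_length = 1024,
                      overlap = 0.5) {
  if (inherits(x, "artifact_screen")) {
    sampling_rate <- x$sampling_rate
    x <- x$segments
  }
  if (is.null(sampling_rate)) abort_config("`sampling_rate` is required")
  check_number(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  check_number(block_length, "block_length", 2)
  check_number(overlap, "overlap", 0, 1)
  if (overlap >= 1) abort_config("`overlap` must be < 1")
  segments <- if (is.list(x)) x else list(x)

  blocks <- welch_block_matrix(segments, block_length, overlap)
  if (is.null(blocks)) {
    abort_insufficient("no segment is at least one block long")
  }
  w <- hann_window(block_length)
  wb <- blocks * w # recycles column-wise over the block matrix
  spec <- stats::mvfft(wb)
  half <- block_length %/% 2 + 1L
  p2 <- rowMeans(Matrix_mod2(spec))[seq_len(half)]
  scale <- 1 / (sampling_rate * sum(w^2))
  power <- p2 * scale
  power[2:(half - 1L)] <- 2 * power[2:(half - 1L)] # one-sided doubling
  out <- tibble::tibble(
    frequency = (seq_len(half) - 1L) * sampling_rate / block_length,
    power = power
  )
  structure(out,
            class = c("psd_tbl", class(out)),
            resolution = sampling_rate / block_length,
            n_blocks = ncol(blocks), window = "hann",
            sampling_rate = sampling_rate, block_length = block_length)
}

Matrix_mod2 <- function(z) Re(z)^2 + Im(z)^2

# periodic Hann window
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# demeaned block matrix (block_length x n_blocks) pooled across segments
welch_block_matrix <- function(segments, block_length, overlap) {
  step <- max(1L, round(block_length * (1 - overlap)))
  cols <- list()
  for (seg in segments) {
    if (!is.numeric(seg)) abort_data("segments must be numeric vectors")
    n <- length(seg)
    if (n < block_length) next
    starts <- seq(1L, n - block_length + 1L, by = step)
    m <- vapply(starts, function(s) seg[s:(s + block_length - 1L)],
                numeric(block_length))
    cols[[length(cols) + 1]] <- m
  }
  if (length(cols) == 0L) return(NULL)
  m <- do.call(cbind, cols)
  sweep(m, 2L, colMeans(m)) # per-block mean removal
}

#' Absolute and relative band power
#'
#' Integrates the PSD over each band with the trapezoidal rule, linearly
#' interpolating the spectrum at the exact band edges so that band areas are
#' proportional to bandwidth for a flat spectrum. Relative power is the band
#' area as a percentage of the area over `denominator_range` (default
#' 1-100 Hz, excluding DC and sub-delta drift).
#'
#' @param spectrum A `psd_tbl` from [welch_psd()] (or any data frame with
#'   `frequency` and `power` columns).
#' @param bands Band definition table, see [canonical_bands()].
#' @param denominator_range Length-2 numeric, the reference interval in Hz.
#' @return A tibble of class `band_power_tbl` with columns `band`, `low_hz`,
#'   `high_hz`, `absolute_power`, `relative_power_pct` and attribute
#'   `denominator` (the reference area).
#' @export
band_power <- function(spectrum, bands = canonical_bands(),
                       denominator_range = c(1, 100)) {
  if (!is.data.frame(spectrum) ||
      !all(c("frequency", "power") %in% names(spectrum))) {
    abort_data("`spectrum` must have columns frequency and power")
  }
  check_bands(bands)
  if (length(denominator_range) != 2L ||
      denominator_range[1] >= denominator_range[2]) {
    abort_config("`denominator_range` must be an increasing length-2 interval")
  }
  f <- spectrum$frequency
  p <- spectrum$power
  if (any(p < 0)) abort_data("PSD values must be non-negative")
  support <- range(f)
  if (denominator_range[1] < support[1] || denominator_range[2] > support[2]) {
    abort_config("`denominator_range` must lie within the spectrum support")
  }
  if (any(bands$low_hz < denominator_range[1] - 1e-9) ||
      any(bands$high_hz > denominator_range[2] + 1e-9)) {
    abort_config("bands must lie within `denominator_range`")
  }
  denom <- band_area(f, p, denominator_range[1], denominator_range[2])
  if (denom <= 0) abort_data("zero spectral area over the denominator range")
  abs_power <- mapply(function(lo, hi) band_area(f, p, lo, hi),
                      bands$low_hz, bands$high_hz)
  out <- tibble::tibble(
    band = bands$band, low_hz = bands$low_hz, high_hz = bands$high_hz,
    absolute_power = abs_power,
    relative_power_pct = 100 * abs_power / denom
  )
  structure(out, class = c("band_power_tbl", class(out)),
            denominator = denom)
}

# trapezoidal area of (f, p) over [lo, hi] with interpolated edge ordinates
band_area <- function(f, p, lo, hi) {
  inner <- f > lo & f < hi
  xs <- c(lo, f[inner], hi)
  ys <- c(stats::approx(f, p, xout = lo)$y, p[inner],
          stats::approx(f, p, xout = hi)$y)
  trapezoid(xs, ys)
}
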