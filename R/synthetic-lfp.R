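#' Simulate a coupled LFP/ECoG signal pair
#'
#' Each trace is synthesized in the frequency domain as the sum of four
#' band-limited oscillatory carriers (complex-Gaussian coefficients with
#' randomized phase on the canonical theta/alpha/beta/gamma bands), broadband
#' `1/f` background noise, and a deterministic 50 Hz mains line component.
#' For every band a fraction `coupling` of the carrier *variance* is a
#' component shared between the two traces, the remainder independent; the
#' expected magnitude-squared coherence inside a band is therefore
#' `coupling^2` (coupling 1 gives sample-identical shared carriers, coupling
#' 0 leaves only the estimator bias floor).
#'
#' @param band_amplitudes Named numeric vector of carrier RMS amplitudes in
#'   microvolts for `theta`, `alpha`, `beta`, `gamma` (missing bands = 0).
#' @param coupling Shared-variance fraction in `[0, 1]`; either a single
#'   number applied to every band or a named per-band vector.
#' @param duration Trace length, seconds.
#' @param sampling_rate Sampling rate, Hz.
#' @param band_amplitudes_y Optional distinct amplitudes for the second trace
#'   (defaults to `band_amplitudes`); lets the two channels differ in band
#'   structure while staying coupled.
#' @param noise_exponent Spectral slope of the `1/f^a` background (default 1).
#' @param noise_amplitude Background noise RMS amplitude, microvolts.
#' @param line_amplitude Peak amplitude of the 50 Hz line component,
#'   microvolts; included by default so the notch filter stage is exercised.
#' @param seed Optional integer seed.
#' @return A list with numeric vectors `x` and `y` (microvolts, equal length
#'   `duration * sampling_rate`) and the `sampling_rate`.
#' @examples
#' p <- generate_lfp_pair(c(theta = 10, alpha = 1, beta = 1, gamma = 1),
#'                        coupling = 0.5, duration = 10,
#'                        sampling_rate = 1000, seed = 1)
#' length(p$x)
#' @export
generate_lfp_pair <- function(band_amplitudes, coupling = 0, duration,
                              sampling_rate,
                              band_amplitudes_y = band_amplitudes,
                              noise_exponent = 1, noise_amplitude = 5,
                              line_amplitude = 2, seed = NULL) {
  check_number(duration, "duration", 0, strict_lower = TRUE)
  check_number(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  check_number(noise_exponent, "noise_exponent", 0)
  check_number(noise_amplitude, "noise_amplitude", 0)
  check_number(line_amplitude, "line_amplitude", 0)
  n <- round(duration * sampling_rate)
  if (n < 2 * 1024) {
    abort_config("duration x sampling_rate must cover at least two 1024-sample Welch blocks")
  }
  bands <- canonical_bands()
  amp_x <- band_amplitude_vector(band_amplitudes, bands$band)
  amp_y <- band_amplitude_vector(band_amplitudes_y, bands$band)
  cpl <- coupling_vector(coupling, bands$band)

  freq <- (seq_len(n %/% 2)) * sampling_rate / n # positive-frequency grid

  with_seed_if(seed, {
    zx <- complex(real = numeric(length(freq)), imaginary = numeric(length(freq)))
    zy <- zx
    for (b in seq_len(nrow(bands))) {
      sel <- which(freq >= bands$low_hz[b] & freq < bands$high_hz[b])
      k <- length(sel)
      if (k == 0L) next
      shared <- cgauss(k)
      ix <- cgauss(k)
      iy <- cgauss(k)
      mix_x <- sqrt(cpl[b]) * shared + sqrt(1 - cpl[b]) * ix
      mix_y <- sqrt(cpl[b]) * shared + sqrt(1 - cpl[b]) * iy
      # scale so the band component variance equals amplitude^2
      sc <- n / sqrt(2 * k)
      zx[sel] <- zx[sel] + amp_x[b] * sc * mix_x
      zy[sel] <- zy[sel] + amp_y[b] * sc * mix_y
    }
    if (noise_amplitude > 0) {
      w <- freq^(-noise_exponent / 2)
      w <- w / sqrt(sum(2 * w^2) / n^2) # normalize noise RMS to 1
      zx <- zx + noise_amplitude * w * cgauss(length(freq))
      zy <- zy + noise_amplitude * w * cgauss(length(freq))
    }
    x <- synth_real(zx, n)
    y <- synth_real(zy, n)
    if (line_amplitude > 0) {
      tt <- (0:(n - 1)) / sampling_rate
      line_phase <- stats::runif(1, 0, 2 * pi)
      line <- line_amplitude * sin(2 * pi * 50 * tt + line_phase)
      x <- x + line
      y <- y + line
    }
    list(x = x, y = y, sampling_rate = sampling_rate)
  })
}

# standard complex Gaussian CN(0, 1)
cgauss <- function(k) {
  complex(real = stats::rnorm(k, sd = sqrt(0.5)),
          imaginary = stats::rnorm(k, sd = sqrt(0.5)))
}

# real signal from positive-frequency coefficients (Hermitian completion)
synth_real <- function(zpos, n) {
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  kmax <- length(zpos)
  spec[2:(kmax + 1)] <- zpos
  # mirror; for even n the Nyquist bin (kmax) is its own conjugate partner
  mirror_idx <- n:(n - kmax + 2)
  spec[mirror_idx] <- Conj(zpos[seq_len(kmax - 1)])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

band_amplitude_vector <- function(amps, band_names) {
  if (is.null(names(amps)) && length(amps) == length(band_names)) {
    names(amps) <- band_names
  }
  if (!is.numeric(amps) || is.null(names(amps)) ||
      !all(names(amps) %in% band_names)) {
    abort_config("`band_amplitudes` must be a numeric vector named after canonical bands")
  }
  if (any(amps < 0)) abort_config("band amplitudes must be >= 0")
  out <- stats::setNames(numeric(length(band_names)), band_names)
  out[names(amps)] <- amps
  out
}

coupling_vector <- function(coupling, band_names) {
  if (length(coupling) == 1L && is.null(names(coupling))) {
    coupling <- stats::setNames(rep(coupling, length(band_names)), band_names)
  }
  if (!is.numeric(coupling) || is.null(names(coupling)) ||
      !all(names(coupling) %in% band_names)) {
    abort_config("`coupling` must be a single number or a per-band named vector")
  }
  if (any(coupling < 0 | coupling > 1)) {
    abort_config("`coupling` must lie in [0, 1]")
  }
  out <- stats::setNames(numeric(length(band_names)), band_names)
  out[names(coupling)] <- coupling
  out
}
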