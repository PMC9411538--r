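# Morlet wavelet spectrograms.
#
# The transform is implemented in the frequency domain: the FFT of the trace
# is multiplied with an analytic Gaussian window centred on each analysis
# frequency, giving the complex Morlet coefficient series per frequency. A
# wavelet with n_cycles cycles has spectral standard deviation
# sigma_f = f / n_cycles and temporal standard deviation
# sigma_t = n_cycles / (2 pi f).
#
# Scaling: the window peak is 2 (analytic signal convention), so a pure
# sinusoid of amplitude A yields power A^2 at its own frequency row.

#' Spectrogram analysis parameters
#'
#' Defaults implement event-locked analysis of withdrawal trials: power on a
#' 0.5-Hz frequency grid between 4 and 100 Hz at 1-ms time resolution,
#' windows of 3 s around the stimulation onset, a 1-s pre-onset baseline and
#' a 2-s post-onset quantification window.
#'
#' @param freq_step Frequency grid step (Hz).
#' @param freq_range Analysis range `c(lo, hi)` in Hz.
#' @param time_resolution Spectrogram time step (s).
#' @param n_cycles Morlet wavelet width in cycles (see the methods vignette
#'   for why the default favours spectral concentration).
#' @param wavelet_base_param Center-frequency constant of the classic Morlet
#'   mother wavelet, kept as provenance metadata only; the analysis wavelet
#'   is parameterized by `n_cycles`.
#' @param pre_window,post_window Seconds before/after onset to extract.
#' @param baseline_window Seconds before onset used for normalization.
#' @param quant_window Seconds after onset used for band quantification.
#' @param timecourse_bin Bin width (s) for band time courses.
#' @param baseline_mode `"pooled"`: each frequency row is normalized by the
#'   baseline mean pooled across trials (default); `"per_trial"`: each trial
#'   is normalized by its own 1-s baseline before averaging.
#' @param withdrawal_only Use only withdrawal trials in event-locked averages.
#' @return A list of class `spectrogram_params`.
#' @export
spectrogram_params <- function(freq_step = 0.5, freq_range = c(4, 100),
                               time_resolution = 0.001, n_cycles = 7,
                               wavelet_base_param = 0.8125,
                               pre_window = 3, post_window = 3,
                               baseline_window = 1, quant_window = 2,
                               timecourse_bin = 0.1,
                               baseline_mode = c("pooled", "per_trial"),
                               withdrawal_only = TRUE) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(length(freq_range) == 2, freq_range[1] < freq_range[2])
  if (baseline_window > pre_window)
    pe_stop("badarg", "baseline_window must not exceed pre_window")
  if (quant_window > post_window)
    pe_stop("badarg", "quant_window must not exceed post_window")
  structure(list(freq_step = freq_step, freq_range = freq_range,
                 time_resolution = time_resolution, n_cycles = n_cycles,
                 wavelet_base_param = wavelet_base_param,
                 pre_window = pre_window, post_window = post_window,
                 baseline_window = baseline_window, quant_window = quant_window,
                 timecourse_bin = timecourse_bin, baseline_mode = baseline_mode,
                 withdrawal_only = withdrawal_only),
            class = "spectrogram_params")
}

#' Frequency grid of a parameter set
#' @param params A [spectrogram_params()] object.
#' @return Numeric vector of analysis frequencies (Hz).
#' @export
spectrogram_freqs <- function(params) {
  seq(params$freq_range[1], params$freq_range[2] - params$freq_step,
      by = params$freq_step)
}

#' Morlet wavelet power spectrogram
#'
#' @param trace Numeric signal (typically the preprocessed 1-kHz LFP).
#' @param fs Sampling rate of `trace` (Hz).
#' @param params A [spectrogram_params()] object.
#' @return Object of class `spectrogram`: list with `power`
#'   (frequency x time matrix), `freq`, `time` (s from trace start), `fs`,
#'   `support_s` (per-frequency half-support; samples closer than this to
#'   either trace edge are not valid) and `params`.
#' @export
morlet_spectrogram <- function(trace, fs, params = spectrogram_params()) {
  stopifnot(inherits(params, "spectrogram_params"))
  assert_finite(trace, "trace")
  freqs <- spectrogram_freqs(params)
  if (max(freqs) >= fs / 2)
    pe_stop("badarg", "requested frequency %g Hz is not below fs/2 = %g Hz",
            max(freqs), fs / 2)
  n <- length(trace)
  support <- wavelet_support(freqs, params$n_cycles)
  if (n / fs < 2 * max(support))
    pe_stop("badarg",
            "trace (%.2f s) is shorter than the longest wavelet support (2 x %.2f s)",
            n / fs, max(support))
  nfft <- stats::nextn(n + ceiling(max(support) * fs), factors = 2)
  X <- stats::fft(c(trace, numeric(nfft - n)))
  fgrid <- (seq_len(nfft) - 1) * fs / nfft   # 0 .. fs(1-1/nfft)
  pos <- fgrid <= fs / 2                      # analytic: keep positive freqs
  stride <- max(1L, round(fs * params$time_resolution))
  keep <- seq(1L, n, by = stride)
  power <- matrix(0, nrow = length(freqs), ncol = length(keep))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sigma_f <- f / params$n_cycles
    G <- numeric(nfft)
    G[pos] <- 2 * exp(-((fgrid[pos] - f)^2) / (2 * sigma_f^2))
    coef <- stats::fft(X * G, inverse = TRUE)[keep] / nfft
    power[i, ] <- Re(coef)^2 + Im(coef)^2
  }
  structure(list(power = power, freq = freqs, time = (keep - 1) / fs,
                 fs = fs / stride, support_s = support, params = params),
            class = "spectrogram")
}

# half-support (seconds) after which the truncated Gaussian tail is < exp(-8)
wavelet_support <- function(freqs, n_cycles) {
  4 * n_cycles / (2 * pi * freqs)
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("Morlet spectrogram: %d frequencies (%.1f-%.1f Hz), %d time points at %g Hz\n",
              length(x$freq), min(x$freq), max(x$freq), ncol(x$power), x$fs))
  invisible(x)
}
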