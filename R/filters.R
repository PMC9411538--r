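# Anti-alias filtering and decimation of the raw wide-band trace.
#
# The preprocessing contract is a 3rd-order lowpass Chebyshev type I filter
# (0.5 dB passband ripple, 200 Hz passband edge) applied zero-phase, followed
# by downsampling to 1 kHz.  The filter is designed here from the analog
# prototype via the bilinear transform with the passband edge prewarped, so
# the digital magnitude at the edge frequency equals -ripple_db exactly.

#' Preprocessing parameters for the raw LFP trace
#'
#' @param filter_order Order of the lowpass Chebyshev type I filter.
#' @param ripple_db Passband ripple in dB.
#' @param passband_edge Passband edge frequency in Hz.
#' @param fs_out Output sampling rate in Hz after decimation.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(filter_order = 3, ripple_db = 0.5,
                              passband_edge = 200, fs_out = 1000) {
  assert_scalar_num(filter_order, "filter_order", 1, 12)
  assert_scalar_num(ripple_db, "ripple_db", 1e-6, 10)
  assert_scalar_num(passband_edge, "passband_edge", 1)
  assert_scalar_num(fs_out, "fs_out", 1)
  if (passband_edge >= fs_out / 2)
    pe_stop("badarg", "passband_edge (%g Hz) must be below fs_out/2 (%g Hz)",
            passband_edge, fs_out / 2)
  structure(list(filter_order = filter_order, ripple_db = ripple_db,
                 passband_edge = passband_edge, fs_out = fs_out),
            class = "preprocess_params")
}

#' Design a digital lowpass Chebyshev type I filter
#'
#' Analog prototype poles are mapped through the bilinear transform with the
#' passband edge prewarped, so `|H|` at `fc` is exactly `-ripple_db` dB for
#' odd orders.
#'
#' @param order Filter order.
#' @param ripple_db Passband ripple (dB).
#' @param fc Passband edge frequency (Hz).
#' @param fs Sampling rate (Hz).
#' @return List with numerator `b`, denominator `a` (direct-form coefficients,
#'   `a[1] == 1`) plus the design parameters.
#' @export
cheby1_design <- function(order, ripple_db, fc, fs) {
  if (fs < 2 * fc)
    pe_stop("badarg", "sampling rate %g Hz is below 2 x passband edge %g Hz", fs, fc)
  eps <- sqrt(10^(ripple_db / 10) - 1)
  mu <- asinh(1 / eps) / order
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  # unit-cutoff analog prototype poles
  p <- complex(real = -sinh(mu) * sin(theta), imaginary = cosh(mu) * cos(theta))
  gain <- Re(prod(-p))
  if (order %% 2 == 0) gain <- gain / sqrt(1 + eps^2)
  # prewarp the edge and scale the prototype
  warped <- 2 * fs * tan(pi * fc / fs)
  p <- p * warped
  gain <- gain * warped^order
  # bilinear transform: s = 2 fs (z-1)/(z+1); zeros all map to z = -1
  zd <- (2 * fs + p) / (2 * fs - p)
  gd <- gain / Re(prod(2 * fs - p))
  b <- Re(gd * poly_from_roots(rep(-1 + 0i, order)))
  a <- Re(poly_from_roots(zd))
  list(b = b, a = a, order = order, ripple_db = ripple_db, fc = fc, fs = fs)
}

# monic polynomial coefficients (descending powers) from roots
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
  coefs
}

#' Frequency response of a digital filter
#'
#' @param filt List with `b`, `a`, `fs` as returned by [cheby1_design()].
#' @param f Frequencies (Hz) at which to evaluate.
#' @return Complex response `H(f)`.
#' @export
filter_response <- function(filt, f) {
  z <- exp(-1i * 2 * pi * f / filt$fs)
  pb <- vapply(z, function(zi) sum(filt$b * zi^(seq_along(filt$b) - 1)),
               complex(1))
  pa <- vapply(z, function(zi) sum(filt$a * zi^(seq_along(filt$a) - 1)),
               complex(1))
  pb / pa
}

#' Analytic magnitude of the analog Chebyshev type I lowpass
#'
#' `|H(f)|^2 = 1 / (1 + eps^2 T_n(f/fc)^2)` with `T_n` the Chebyshev
#' polynomial. Used as the independent oracle for the digital design (the
#' bilinear warp is negligible far below Nyquist).
#'
#' @param order,ripple_db,fc As in [cheby1_design()].
#' @param f Frequencies (Hz).
#' @return Magnitude `|H(f)|`.
#' @export
cheby1_analog_gain <- function(order, ripple_db, fc, f) {
  eps <- sqrt(10^(ripple_db / 10) - 1)
  x <- f / fc
  tn <- ifelse(abs(x) <= 1, cos(order * acos(x)), cosh(order * acosh(abs(x))))
  1 / sqrt(1 + eps^2 * tn^2)
}

# Single-pass IIR filtering via stats::filter (C loop): FIR part by
# convolution, then the recursive part.
iir_filter <- function(b, a, x) {
  n <- length(x)
  v <- stats::filter(c(numeric(length(b) - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[length(b):(length(b) - 1 + n)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward and backward so the net phase is zero. Edges
#' are protected with odd-reflection padding long enough for the transient of
#' the recursive filter to die out.
#'
#' @param filt Filter as from [cheby1_design()].
#' @param x Numeric signal.
#' @param padlen Reflection pad length in samples (default: 6 time constants
#'   of the slowest pole, capped at `length(x) - 1`).
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(filt, x, padlen = NULL) {
  assert_finite(x, "x")
  n <- length(x)
  if (is.null(padlen)) {
    r <- max(abs(polyroot(rev(filt$a))))
    r <- min(r, 1 - 1e-9)
    padlen <- ceiling(-6 / log(r))
  }
  padlen <- min(padlen, n - 1)
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  y <- c(pre, x, post)
  y <- iir_filter(filt$b, filt$a, y)
  y <- rev(iir_filter(filt$b, filt$a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Filter and downsample a raw LFP trace
#'
#' Zero-phase Chebyshev type I lowpass followed by decimation to
#' `params$fs_out`. Integer decimation ratios take every M-th sample;
#' non-integer ratios are interpolated onto the output grid after filtering
#' (the signal is already band-limited well below the output Nyquist).
#'
#' @param raw_trace Numeric vector, raw samples.
#' @param fs_raw Input sampling rate (Hz).
#' @param params A [preprocess_params()] object.
#' @return Numeric vector of length `floor(length(raw_trace) * fs_out / fs_raw)`
#'   with attributes `fs` and `filter`.
#' @export
preprocess_lfp <- function(raw_trace, fs_raw, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  assert_scalar_num(fs_raw, "fs_raw", 1)
  if (fs_raw < 2 * params$passband_edge)
    pe_stop("badarg", "fs_raw = %g Hz is below 2 x passband edge (%g Hz)",
            fs_raw, 2 * params$passband_edge)
  if (params$fs_out > fs_raw)
    pe_stop("badarg", "fs_out (%g) exceeds fs_raw (%g)", params$fs_out, fs_raw)
  assert_finite(raw_trace, "raw_trace")
  n_out <- floor(length(raw_trace) * params$fs_out / fs_raw)
  filt <- cheby1_design(params$filter_order, params$ripple_db,
                        params$passband_edge, fs_raw)
  y <- filtfilt(filt, raw_trace)
  ratio <- fs_raw / params$fs_out
  if (abs(ratio - round(ratio)) < 1e-9) {
    out <- y[seq(1, by = round(ratio), length.out = n_out)]
  } else {
    t_out <- (seq_len(n_out) - 1) / params$fs_out
    out <- stats::approx(x = (seq_along(y) - 1) / fs_raw, y = y,
                         xout = t_out, rule = 2)$y
  }
  structure(out, fs = params$fs_out, filter = filt[c("order", "ripple_db", "fc")])
}
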