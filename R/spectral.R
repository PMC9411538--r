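# Event-locked normalization and band quantification of spectrograms.

#' Frequency band definitions
#'
#' Theta 4-8, alpha 8-14, beta 14-30 and gamma 30-100 Hz. Bands are half-open
#' `[lo, hi)`: a shared edge belongs to the upper band (8 Hz is alpha, 14 Hz
#' beta, 30 Hz gamma).
#'
#' @return A data frame with columns `band`, `lo`, `hi`.
#' @export
band_table <- function() {
  data.frame(band = c("theta", "alpha", "beta", "gamma"),
             lo = c(4, 8, 14, 30), hi = c(8, 14, 30, 100),
             stringsAsFactors = FALSE)
}

band_row_index <- function(freq, band) {
  bt <- band_table()
  if (!band %in% bt$band)
    pe_stop("badarg", "unknown band '%s' (use one of %s)", band,
            paste(bt$band, collapse = ", "))
  b <- bt[bt$band == band, ]
  idx <- which(freq >= b$lo & freq < b$hi)
  if (!length(idx))
    pe_stop("badarg", "frequency grid has no rows in band '%s'", band)
  idx
}

#' Event-locked, baseline-normalized spectrogram
#'
#' Extracts a `[-pre_window, +post_window]` epoch around each onset from a
#' session spectrogram, normalizes each 0.5-Hz frequency row to its
#' pre-stimulation baseline mean and averages across trials. Values are
#' percent deviations from baseline.
#'
#' With `baseline_mode = "pooled"` (default) the baseline mean of each row is
#' pooled across the trials' baseline windows and the trial-averaged power is
#' normalized by it; with `"per_trial"` every trial is normalized by its own
#' 1-s baseline before averaging (see the methods vignette for the bias
#' implications of the per-trial mode).
#'
#' @param spec A [morlet_spectrogram()] result.
#' @param onsets Stimulation onsets (s, same clock as `spec$time`).
#' @param params A [spectrogram_params()] object (defaults to the one stored
#'   in `spec`).
#' @return Object of class `normalized_spectrogram`: `pct` matrix
#'   (frequency x relative time), `time` (s, onset = 0), `freq`, `n_trials`,
#'   `baseline_mode`.
#' @export
extract_and_normalize <- function(spec, onsets, params = spec$params) {
  stopifnot(inherits(spec, "spectrogram"))
  if (!length(onsets)) pe_stop("badarg", "no onsets supplied")
  fs <- spec$fs
  t0 <- spec$time[1]
  margin <- max(spec$support_s)
  lo_ok <- onsets - params$pre_window - margin >= t0
  hi_ok <- onsets + params$post_window + margin <= spec$time[length(spec$time)]
  if (any(!lo_ok | !hi_ok))
    pe_stop("badonset",
            "onset %.3f s too close to the trace edge (needs %g s + %.2f s wavelet support on each side)",
            onsets[which(!lo_ok | !hi_ok)[1]], params$pre_window, margin)
  rel <- seq(-params$pre_window, params$post_window, by = 1 / fs)
  base_cols <- which(rel >= -params$baseline_window & rel < 0)
  acc <- 0
  base_acc <- 0
  for (on in onsets) {
    j0 <- round((on - t0) * fs) + 1L
    cols <- j0 + round(rel * fs)
    ep <- spec$power[, cols, drop = FALSE]
    if (params$baseline_mode == "per_trial") {
      mu <- rowMeans(ep[, base_cols, drop = FALSE])
      if (any(mu == 0))
        pe_stop("zerobaseline", "baseline mean is zero for frequency row %.1f Hz",
                spec$freq[which(mu == 0)[1]])
      acc <- acc + 100 * (ep - mu) / mu
    } else {
      acc <- acc + ep
      base_acc <- base_acc + rowMeans(ep[, base_cols, drop = FALSE])
    }
  }
  n <- length(onsets)
  if (params$baseline_mode == "per_trial") {
    pct <- acc / n
  } else {
    mu <- base_acc / n
    if (any(mu == 0))
      pe_stop("zerobaseline", "baseline mean is zero for frequency row %.1f Hz",
              spec$freq[which(mu == 0)[1]])
    pct <- 100 * (acc / n - mu) / mu
  }
  structure(list(pct = pct, time = rel, freq = spec$freq, n_trials = n,
                 baseline_mode = params$baseline_mode, params = params),
            class = "normalized_spectrogram")
}

#' @export
print.normalized_spectrogram <- function(x, ...) {
  cat(sprintf("Normalized spectrogram: %d trials, %d frequencies, t in [%g, %g] s\n",
              x$n_trials, length(x$freq), min(x$time), max(x$time)))
  invisible(x)
}

#' Mean band-power change in the post-stimulation window
#'
#' Mean of the normalized (% change) values over the band's frequency rows
#' and `[0, quant_window]` seconds after onset.
#'
#' @param nspec A [extract_and_normalize()] result.
#' @param band Band name (see [band_table()]).
#' @param quant_window Quantification window length (s).
#' @return Scalar percent change.
#' @export
band_power_change <- function(nspec, band,
                              quant_window = nspec$params$quant_window) {
  stopifnot(inherits(nspec, "normalized_spectrogram"))
  rows <- band_row_index(nspec$freq, band)
  cols <- which(nspec$time >= 0 & nspec$time <= quant_window)
  mean(nspec$pct[rows, cols])
}

#' Band time course in 100-ms bins
#'
#' Partitions the epoch into `bin`-second bins and averages the normalized
#' band values per bin. If the bin width does not divide the epoch evenly the
#' trailing partial bin is dropped with a warning.
#'
#' @param nspec A [extract_and_normalize()] result.
#' @param band Band name.
#' @param bin Bin width (s).
#' @param withdrawal_times Optional withdrawal latencies (s, onset-relative)
#'   of the contributing trials; their median is reported as reference.
#' @return Data frame with `bin_center` (s) and `pct`; attribute
#'   `median_withdrawal_time` when latencies are given.
#' @export
band_timecourse <- function(nspec, band, bin = nspec$params$timecourse_bin,
                            withdrawal_times = NULL) {
  stopifnot(inherits(nspec, "normalized_spectrogram"))
  rows <- band_row_index(nspec$freq, band)
  t0 <- nspec$time[1]; t1 <- nspec$time[length(nspec$time)]
  n_bins <- floor((t1 - t0) / bin + 1e-9)
  if (abs(n_bins * bin - (t1 - t0)) > 1e-9)
    pe_warn("bin width %g s does not divide the %g s window evenly; dropping the partial trailing bin",
            bin, t1 - t0)
  edges <- t0 + bin * (0:n_bins)
  # mean per bin over the band-averaged series
  bandmean <- colMeans(nspec$pct[rows, , drop = FALSE])
  bidx <- findInterval(nspec$time, edges, rightmost.closed = TRUE)
  ok <- bidx >= 1 & bidx <= n_bins
  pct <- as.numeric(tapply(bandmean[ok], bidx[ok], mean))
  out <- data.frame(bin_center = (edges[-length(edges)] + edges[-1]) / 2,
                    pct = pct)
  if (!is.null(withdrawal_times))
    attr(out, "median_withdrawal_time") <- stats::median(withdrawal_times)
  out
}

#' Per-force band-power summary across sessions
#'
#' For each session the normalized band change over the post-stimulation
#' quantification window is computed separately for each filament force
#' (withdrawal trials only, unless the session params say otherwise); forces
#' are then aggregated across sessions as mean +/- SEM.
#'
#' @param session_tables A list of per-session data frames as returned by
#'   [session_band_by_force()] (one per animal).
#' @param band Band name.
#' @return Data frame with `force_g`, `mean_pct`, `sem_pct` (NA with a single
#'   session), `n_sessions`.
#' @export
band_power_by_force <- function(session_tables, band) {
  stopifnot(length(session_tables) >= 1)
  all <- do.call(rbind, lapply(seq_along(session_tables), function(i) {
    st <- session_tables[[i]]
    st <- st[st$band == band, c("force_g", "pct")]
    if (nrow(st)) st$session <- i
    st
  }))
  if (is.null(all) || !nrow(all))
    pe_stop("badarg", "no per-force values for band '%s'", band)
  forces <- sort(unique(all$force_g))
  out <- do.call(rbind, lapply(forces, function(f) {
    v <- all$pct[all$force_g == f]
    data.frame(force_g = f, mean_pct = mean(v),
               sem_pct = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n_sessions = length(v))
  }))
  out
}
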