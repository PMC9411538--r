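# Session-level analysis drivers tying preprocessing, spectrograms and unit
# analysis together.

#' Event-locked normalized spectrogram of a recording session
#'
#' Preprocesses the raw LFP, then computes the Morlet power epoch around each
#' (by default withdrawal) trial onset and the baseline-normalized average.
#' Epochs are transformed individually with padding beyond the wavelet
#' support, which is numerically equivalent to transforming the whole trace
#' but keeps memory bounded.
#'
#' @param session A `recording_session` (simulated or loaded).
#' @param params A [spectrogram_params()] object.
#' @param pre_params A [preprocess_params()] object.
#' @param trials Optional replacement trial table (e.g. a force subset).
#' @return A `normalized_spectrogram` (see [extract_and_normalize()]).
#' @export
session_normalized_spectrogram <- function(session,
                                           params = spectrogram_params(),
                                           pre_params = preprocess_params(),
                                           trials = NULL) {
  stopifnot(inherits(session, "recording_session"))
  trials <- trials %||% session$trials
  if (params$withdrawal_only) trials <- trials[trials$withdrawal == 1, ]
  if (!nrow(trials)) pe_stop("badarg", "no trials to analyze")
  lfp <- preprocess_lfp(as.numeric(session$lfp), attr(session$lfp, "fs"),
                        pre_params)
  fs <- attr(lfp, "fs")
  freqs <- spectrogram_freqs(params)
  margin <- max(wavelet_support(freqs, params$n_cycles))
  rel <- seq(-params$pre_window, params$post_window, by = 1 / fs)
  base_cols <- which(rel >= -params$baseline_window & rel < 0)
  acc <- 0; base_acc <- 0
  for (on in trials$onset_s) {
    seg0 <- on - params$pre_window - margin
    seg1 <- on + params$post_window + margin
    i0 <- floor(seg0 * fs) + 1L
    i1 <- ceiling(seg1 * fs) + 1L
    if (i0 < 1 || i1 > length(lfp))
      pe_stop("badonset", "onset %.3f s too close to the trace edge", on)
    spec <- morlet_spectrogram(lfp[i0:i1], fs, params)
    t_seg <- (i0 - 1) / fs                  # segment start time
    cols <- round((on - t_seg) * fs) + 1L + round(rel * fs)
    ep <- spec$power[, cols, drop = FALSE]
    if (params$baseline_mode == "per_trial") {
      mu <- rowMeans(ep[, base_cols, drop = FALSE])
      if (any(mu == 0)) pe_stop("zerobaseline", "zero baseline mean")
      acc <- acc + 100 * (ep - mu) / mu
    } else {
      acc <- acc + ep
      base_acc <- base_acc + rowMeans(ep[, base_cols, drop = FALSE])
    }
  }
  n <- nrow(trials)
  pct <- if (params$baseline_mode == "per_trial") acc / n else {
    mu <- base_acc / n
    if (any(mu == 0)) pe_stop("zerobaseline", "zero baseline mean")
    100 * (acc / n - mu) / mu
  }
  structure(list(pct = pct, time = rel, freq = freqs, n_trials = n,
                 baseline_mode = params$baseline_mode, params = params,
                 withdrawal_latencies = trials$latency_s),
            class = "normalized_spectrogram")
}

#' Per-force band-power table for one session
#'
#' Band change over the post-stimulation quantification window, computed
#' separately for each filament force present among the session's
#' (withdrawal) trials. Forces without analyzable trials are omitted with a
#' warning.
#'
#' @param session A `recording_session`.
#' @param params,pre_params Analysis parameter objects.
#' @return Data frame `force_g`, `band`, `pct`, `n_trials`.
#' @export
session_band_by_force <- function(session, params = spectrogram_params(),
                                  pre_params = preprocess_params()) {
  trials <- session$trials
  if (params$withdrawal_only) trials <- trials[trials$withdrawal == 1, ]
  forces <- sort(unique(session$trials$force_g))
  out <- list()
  for (f in forces) {
    sub <- trials[trials$force_g == f, ]
    if (!nrow(sub)) {
      pe_warn("force %g g has no analyzable trials; omitted", f)
      next
    }
    ns <- session_normalized_spectrogram(session, params, pre_params,
                                         trials = sub)
    for (b in band_table()$band)
      out[[length(out) + 1]] <- data.frame(force_g = f, band = b,
                                           pct = band_power_change(ns, b),
                                           n_trials = nrow(sub))
  }
  do.call(rbind, out)
}

#' Unit response analysis of a recording session
#'
#' @param session A `recording_session`.
#' @param params A [psth_params()] object.
#' @return List of [unit_response()] objects (one per unit).
#' @export
session_unit_responses <- function(session, params = psth_params()) {
  onsets <- session$trials$onset_s[session$trials$withdrawal == 1]
  lapply(seq_along(session$units), function(j)
    unit_response(session$units[[j]]$spike_times, onsets, session$duration,
                  params, unit_id = j))
}

#' Waveform features of all units in a session
#'
#' @param session A `recording_session`.
#' @param baseline_samples See [extract_waveform_features()].
#' @return Data frame of features, one row per unit.
#' @export
session_waveform_features <- function(session, baseline_samples = 10) {
  do.call(rbind, lapply(seq_along(session$units), function(j) {
    u <- session$units[[j]]
    ft <- extract_waveform_features(as.numeric(u$waveform), u$fs_wave,
                                    u$spike_times, session$duration,
                                    baseline_samples)
    cbind(unit_id = j, ft)
  }))
}

#' Detect stimulation onsets from a piezo transducer trace
#'
#' Optional plumbing for sessions without a trial table: onsets are
#' threshold crossings of the absolute piezo signal at `k` standard
#' deviations of a quiescent baseline segment, debounced by a minimum
#' inter-onset interval. The reference workflow takes onsets from the trial
#' table (video + piezo inspection); this detector is a convenience only.
#'
#' @param trace Piezo signal.
#' @param fs Sampling rate (Hz).
#' @param k Threshold in baseline SDs.
#' @param quiescent Indices (or logical mask) of a quiescent segment used
#'   for the baseline statistics; defaults to the first second.
#' @param min_interval Minimum spacing between onsets (s).
#' @return Onset times (s).
#' @export
detect_onsets_piezo <- function(trace, fs, k = 5, quiescent = NULL,
                                min_interval = 1) {
  assert_finite(trace, "trace")
  if (is.null(quiescent)) quiescent <- seq_len(min(length(trace), fs))
  base <- trace[quiescent]
  thr <- mean(base) + k * stats::sd(base)
  above <- abs(trace - mean(base)) > abs(thr - mean(base))
  idx <- which(above & !c(FALSE, above[-length(above)]))  # rising edges
  if (!length(idx)) return(numeric(0))
  out <- idx[1]
  for (j in idx[-1]) if (j - out[length(out)] >= min_interval * fs)
    out <- c(out, j)
  (out - 1) / fs
}
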