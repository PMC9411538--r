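# Detection of stimulation-responsive single units.
#
# Firing of each withdrawal trial is aligned to the stimulation onset,
# binned at 250 ms over [-3, +3] s, averaged across trials, and each
# post-stimulation bin is z-scored against the 3-s pre-stimulation baseline.
# A unit is excited (inhibited) if at least one post bin exceeds +3.09
# (-3.09), the two-sided normal critical value for P < 0.001 per bin.

#' PSTH and response-detection parameters
#'
#' @param bin_width Bin width (s).
#' @param pre_window,post_window Seconds before/after onset (integer
#'   multiples of `bin_width`).
#' @param z_threshold Per-bin z threshold (3.09 corresponds to P < 0.001).
#' @param min_rate Minimum session mean firing rate (Hz) for inclusion.
#' @param min_trials Minimum number of withdrawal trials for inclusion.
#' @param baseline_stat `"pooled"` (default): baseline mean and SD estimated
#'   from the per-trial baseline bin rates, with the SD scaled to the
#'   standard error of a trial-averaged bin (and the baseline-mean
#'   uncertainty propagated), so the per-bin statistic is calibrated against
#'   the stated threshold/significance correspondence. `"bins"`: mean and
#'   sample SD of the 12 baseline bins of the trial-averaged PSTH.
#' @return A list of class `psth_params`.
#' @export
psth_params <- function(bin_width = 0.25, pre_window = 3, post_window = 3,
                        z_threshold = 3.09, min_rate = 1, min_trials = 3,
                        baseline_stat = c("pooled", "bins")) {
  baseline_stat <- match.arg(baseline_stat)
  if (abs(pre_window / bin_width - round(pre_window / bin_width)) > 1e-9 ||
      abs(post_window / bin_width - round(post_window / bin_width)) > 1e-9)
    pe_stop("badarg", "windows must be integer multiples of bin_width")
  if (z_threshold <= 0) pe_stop("badarg", "z_threshold must be > 0")
  structure(list(bin_width = bin_width, pre_window = pre_window,
                 post_window = post_window, z_threshold = z_threshold,
                 min_rate = min_rate, min_trials = min_trials,
                 baseline_stat = baseline_stat),
            class = "psth_params")
}

#' Peri-stimulus time histogram
#'
#' Counts per bin per trial, converted to firing rate (Hz) and averaged
#' across trials. Trials whose window extends past the recording are dropped
#' with a warning.
#'
#' @param spike_times Sorted spike times (s).
#' @param onsets Stimulation onsets (s).
#' @param params A [psth_params()] object.
#' @param t_max Optional recording end time (s) used to validate windows.
#' @return Object of class `psth`: `rate` (Hz per bin, trial-averaged),
#'   `bin_centers` (s, onset-relative), `counts` (trials x bins matrix),
#'   `n_trials`, `params`.
#' @export
compute_psth <- function(spike_times, onsets, params = psth_params(),
                         t_max = NULL) {
  stopifnot(inherits(params, "psth_params"))
  if (!length(onsets)) pe_stop("badarg", "at least one onset is required")
  if (is.unsorted(spike_times)) pe_stop("unsorted", "spike times must be sorted")
  drop <- onsets - params$pre_window < 0
  if (!is.null(t_max)) drop <- drop | onsets + params$post_window > t_max
  if (any(drop)) {
    pe_warn("%d trial(s) dropped: window extends past the recording", sum(drop))
    onsets <- onsets[!drop]
    if (!length(onsets)) pe_stop("badarg", "no trials left after dropping")
  }
  nb <- round((params$pre_window + params$post_window) / params$bin_width)
  edges_rel <- -params$pre_window + params$bin_width * (0:nb)
  counts <- t(vapply(onsets, function(on) {
    idx <- findInterval(spike_times, on + edges_rel,
                        rightmost.closed = FALSE, left.open = FALSE)
    tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
  }, numeric(nb)))
  rate <- colMeans(counts) / params$bin_width
  structure(list(rate = rate,
                 bin_centers = (edges_rel[-1] + edges_rel[-(nb + 1)]) / 2,
                 counts = counts, n_trials = length(onsets), params = params),
            class = "psth")
}

#' Z-score the post-stimulation PSTH bins against the baseline
#'
#' Baseline statistics come from the pre-stimulation window (see
#' `baseline_stat` in [psth_params()]). If the baseline SD is zero the unit
#' cannot be scored and `NULL` is returned (caller labels it excluded).
#'
#' @param psth A [compute_psth()] result.
#' @param params A [psth_params()] object.
#' @return Numeric z per post-stimulation bin (names are bin centers), or
#'   `NULL` when the baseline SD is zero.
#' @export
zscore_psth <- function(psth, params = psth$params) {
  stopifnot(inherits(psth, "psth"))
  pre <- psth$bin_centers < 0
  post <- psth$bin_centers > 0
  if (params$baseline_stat == "bins") {
    mu <- mean(psth$rate[pre])
    sdev <- stats::sd(psth$rate[pre])       # sample SD, n-1, over the 12 bins
    if (!is.finite(sdev) || sdev == 0) return(NULL)
    z <- (psth$rate[post] - mu) / sdev
  } else {
    base <- psth$counts[, pre, drop = FALSE] / params$bin_width
    mu <- mean(base)
    s1 <- stats::sd(as.numeric(base))       # per-trial bin rate SD
    if (!is.finite(s1) || s1 == 0) return(NULL)
    n <- psth$n_trials
    nb <- sum(pre)
    # SE of (trial-averaged bin - pooled baseline mean)
    se <- s1 * sqrt(1 / n + 1 / (n * nb))
    z <- (psth$rate[post] - mu) / se
  }
  names(z) <- psth$bin_centers[post]
  z
}

#' Classify a unit's response from its post-stimulation z-scores
#'
#' Excited if any post bin exceeds `+z_threshold`, inhibited if any falls
#' below `-z_threshold`; when both occur the direction of the larger `|z|`
#' wins and the unit is flagged mixed. Otherwise unresponsive.
#'
#' @param z Post-bin z-scores from [zscore_psth()] (or `NULL`).
#' @param params A [psth_params()] object.
#' @return Character label, attribute `mixed` when both directions crossed.
#' @export
classify_response <- function(z, params = psth_params()) {
  if (is.null(z)) return("excluded")
  up <- any(z > params$z_threshold)
  down <- any(z < -params$z_threshold)
  label <- if (up && down) {
    if (max(z) >= abs(min(z))) "excited" else "inhibited"
  } else if (up) "excited" else if (down) "inhibited" else "unresponsive"
  if (up && down) attr(label, "mixed") <- TRUE
  label
}

#' Inclusion filter for the response analysis
#'
#' A unit enters the analysis iff its session mean firing rate is at least
#' `min_rate` (1.0 Hz included) and the number of withdrawal trials is at
#' least `min_trials` (exactly 3 included).
#'
#' @param spike_times Unit spike times (s).
#' @param duration Session duration (s).
#' @param n_withdrawal_trials Number of withdrawal trials.
#' @param params A [psth_params()] object.
#' @return Logical.
#' @export
apply_inclusion <- function(spike_times, duration, n_withdrawal_trials,
                            params = psth_params()) {
  mean_rate <- length(spike_times) / duration
  mean_rate >= params$min_rate && n_withdrawal_trials >= params$min_trials
}

#' Full response analysis of one unit
#'
#' @param spike_times Unit spike times (s).
#' @param onsets Withdrawal-trial onsets (s).
#' @param duration Session duration (s).
#' @param params A [psth_params()] object.
#' @param unit_id Identifier carried through to the result.
#' @return Object of class `unit_response`: `unit_id`, `label`, `z`
#'   (post-bin z-scores or NULL), `z_max`/`z_min` (defined for
#'   excited/inhibited respectively, else NA), `psth`, `included`, `mixed`.
#' @export
unit_response <- function(spike_times, onsets, duration,
                          params = psth_params(), unit_id = NA) {
  included <- apply_inclusion(spike_times, duration, length(onsets), params)
  if (!included)
    return(structure(list(unit_id = unit_id, label = "excluded", z = NULL,
                          z_max = NA_real_, z_min = NA_real_, psth = NULL,
                          included = FALSE, mixed = FALSE),
                     class = "unit_response"))
  ps <- compute_psth(spike_times, onsets, params, t_max = duration)
  z <- zscore_psth(ps, params)
  label <- classify_response(z, params)
  structure(list(
    unit_id = unit_id, label = as.character(label), z = z,
    z_max = if (identical(as.character(label), "excited")) max(z) else NA_real_,
    z_min = if (identical(as.character(label), "inhibited")) min(z) else NA_real_,
    psth = ps, included = !identical(as.character(label), "excluded"),
    mixed = isTRUE(attr(label, "mixed"))), class = "unit_response")
}

#' Response-magnitude summary across units
#'
#' Maximal z of excited units and minimal z of inhibited units, optionally
#' grouped (e.g. by condition or waveform class).
#'
#' @param responses List of [unit_response()] objects.
#' @param groups Optional grouping vector, same length as `responses`.
#' @return Data frame `group`, `label`, `n`, `mean_z`, `sem_z`; zero rows
#'   (with the full column set) when no responsive units exist.
#' @export
response_magnitudes <- function(responses, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(responses))
  rows <- list()
  for (g in unique(groups)) {
    sub <- responses[groups == g]
    for (lab in c("excited", "inhibited")) {
      v <- vapply(sub, function(r) {
        if (identical(r$label, lab))
          if (lab == "excited") r$z_max else r$z_min
        else NA_real_
      }, numeric(1))
      v <- v[!is.na(v)]
      if (length(v))
        rows[[length(rows) + 1]] <- data.frame(
          group = g, label = lab, n = length(v), mean_z = mean(v),
          sem_z = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
    }
  }
  if (!length(rows))
    return(data.frame(group = character(0), label = character(0),
                      n = integer(0), mean_z = numeric(0), sem_z = numeric(0)))
  do.call(rbind, rows)
}
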