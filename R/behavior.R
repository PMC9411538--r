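# Behavioral quantification: Dixon up-down withdrawal thresholds, per-force
# stimulus-response curves, thermal latencies, nocifensive durations.

#' Mean log10 step of a filament set
#'
#' The 7-filament von Frey series is not exactly log-uniform; the up-down
#' step constant delta is taken as the mean log10 inter-filament spacing.
#'
#' @param filament_set Ordered forces (g).
#' @return Scalar delta (log10 g).
#' @export
updown_delta <- function(filament_set) {
  mean(diff(log10(filament_set)))
}

#' 50% withdrawal threshold from an up-down sequence
#'
#' Dixon's up-down estimator on the ordered filament set. Boundary
#' conventions: an all-positive sequence returns the lowest force, an
#' all-negative sequence the highest. Otherwise the threshold is
#' `10^mu` with `mu` the maximum-likelihood 50% point of a probit
#' psychometric in log10 force whose spread is fixed at the step constant
#' delta — the construction underlying the published pattern/k tables; the
#' equivalent correction constant `k = (mu - x_f)/delta` relative to the
#' final force `x_f` is reported alongside. Estimates are clamped to the
#' force range of the set.
#'
#' @param forces Presented forces (g), in order.
#' @param responses 0/1 responses, same length.
#' @param filament_set The ordered force set used for stepping.
#' @param validate Check the up-down stepping structure of the sequence.
#' @return List: `threshold_g`, `k`, `delta`, `final_force_g`, `boundary`
#'   (`"low"`, `"high"` or `NA`).
#' @export
updown_threshold <- function(forces, responses,
                             filament_set = c(0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4),
                             validate = TRUE) {
  n <- length(forces)
  stopifnot(length(responses) == n, n >= 1)
  if (!all(forces %in% filament_set))
    pe_stop("badarg", "presented force %g g is not in the filament set",
            forces[which(!forces %in% filament_set)[1]])
  idx <- match(forces, filament_set)
  if (validate && n > 1) {
    for (j in seq_len(n - 1)) {
      expect <- idx[j] + if (responses[j] == 1) -1L else 1L
      if (idx[j + 1] != expect)
        pe_stop("badsequence",
                "malformed up-down stepping at presentation %d: force %g g followed by %g g after a %s response",
                j, forces[j], forces[j + 1],
                if (responses[j] == 1) "positive" else "negative")
    }
  }
  delta <- updown_delta(filament_set)
  xf <- log10(forces[n])
  if (all(responses == 1))
    return(list(threshold_g = min(filament_set), k = NA_real_, delta = delta,
                final_force_g = forces[n], boundary = "low"))
  if (all(responses == 0))
    return(list(threshold_g = max(filament_set), k = NA_real_, delta = delta,
                final_force_g = forces[n], boundary = "high"))
  x <- log10(forces)
  negll <- function(mu) {
    p <- stats::pnorm((x - mu) / delta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(responses * log(p) + (1 - responses) * log(1 - p))
  }
  lo <- log10(min(filament_set)) - 5 * delta
  hi <- log10(max(filament_set)) + 5 * delta
  mu <- stats::optimize(negll, c(lo, hi), tol = 1e-9)$minimum
  thr <- min(max(10^mu, min(filament_set)), max(filament_set))
  list(threshold_g = thr, k = (mu - xf) / delta, delta = delta,
       final_force_g = forces[n], boundary = NA_character_)
}

#' Stimulus-response curve from a trial table
#'
#' Percent positive responses per filament force. With a `group` column the
#' curve is computed per group level (e.g. laser ON/OFF).
#'
#' @param trials Data frame with `force_g` and a 0/1 response column.
#' @param response_col Name of the response column.
#' @param group Optional grouping column name.
#' @return Data frame `force_g` (, `group`), `n_presented`, `n_positive`,
#'   `percent`.
#' @export
response_curve <- function(trials, response_col = "withdrawal", group = NULL) {
  stopifnot(is.data.frame(trials), response_col %in% names(trials))
  split_by <- if (is.null(group)) list(trials$force_g)
              else list(trials$force_g, trials[[group]])
  agg <- aggregate(trials[[response_col]], by = split_by,
                   FUN = function(v) c(n = length(v), pos = sum(v)))
  out <- data.frame(force_g = agg[[1]])
  if (!is.null(group)) out$group <- agg[[2]]
  out$n_presented <- agg$x[, "n"]
  out$n_positive <- agg$x[, "pos"]
  out$percent <- 100 * out$n_positive / out$n_presented
  out[order(if (is.null(group)) out$force_g else paste(out$group, out$force_g)), ]
}

#' Aggregate per-animal response curves as group mean +/- SEM
#'
#' @param curves List of [response_curve()] results (one per animal).
#' @return Data frame `force_g`, `mean_percent`, `sem_percent`, `n_animals`.
#' @export
response_curve_summary <- function(curves) {
  all <- do.call(rbind, lapply(seq_along(curves), function(i)
    cbind(curves[[i]][, c("force_g", "percent")], animal = i)))
  forces <- sort(unique(all$force_g))
  do.call(rbind, lapply(forces, function(f) {
    v <- all$percent[all$force_g == f]
    data.frame(force_g = f, mean_percent = mean(v),
               sem_percent = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n_animals = length(v))
  }))
}

#' Thermal withdrawal latency summary
#'
#' Latencies are censored at the cutoff (values above it are clipped with a
#' warning) and averaged per animal/condition.
#'
#' @param latencies Withdrawal latencies (s).
#' @param cutoff Cutoff time (s).
#' @return List `mean_latency_s`, `n_trials`, `n_censored`, `censored`.
#' @export
thermal_latency_summary <- function(latencies, cutoff = 30) {
  stopifnot(length(latencies) >= 1, all(is.finite(latencies)))
  over <- latencies > cutoff
  if (any(over))
    pe_warn("%d latency value(s) above the %g s cutoff clipped", sum(over), cutoff)
  lat <- pmin(latencies, cutoff)
  list(mean_latency_s = mean(lat), n_trials = length(lat),
       n_censored = sum(lat == cutoff), censored = any(lat == cutoff))
}

#' Total nocifensive behavior duration in an observation window
#'
#' Overlapping behavior intervals are merged, clipped to `[0, window]`, and
#' their total length returned.
#'
#' @param intervals Two-column matrix or data frame of `(start, end)` times (s).
#' @param window Observation window length (s).
#' @return Total duration (s).
#' @export
nocifensive_duration <- function(intervals, window = 300) {
  m <- as.matrix(intervals)
  if (!nrow(m)) return(0)
  stopifnot(ncol(m) == 2)
  if (any(m[, 2] < m[, 1])) pe_stop("badarg", "interval end before start")
  m[, 1] <- pmax(m[, 1], 0)
  m[, 2] <- pmin(m[, 2], window)
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (!nrow(m)) return(0)
  m <- m[order(m[, 1]), , drop = FALSE]
  total <- 0; cur <- m[1, ]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= cur[2]) cur[2] <- max(cur[2], m[i, 2])
    else { total <- total + cur[2] - cur[1]; cur <- m[i, ] }
  }
  total + cur[2] - cur[1]
}
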