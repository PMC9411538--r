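# Waveform feature extraction and unit-type classification.
#
# Six parameters per unit: firing rate, ISI coefficient of variation,
# peak-to-peak amplitude, time between early and late waveform peaks, time
# from trough to the return to baseline, and waveform asymmetry (difference
# of the baseline-to-early-peak and late-peak-to-return times over their
# sum). Final classification uses k-means (k = 2) on the standardized
# (asymmetry, trough-to-return) pair; the cluster with the larger mean
# trough-to-return time is class 1 (broad), the other class 2 (narrow).

#' Extract waveform and firing features of a unit
#'
#' Landmarks: baseline is the mean of the first `baseline_samples` samples;
#' the trough is the global minimum; the early/late peaks are the maxima
#' before/after the trough; departure-from- and return-to-baseline times are
#' found by linear interpolation of the baseline-level crossings adjacent to
#' the early peak and following the late peak.
#'
#' @param mean_waveform Numeric waveform.
#' @param fs_wave Waveform sampling rate (Hz).
#' @param spike_times Spike times (s) for rate and ISI statistics; optional.
#' @param duration Session duration (s), needed with `spike_times`.
#' @param baseline_samples Samples defining the baseline level.
#' @return Object of class `waveform_features` (a one-row data frame):
#'   `firing_rate`, `isi_cv`, `peak_to_peak`, `peak_to_peak_time`,
#'   `trough_to_return`, `asymmetry`, `unclassifiable`.
#' @export
extract_waveform_features <- function(mean_waveform, fs_wave,
                                      spike_times = NULL, duration = NULL,
                                      baseline_samples = 10) {
  w <- as.numeric(mean_waveform)
  n <- length(w)
  if (n < baseline_samples + 5)
    pe_stop("badarg", "waveform too short (%d samples)", n)
  base <- mean(w[seq_len(baseline_samples)])
  it <- which.min(w)
  bad <- function() data.frame(firing_rate = NA_real_, isi_cv = NA_real_,
                               peak_to_peak = NA_real_,
                               peak_to_peak_time = NA_real_,
                               trough_to_return = NA_real_,
                               asymmetry = NA_real_, unclassifiable = TRUE)
  if (it <= 2 || it >= n - 1) return(structure(bad(), class = c("waveform_features", "data.frame")))
  ie <- which.max(w[1:(it - 1)])
  il <- it + which.max(w[(it + 1):n])
  if (w[ie] <= base || w[il] <= base)
    return(structure(bad(), class = c("waveform_features", "data.frame")))
  cross_down <- function(i_from, level) {
    # first index j > i_from with w crossing below level; interpolated
    for (j in seq(i_from, n - 1)) {
      if (w[j] >= level && w[j + 1] < level)
        return(j + (w[j] - level) / (w[j] - w[j + 1]))
    }
    NA_real_
  }
  cross_up_before <- function(i_to, level) {
    # last index j < i_to with w crossing above level; interpolated
    for (j in seq(i_to - 1, 1)) {
      if (w[j] <= level && w[j + 1] > level)
        return(j + (level - w[j]) / (w[j + 1] - w[j]))
    }
    NA_real_
  }
  dep <- cross_up_before(ie, base)           # baseline departure before early peak
  ret <- cross_down(il, base)                # return to baseline after late peak
  t_ret_from_trough <- {
    r2 <- NA_real_
    for (j in seq(it, n - 1)) {
      if (w[j] < base && w[j + 1] >= base) { r2 <- j + (base - w[j]) / (w[j + 1] - w[j]); break }
    }
    r2
  }
  if (is.na(dep) || is.na(ret) || is.na(t_ret_from_trough))
    return(structure(bad(), class = c("waveform_features", "data.frame")))
  dt <- 1 / fs_wave
  t1 <- (ie - dep) * dt                      # baseline -> early peak
  t2 <- (ret - il) * dt                      # late peak -> return
  fr <- NA_real_; cv <- NA_real_
  if (!is.null(spike_times) && length(spike_times) > 2) {
    if (is.null(duration)) duration <- max(spike_times)
    fr <- length(spike_times) / duration
    isi <- diff(spike_times)
    cv <- stats::sd(isi) / mean(isi)
  }
  structure(data.frame(
    firing_rate = fr, isi_cv = cv,
    peak_to_peak = w[il] - w[it],
    peak_to_peak_time = (il - ie) * dt,
    trough_to_return = (t_ret_from_trough - it) * dt,
    asymmetry = (t1 - t2) / (t1 + t2),
    unclassifiable = FALSE), class = c("waveform_features", "data.frame"))
}

#' Classify units into broad (class 1) and narrow (class 2) types
#'
#' `mode = "final"` (default): k-means with k = 2 on the standardized
#' asymmetry and trough-to-return features. `mode = "exploratory"`: all six
#' features are standardized, embedded in 2-D with t-SNE, then k-means
#' clustered. Either way the cluster with the larger mean trough-to-return
#' is labeled class 1.
#'
#' @param features Data frame of [extract_waveform_features()] rows.
#' @param mode `"final"` or `"exploratory"`.
#' @param seed Seed for k-means restarts and the t-SNE embedding.
#' @param perplexity t-SNE perplexity; defaults to 30, or n/4 for fewer than
#'   120 units.
#' @return Integer vector of class labels (1 = broad, 2 = narrow); NA for
#'   unclassifiable units. Attribute `embedding` in exploratory mode.
#' @export
cluster_unit_types <- function(features, mode = c("final", "exploratory"),
                               seed = 1L, perplexity = NULL) {
  mode <- match.arg(mode)
  ok <- !features$unclassifiable
  if (sum(ok) < 2) pe_stop("badarg", "need at least 2 classifiable units")
  cols <- if (mode == "final") c("asymmetry", "trough_to_return")
          else c("firing_rate", "isi_cv", "peak_to_peak",
                 "peak_to_peak_time", "trough_to_return", "asymmetry")
  X <- as.matrix(features[ok, cols])
  if (anyNA(X)) pe_stop("badarg", "features contain NA for classifiable units")
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) pe_stop("degenerate", "all features identical; no cluster structure")
  Xs <- scale(X[, sds > 0, drop = FALSE])
  emb <- NULL
  if (mode == "exploratory") {
    if (is.null(perplexity))
      perplexity <- if (nrow(Xs) < 120) max(2, floor(nrow(Xs) / 4)) else 30
    emb <- tsne_embed(Xs, perplexity = perplexity, seed = seed)
    Xs <- emb
  }
  cluster <- if (nrow(Xs) == 2) 1:2   # k-means needs k < n; trivial split
  else with_seed(seed, stats::kmeans(Xs, centers = 2, nstart = 50,
                                     iter.max = 100))$cluster
  ttr <- features$trough_to_return[ok]
  m1 <- mean(ttr[cluster == 1]); m2 <- mean(ttr[cluster == 2])
  lab <- if (m1 >= m2) c(1L, 2L)[cluster] else c(2L, 1L)[cluster]
  out <- rep(NA_integer_, nrow(features))
  out[ok] <- lab
  if (!is.null(emb)) attr(out, "embedding") <- emb
  out
}

#' Exact t-SNE embedding (2-D)
#'
#' Small-n exact implementation (O(n^2)): Gaussian input affinities with
#' per-point bandwidth matched to the target perplexity by bisection,
#' Student-t low-dimensional kernel, gradient descent with momentum and
#' early exaggeration. Deterministic given the seed.
#'
#' @param X Numeric matrix (rows = units).
#' @param perplexity Target perplexity.
#' @param n_iter Gradient-descent iterations.
#' @param seed Seed for the random initialization.
#' @return n x 2 embedding matrix.
#' @export
tsne_embed <- function(X, perplexity = 30, n_iter = 400, seed = 1L) {
  n <- nrow(X)
  if (perplexity >= n) perplexity <- max(2, floor((n - 1) / 3))
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { beta <- beta / 2; next }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else { betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  Y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  dY <- matrix(0, n, 2); gains <- matrix(1, n, 2); update <- matrix(0, n, 2)
  eta <- 200
  for (iter in seq_len(n_iter)) {
    mult <- if (iter <= 100) 4 else 1       # early exaggeration
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (mult * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(update), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    update <- momentum * update - eta * gains * grad
    Y <- Y + update
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
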