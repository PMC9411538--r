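# Morlet spectrograms, event-locked normalization and band quantification.

test_that("zero trace gives zero power; frequency guard works", {
  sp <- morlet_spectrogram(numeric(4000), 1000)
  expect_true(all(sp$power == 0))
  expect_error(morlet_spectrogram(numeric(4000), 150), "fs/2")
})

test_that("pure tones peak at their own frequency row (periodogram oracle)", {
  fs <- 1000
  t <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * 20 * t)
  sp <- morlet_spectrogram(x, fs)
  valid <- sp$time > 3 & sp$time < 17
  peaks <- sp$freq[apply(sp$power[, valid], 2, which.max)]
  expect_true(all(peaks == 20))
  # power at the tone row equals amplitude^2
  expect_equal(mean(sp$power[sp$freq == 20, valid]), 1, tolerance = 1e-3)

  # two tones -> two local maxima at 10 and 60 Hz; cross-checked against the
  # smoothed-periodogram oracle
  x2 <- sin(2 * pi * 10 * t) + 0.7 * sin(2 * pi * 60 * t)
  sp2 <- morlet_spectrogram(x2, fs)
  prof <- rowMeans(sp2$power[, valid])
  locmax <- which(diff(sign(diff(prof))) == -2) + 1
  expect_setequal(sp2$freq[locmax], c(10, 60))
  # periodogram oracle: within each band neighbourhood the raw-spectrum peak
  # sits at the same frequency
  pg <- spec.pgram(x2, plot = FALSE, taper = 0)
  fhz <- pg$freq * fs
  for (f0 in c(10, 60)) {
    win <- fhz > f0 - 5 & fhz < f0 + 5
    expect_equal(fhz[win][which.max(pg$spec[win])], f0, tolerance = 0.01)
  }
})

test_that("Morlet power of white noise is flat across frequency", {
  set.seed(11)
  fs <- 1000
  x <- rnorm(60 * fs)
  sp <- morlet_spectrogram(x, fs, spectrogram_params(freq_range = c(20, 90)))
  valid <- sp$time > 3 & sp$time < 57
  prof <- rowMeans(sp$power[, valid])
  # for a flat spectrum the expected row power is 2 S1 sqrt(pi) sigma_f with
  # sigma_f = f / n_cycles (the wavelet's known bandwidth bias); estimate the
  # noise floor S1 independently with a smoothed periodogram
  pg <- spec.pgram(x, spans = 31, plot = FALSE, taper = 0)
  floor_est <- 2 * mean(pg$spec[pg$freq * fs > 20 & pg$freq * fs < 90]) / fs
  sigma_f <- sp$freq / sp$params$n_cycles
  pred <- 2 * floor_est * sqrt(pi) * sigma_f
  expect_lt(abs(mean(prof / pred) - 1), 0.05)
  expect_lt(max(abs(prof / pred - 1)), 0.20)
})

test_that("extract_and_normalize: baseline invariants and trivial cases", {
  set.seed(4)
  fs <- 1000
  x <- rnorm(40 * fs)
  p <- spectrogram_params(baseline_mode = "per_trial")
  sp <- morlet_spectrogram(x, fs, p)
  onsets <- c(10, 20, 30)
  ns <- extract_and_normalize(sp, onsets, p)
  expect_s3_class(ns, "normalized_spectrogram")
  # per-trial mode: baseline-window mean is 0 for the average too
  base_cols <- ns$time >= -1 & ns$time < 0
  expect_equal(max(abs(rowMeans(ns$pct[, base_cols]))), 0, tolerance = 1e-9)
  expect_true(all(ns$pct >= -100 - 1e-9))   # -100% is the floor

  # pooled mode: baseline mean of the averaged matrix is 0 by construction
  p2 <- spectrogram_params()
  ns2 <- extract_and_normalize(sp, onsets, p2)
  expect_equal(max(abs(rowMeans(ns2$pct[, base_cols]))), 0, tolerance = 1e-9)

  # onset too close to the edge is rejected with a message
  expect_error(extract_and_normalize(sp, c(1.5), p), "too close")
})

test_that("normalization is idempotent on its power-equivalent reconstruction", {
  set.seed(5)
  fs <- 1000
  x <- rnorm(30 * fs)
  p <- spectrogram_params()
  sp <- morlet_spectrogram(x, fs, p)
  ns <- extract_and_normalize(sp, c(10, 18), p)
  # reconstruct power with unit baseline mean per row, re-normalize
  sp2 <- sp
  rel <- seq(-p$pre_window, p$post_window, by = 1 / fs)
  recon <- 1 + ns$pct / 100
  j0 <- round(10 * fs) + 1L
  sp2$power <- matrix(1, nrow(recon), length(sp$time))
  sp2$power[, j0 + round(rel * fs)] <- recon
  ns2 <- extract_and_normalize(sp2, 10, p)
  expect_equal(ns2$pct, ns$pct, tolerance = 1e-9)
})

test_that("band quantification: arithmetic and internal consistency", {
  p <- spectrogram_params()
  freq <- spectrogram_freqs(p)
  tm <- seq(-3, 3, by = 0.001)
  m <- matrix(0, length(freq), length(tm))
  ns <- structure(list(pct = m, time = tm, freq = freq, n_trials = 1,
                       baseline_mode = "pooled", params = p),
                  class = "normalized_spectrogram")
  expect_equal(band_power_change(ns, "gamma"), 0)
  # +50% on gamma rows only
  ns$pct[freq >= 30, ] <- 50
  expect_equal(band_power_change(ns, "gamma"), 50)
  expect_equal(band_power_change(ns, "beta"), 0)
  # band edges are half-open: the 30 Hz row is gamma, 29.5 Hz beta
  expect_true(30 %in% freq[painephys:::band_row_index(freq, "gamma")])
  expect_false(30 %in% freq[painephys:::band_row_index(freq, "beta")])

  # constant +20%: every timecourse bin is 20
  ns$pct[] <- 20
  tc <- band_timecourse(ns, "alpha")
  expect_equal(tc$pct, rep(20, nrow(tc)))
  expect_equal(nrow(tc), 60)               # 6 s / 0.1 s

  # step 0 -> 100 at onset
  ns$pct[] <- 0
  ns$pct[, tm > 0] <- 100
  tc <- band_timecourse(ns, "beta")
  expect_true(all(tc$pct[tc$bin_center < -0.05] == 0))
  expect_true(all(abs(tc$pct[tc$bin_center > 0.1] - 100) < 1e-9))

  # median withdrawal time reference
  tc <- band_timecourse(ns, "beta", withdrawal_times = c(0.2, 0.4, 0.9))
  expect_equal(attr(tc, "median_withdrawal_time"), 0.4)

  # partial trailing bin dropped with a warning
  expect_warning(band_timecourse(ns, "beta", bin = 0.7), "partial")
})

test_that("timecourse post-window mean equals band_power_change", {
  set.seed(6)
  s <- simulate_session(tiny_session_config(seed = 6, gamma_gain = 2))
  ns <- session_normalized_spectrogram(s)
  tc <- band_timecourse(ns, "gamma")
  post <- tc$pct[tc$bin_center > 0 & tc$bin_center < 2]
  expect_equal(mean(post), band_power_change(ns, "gamma"), tolerance = 0.01)
})

test_that("per-force table and cross-session aggregation", {
  s <- simulate_session(tiny_session_config(seed = 8))
  tab <- session_band_by_force(s)
  expect_setequal(unique(tab$force_g), c(0.6, 1.0))
  expect_setequal(unique(tab$band), band_table()$band)
  agg1 <- band_power_by_force(list(tab), "gamma")
  expect_true(all(is.na(agg1$sem_pct)))     # single animal -> SEM not available
  agg2 <- band_power_by_force(list(tab, tab), "gamma")
  expect_equal(agg2$sem_pct, rep(0, nrow(agg2)))
  expect_equal(agg2$mean_pct, agg1$mean_pct)
})
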