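# PSTH computation, z-scoring and response classification.

test_that("compute_psth recovers regular and empty trains", {
  p <- psth_params()
  onsets <- c(10, 20, 30)
  # regular train whose period divides the bin width: every bin at the rate
  st <- seq(0.025, 40, by = 0.05)            # 20 Hz, 5 spikes per 250-ms bin
  ps <- compute_psth(st, onsets, p)
  expect_equal(ps$rate, rep(20, 24), tolerance = 1e-9)
  expect_equal(length(ps$bin_centers), 24)
  # no spikes
  ps0 <- compute_psth(numeric(0), onsets, p)
  expect_true(all(ps0$rate == 0))
  # trial extending past the recording is dropped with a warning
  expect_warning(ps2 <- compute_psth(st, c(10, 39.5), p, t_max = 40), "dropped")
  expect_equal(ps2$n_trials, 1)
  expect_error(compute_psth(c(2, 1), onsets, p), "sorted")
})

test_that("Poisson PSTH bins match the rate within 4 sigma", {
  onsets <- 5 + (0:49) * 6.5
  dur <- max(onsets) + 4
  st <- simulate_spike_train(unit_spec(20), numeric(0), dur, seed = 77)
  ps <- compute_psth(st, onsets, psth_params(), t_max = dur)
  sigma <- sqrt(20 / 0.25) / sqrt(50)
  expect_true(all(abs(ps$rate - 20) < 4 * sigma + 0.5))
})

test_that("zscore conventions: bins mode matches the hand-worked oracle", {
  p <- psth_params(baseline_stat = "bins")
  # trial-averaged baseline alternating 4,6 Hz; one post bin at 10 Hz
  counts <- matrix(0, nrow = 4, ncol = 24)
  base_rates <- rep(c(4, 6), 6)
  for (b in 1:12) counts[, b] <- base_rates[b] * 0.25
  counts[, 13] <- 10 * 0.25
  ps <- structure(list(rate = colMeans(counts) / 0.25,
                       bin_centers = seq(-2.875, 2.875, by = 0.25),
                       counts = counts, n_trials = 4, params = p),
                  class = "psth")
  z <- zscore_psth(ps, p)
  # sample SD (n-1) of the 12 baseline bins is 1.0445, not 1
  expect_equal(unname(z[1]), (10 - 5) / sd(base_rates), tolerance = 1e-12)
  # degenerate: all bins equal -> NULL -> excluded
  ps$rate[] <- 5; ps$counts[] <- 5 * 0.25
  expect_null(zscore_psth(ps, p))
  expect_identical(classify_response(NULL, p), "excluded")
})

test_that("z is invariant to adding or scaling baseline rates", {
  onsets <- 5 + (0:19) * 6.5
  dur <- max(onsets) + 4
  st <- simulate_spike_train(unit_spec(15), numeric(0), dur, seed = 3)
  ps <- compute_psth(st, onsets, psth_params(), t_max = dur)
  z0 <- zscore_psth(ps)
  for (f in list(function(c) c + 2, function(c) c * 3)) {
    ps2 <- ps
    ps2$counts <- f(ps$counts)
    ps2$rate <- colMeans(ps2$counts) / 0.25
    expect_equal(zscore_psth(ps2), z0, tolerance = 1e-9)
  }
})

test_that("classification thresholds and mixed rule", {
  p <- psth_params()
  expect_identical(classify_response(rep(0.1, 12), p), "unresponsive")
  z <- rep(0, 12); z[4] <- 3.10
  expect_identical(classify_response(z, p), "excited")
  z[4] <- 3.09                      # must exceed, not equal
  expect_identical(classify_response(z, p), "unresponsive")
  z[4] <- 3.2; z[8] <- -4.0
  lab <- classify_response(z, p)
  expect_identical(as.character(lab), "inhibited")  # larger |z| wins
  expect_true(attr(lab, "mixed"))
})

test_that("inclusion boundaries are strict as stated", {
  p <- psth_params()
  dur <- 100
  expect_false(apply_inclusion(seq_len(99), dur, 5, p))    # 0.99 Hz
  expect_true(apply_inclusion(seq_len(100), dur, 5, p))    # 1.00 Hz
  expect_false(apply_inclusion(seq_len(500), dur, 2, p))   # 2 trials
  expect_true(apply_inclusion(seq_len(500), dur, 3, p))    # 3 trials
})

test_that("response magnitudes: extraction and group summaries", {
  mk <- function(label, z_max = NA, z_min = NA)
    structure(list(unit_id = 1, label = label, z_max = z_max, z_min = z_min),
              class = "unit_response")
  rs <- list(mk("excited", z_max = 4), mk("excited", z_max = 6),
             mk("inhibited", z_min = -3.5), mk("unresponsive"))
  out <- response_magnitudes(rs)
  expect_equal(out$mean_z[out$label == "excited"], 5)
  expect_equal(out$n[out$label == "inhibited"], 1)
  empty <- response_magnitudes(list(mk("unresponsive")))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("group", "label", "n", "mean_z") %in% names(empty)))
})

test_that("z_max extraction and stronger evoked rates raise group z_max", {
  onsets <- 5 + (0:19) * 6.5
  dur <- max(onsets) + 4
  zmax <- function(evoked, seed) {
    st <- simulate_spike_train(unit_spec(8, "excited", evoked), onsets, dur,
                               seed = seed)
    r <- unit_response(st, onsets, dur, unit_id = 1)
    if (identical(r$label, "excited")) r$z_max else NA_real_
  }
  weak <- vapply(1:6, function(i) zmax(20, i), numeric(1))
  strong <- vapply(1:6, function(i) zmax(40, 100 + i), numeric(1))
  expect_gt(mean(strong, na.rm = TRUE), mean(weak, na.rm = TRUE))
})

test_that("null units produce approximately standard-normal z (scaled down)", {
  # scaled-down version of the calibration invariant (800 units instead of
  # 10,000) to stay within the test-time budget; the full-size run lives in
  # the acceptance suite
  onsets <- 5 + (0:49) * 6.5
  dur <- max(onsets) + 4
  zs <- unlist(lapply(1:800, function(i) {
    st <- simulate_spike_train(unit_spec(20), numeric(0), dur, seed = 5000 + i)
    ps <- compute_psth(st, onsets, psth_params(), t_max = dur)
    zscore_psth(ps)
  }))
  ks <- suppressWarnings(ks.test(zs, "pnorm"))
  expect_lt(unname(ks$statistic), 0.05)
})
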