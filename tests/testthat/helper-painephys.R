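# Shared fixtures, built in code.

# small, fast session configuration: reduced raw rate (all signal content is
# far below the 200-Hz anti-alias edge, so band quantities are unaffected)
tiny_session_config <- function(seed = 1, gamma_gain = 1, n_trials = 3,
                                forces = c(0.6, 1.0), fs_raw = 4000) {
  simulation_config(fs_raw = fs_raw, n_trials = n_trials,
                    filament_forces = forces,
                    band_gain_profile = c(gamma = gamma_gain),
                    trial_spacing = 7,
                    psychometric = c(threshold = 0.05, slope = 30),
                    seed = seed)
}

# deterministic unit spec shortcut
unit_spec <- function(baseline_rate, kind = "none", evoked_rate = baseline_rate,
                      evoked_duration = 0.5, waveform_class = 1) {
  list(baseline_rate = baseline_rate, response_kind = kind,
       evoked_rate = evoked_rate, evoked_duration = evoked_duration,
       waveform_class = waveform_class)
}

# brute-force probit-MLE oracle for the up-down threshold (independent of
# the package's optimizer): dense grid search over mu
updown_oracle <- function(forces, responses, filament_set) {
  delta <- mean(diff(log10(filament_set)))
  if (all(responses == 1)) return(min(filament_set))
  if (all(responses == 0)) return(max(filament_set))
  x <- log10(forces)
  ll <- function(grid) sapply(grid, function(mu) {
    p <- pnorm((x - mu) / delta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(responses * log(p) + (1 - responses) * log(1 - p))
  })
  # coarse scan, then local refinement around the peak
  g1 <- seq(log10(min(filament_set)) - 5 * delta,
            log10(max(filament_set)) + 5 * delta, length.out = 2001)
  mu1 <- g1[which.max(ll(g1))]
  g2 <- seq(mu1 - 2 * diff(g1[1:2]), mu1 + 2 * diff(g1[1:2]),
            length.out = 2001)
  mu <- g2[which.max(ll(g2))]
  min(max(10^mu, min(filament_set)), max(filament_set))
}

# enumerate every complete up-down sequence of exactly `len` presentations
# starting from `start` on the set (responses drive the stepping; sequences
# that terminate early at a boundary or run longer are skipped)
enumerate_updown_sequences <- function(len = 6, start = 0.4,
                                       filament_set = c(0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4)) {
  k <- length(filament_set)
  out <- list()
  for (code in 0:(2^len - 1)) {
    resp <- as.integer(intToBits(code))[1:len]
    i <- match(start, filament_set)
    forces <- numeric(0)
    reversal_at <- NA
    valid <- TRUE
    n <- 0
    repeat {
      n <- n + 1
      if (n > len) { valid <- FALSE; break }
      forces <- c(forces, filament_set[i])
      y <- resp[n]
      if (is.na(reversal_at) && n > 1 && resp[n] != resp[n - 1]) reversal_at <- n
      done_rule <- !is.na(reversal_at) && n >= reversal_at + 4
      at_bound <- (y == 1 && i == 1) || (y == 0 && i == k)
      if (done_rule || at_bound) break
      i <- i + if (y == 1) -1L else 1L
    }
    if (valid && n == len && !is.na(reversal_at) && n >= reversal_at + 4)
      out[[length(out) + 1]] <- list(forces = forces, responses = resp[1:len])
  }
  out
}
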