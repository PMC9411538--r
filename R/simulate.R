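# Synthetic recording sessions.
#
# The generator states a simple, analytically tractable world with the
# statistical structure the analysis assumes: background 1/f noise plus one
# band-limited noise component per analysis band (so band-power ground truth
# is analytic), inhomogeneous-Poisson spike trains from excited / inhibited /
# unresponsive units with class-1 (broad) and class-2 (narrow) waveform
# templates, trial tables over the 7-filament force set, and up-down
# response sequences drawn from a logistic psychometric in log10 force.

#' Default unit specifications for simulated sessions
#' @noRd
default_unit_specs <- function() {
  list(
    list(baseline_rate = 8,  response_kind = "excited",   evoked_rate = 30,
         evoked_duration = 0.5, waveform_class = 1),
    list(baseline_rate = 12, response_kind = "inhibited", evoked_rate = 1,
         evoked_duration = 0.5, waveform_class = 2),
    list(baseline_rate = 6,  response_kind = "none",      evoked_rate = 6,
         evoked_duration = 0.5, waveform_class = 1),
    list(baseline_rate = 15, response_kind = "none",      evoked_rate = 15,
         evoked_duration = 0.5, waveform_class = 2)
  )
}

#' Configuration of a simulated recording session
#'
#' The defaults state the recording world the analysis was built for: raw
#' acquisition at 32 kHz, the 7-filament von Frey force set, one band-limited
#' noise carrier per analysis band (RMS `carrier_amplitude` each) on top of
#' 1/f background noise, and a logistic psychometric for withdrawal.
#'
#' @param fs_raw Raw sampling rate (Hz).
#' @param n_trials Applications per filament.
#' @param filament_forces Strictly increasing force set (g).
#' @param band_gain_profile Named post-onset power multipliers, one per band.
#' @param carrier_amplitude Baseline RMS of each band-noise carrier.
#' @param carriers Optional explicit carrier list overriding the per-band
#'   defaults; each element is `list(type = "noise", band = <band>)` or
#'   `list(type = "sine", freq = <Hz>)`, plus `amplitude` (RMS for noise,
#'   peak for sine).
#' @param noise_sd RMS of the 1/f background noise.
#' @param one_over_f_exponent Spectral exponent of the background noise.
#' @param evoked_duration Seconds after onset during which gains apply.
#' @param ramp_s Raised-cosine ramp length for the evoked gain envelope.
#' @param unit_specs List of unit specifications (`baseline_rate`,
#'   `response_kind` in excited/inhibited/none, `evoked_rate`,
#'   `evoked_duration`, `waveform_class` in 1/2).
#' @param psychometric `c(threshold = g, slope = logistic slope per log10 g)`.
#' @param trial_spacing Mean inter-trial interval (s).
#' @param session_lead_in Quiet time (s) before the first and after the last
#'   onset (must cover analysis windows plus wavelet support).
#' @param waveform_noise_sd Additive noise on waveform templates.
#' @param seed Integer seed; fully determines the session.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(fs_raw = 32000, n_trials = 10,
                              filament_forces = c(0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4),
                              band_gain_profile = c(theta = 1, alpha = 1,
                                                    beta = 1, gamma = 1),
                              carrier_amplitude = 1, carriers = NULL,
                              noise_sd = 0.2, one_over_f_exponent = 1,
                              evoked_duration = 2, ramp_s = 0.01,
                              unit_specs = default_unit_specs(),
                              psychometric = c(threshold = 0.4, slope = 5),
                              trial_spacing = 8, session_lead_in = 6.5,
                              waveform_noise_sd = 0.02, seed = 1L) {
  if (any(diff(filament_forces) <= 0))
    pe_stop("badarg", "filament_forces must be strictly increasing")
  bt <- band_table()
  if (fs_raw <= 2 * max(bt$hi))
    pe_stop("badarg", "fs_raw must exceed twice the highest synthesized frequency")
  if (is.null(carriers))
    carriers <- lapply(bt$band, function(b)
      list(type = "noise", band = b, amplitude = carrier_amplitude))
  if (!all(names(band_gain_profile) %in% bt$band))
    pe_stop("badarg", "band_gain_profile names must be bands")
  gains <- c(theta = 1, alpha = 1, beta = 1, gamma = 1)
  gains[names(band_gain_profile)] <- band_gain_profile
  for (u in unit_specs) {
    if (u$baseline_rate < 0 || u$evoked_rate < 0)
      pe_stop("badarg", "unit rates must be >= 0")
    if (u$evoked_duration < 0)
      pe_stop("badarg", "evoked_duration must be >= 0")
  }
  structure(list(fs_raw = fs_raw, n_trials = n_trials,
                 filament_forces = filament_forces, band_gain_profile = gains,
                 carriers = carriers, noise_sd = noise_sd,
                 one_over_f_exponent = one_over_f_exponent,
                 evoked_duration = evoked_duration, ramp_s = ramp_s,
                 unit_specs = unit_specs, psychometric = psychometric,
                 trial_spacing = trial_spacing,
                 session_lead_in = session_lead_in,
                 waveform_noise_sd = waveform_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# gain envelope: 1 everywhere, sqrt(power gain) inside evoked windows, with
# raised-cosine ramps to avoid spectral splatter
gain_envelope <- function(n, fs, onsets, duration, gain, ramp_s) {
  env <- rep(1, n)
  if (gain == 1 || !length(onsets)) return(env)
  amp <- sqrt(gain)
  nramp <- max(1L, round(ramp_s * fs))
  up <- (1 - cos(pi * seq_len(nramp) / nramp)) / 2       # 0 -> 1
  for (on in onsets) {
    i0 <- round(on * fs) + 1L
    i1 <- round((on + duration) * fs)
    if (i0 < 1 || i1 > n) next
    env[i0:i1] <- amp
    ui <- i0 - 1L + seq_len(min(nramp, i1 - i0))
    env[ui] <- 1 + (amp - 1) * up[seq_along(ui)]
    di <- i1 + 1L - rev(seq_len(min(nramp, i1 - i0)))
    env[di] <- 1 + (amp - 1) * rev(up)[seq_along(di)]
  }
  env
}

# band-limited Gaussian noise with unit RMS, via frequency-domain synthesis
bandnoise <- function(n, fs, lo, hi) {
  nfft <- stats::nextn(n, factors = 2)
  fgrid <- (seq_len(nfft) - 1) * fs / nfft
  mask <- fgrid >= lo & fgrid < hi & fgrid <= fs / 2
  nk <- sum(mask)
  spec <- complex(real = numeric(nfft), imaginary = numeric(nfft))
  spec[mask] <- complex(real = stats::rnorm(nk), imaginary = stats::rnorm(nk))
  # hermitian completion so the inverse transform is real
  idx <- which(mask)
  spec[nfft - idx + 2] <- Conj(spec[idx])
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)] / nfft
  x / stats::sd(x)
}

# 1/f^alpha background noise with unit RMS
pink_noise <- function(n, fs, exponent) {
  nfft <- stats::nextn(n, factors = 2)
  fgrid <- (seq_len(nfft) - 1) * fs / nfft
  half <- 2:(nfft / 2)
  spec <- complex(real = numeric(nfft), imaginary = numeric(nfft))
  w <- 1 / pmax(fgrid[half], 0.5)^(exponent / 2)
  spec[half] <- complex(real = stats::rnorm(length(half)),
                        imaginary = stats::rnorm(length(half))) * w
  spec[nfft - half + 2] <- Conj(spec[half])
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)] / nfft
  x / stats::sd(x)
}

carrier_band <- function(carrier) {
  bt <- band_table()
  if (identical(carrier$type, "noise")) return(carrier$band)
  b <- bt$band[carrier$freq >= bt$lo & carrier$freq < bt$hi]
  if (length(b)) b else NA_character_
}

#' Simulate a continuous LFP trace
#'
#' Background 1/f noise plus the configured band carriers; carrier amplitude
#' is multiplied by `sqrt(band_gain_profile[band])` inside
#' `[onset, onset + evoked_duration]` with raised-cosine ramps.
#'
#' @param config A [simulation_config()].
#' @param onsets Stimulation onsets (s) at which evoked gains apply.
#' @param duration Trace duration (s).
#' @return Numeric trace at `config$fs_raw`, attribute `fs`.
#' @export
simulate_lfp <- function(config, onsets, duration) {
  stopifnot(inherits(config, "simulation_config"))
  fs <- config$fs_raw
  n <- round(duration * fs)
  if (length(onsets)) {
    if (any(onsets < 0) || any(onsets + config$evoked_duration > duration))
      pe_stop("badonset",
              "onset %.3f s too close to the trace edge for a %g s evoked window",
              onsets[which(onsets < 0 | onsets + config$evoked_duration > duration)[1]],
              config$evoked_duration)
  }
  with_seed(config$seed, {
    x <- if (config$noise_sd > 0)
      config$noise_sd * pink_noise(n, fs, config$one_over_f_exponent)
    else numeric(n)
    bt <- band_table()
    for (carrier in config$carriers) {
      band <- carrier_band(carrier)
      gain <- if (!is.na(band)) config$band_gain_profile[[band]] else 1
      comp <- if (identical(carrier$type, "sine")) {
        carrier$amplitude * sin(2 * pi * carrier$freq * (seq_len(n) - 1) / fs)
      } else {
        b <- bt[bt$band == carrier$band, ]
        carrier$amplitude * bandnoise(n, fs, b$lo, b$hi)
      }
      env <- gain_envelope(n, fs, onsets, config$evoked_duration, gain,
                           config$ramp_s)
      x <- x + comp * env
    }
    structure(x, fs = fs)
  })
}

#' Simulate a spike train
#'
#' Inhomogeneous Poisson process: `baseline_rate` everywhere, replaced by
#' `evoked_rate` on `[onset, onset + evoked_duration]` for excited/inhibited
#' units. A 1-ms refractory period is enforced by thinning.
#'
#' @param spec A unit specification (see [simulation_config()]).
#' @param onsets Stimulation onsets (s).
#' @param duration Session duration (s).
#' @param seed Integer seed.
#' @param refractory Refractory period (s).
#' @return Sorted spike times (s).
#' @export
simulate_spike_train <- function(spec, onsets, duration, seed = NULL,
                                 refractory = 0.001) {
  if (spec$baseline_rate < 0 || spec$evoked_rate < 0)
    pe_stop("badarg", "rates must be >= 0")
  if (spec$evoked_duration < 0)
    pe_stop("badarg", "evoked_duration must be >= 0")
  with_seed(seed, {
    # segment boundaries: baseline everywhere, evoked windows override
    evoked <- spec$response_kind %in% c("excited", "inhibited") &&
      length(onsets) > 0 && spec$evoked_duration > 0
    spikes <- draw_poisson(spec$baseline_rate, 0, duration)
    if (evoked) {
      for (on in onsets) {
        w0 <- on; w1 <- min(on + spec$evoked_duration, duration)
        spikes <- spikes[spikes < w0 | spikes >= w1]
        spikes <- c(spikes, draw_poisson(spec$evoked_rate, w0, w1))
      }
    }
    spikes <- sort(spikes)
    if (length(spikes) > 1 && refractory > 0) {
      keep <- c(TRUE, diff(spikes) >= refractory)
      # iterate: removing a spike can expose a new short interval
      while (!all(keep)) {
        spikes <- spikes[keep]
        keep <- c(TRUE, diff(spikes) >= refractory)
      }
    }
    spikes
  })
}

draw_poisson <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

#' Waveform template parameters
#'
#' Class 1 (broad) and class 2 (narrow) biphasic templates: a small early
#' positive peak, a dominant trough, and a late positive peak whose width
#' controls the trough-to-baseline-return time. Times in ms.
#'
#' @param class_id 1 (broad) or 2 (narrow).
#' @return List of Gaussian bump parameters.
#' @export
waveform_template_params <- function(class_id) {
  if (!class_id %in% c(1, 2)) pe_stop("badarg", "class_id must be 1 or 2")
  if (class_id == 1)
    list(early = c(amp = 0.20, t = 0.45, sd = 0.070),
         trough = c(amp = -1.00, t = 0.80, sd = 0.150),
         late = c(amp = 0.35, t = 1.60, sd = 0.300),
         tail = c(amp = -0.06, t = 2.70, sd = 0.350))
  else
    list(early = c(amp = 0.25, t = 0.45, sd = 0.055),
         trough = c(amp = -1.00, t = 0.70, sd = 0.080),
         late = c(amp = 0.30, t = 1.05, sd = 0.120),
         tail = c(amp = -0.06, t = 1.75, sd = 0.250))
}

#' Simulate a mean spike waveform
#'
#' @param class_id Waveform class, 1 (broad) or 2 (narrow).
#' @param noise_sd Additive Gaussian noise SD (template peak-normalized units).
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @param fs_wave Waveform sampling rate (Hz).
#' @param len_ms Template length (ms).
#' @return Numeric waveform with attribute `fs`.
#' @export
simulate_waveform <- function(class_id, noise_sd = 0, seed = NULL,
                              fs_wave = 32000, len_ms = 3.2) {
  p <- waveform_template_params(class_id)
  t_ms <- (seq_len(round(len_ms * fs_wave / 1000)) - 1) / fs_wave * 1000
  w <- numeric(length(t_ms))
  for (bump in p)
    w <- w + bump["amp"] * exp(-(t_ms - bump["t"])^2 / (2 * bump["sd"]^2))
  if (noise_sd > 0)
    w <- w + with_seed(seed, stats::rnorm(length(w), sd = noise_sd))
  structure(w, fs = fs_wave)
}

#' Simulate an up-down testing sequence
#'
#' Each presentation is answered positive with probability from a logistic
#' psychometric in log10 force; the next filament follows the up-down rule
#' (down after a positive, up after a negative) on the ordered set. The
#' sequence terminates four presentations after the first reversal, or at a
#' boundary of the set (a negative at the highest or a positive at the lowest
#' force before any reversal).
#'
#' @param true_threshold 50% withdrawal threshold (g).
#' @param slope Logistic slope per log10 g; `Inf` gives a deterministic
#'   staircase (positive iff force >= threshold).
#' @param filament_set Ordered force set (g).
#' @param start_force Starting force, must be in `filament_set`.
#' @param max_steps Hard cap on presentations.
#' @param seed Integer seed.
#' @return Data frame `force_g`, `response` (0/1).
#' @export
simulate_updown_responses <- function(true_threshold, slope,
                                      filament_set = c(0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4),
                                      start_force = 0.4, max_steps = 30,
                                      seed = NULL) {
  if (!start_force %in% filament_set)
    pe_stop("badarg", "start_force must be one of the filament set")
  with_seed(seed, {
    i <- match(start_force, filament_set)
    forces <- numeric(0); resp <- integer(0)
    reversal_at <- NA_integer_
    k <- length(filament_set)
    repeat {
      f <- filament_set[i]
      p <- if (is.infinite(slope)) as.numeric(f >= true_threshold)
           else stats::plogis(slope * (log10(f) - log10(true_threshold)))
      y <- stats::rbinom(1, 1, p)
      forces <- c(forces, f); resp <- c(resp, y)
      n <- length(resp)
      if (is.na(reversal_at) && n > 1 && resp[n] != resp[n - 1])
        reversal_at <- n
      if (!is.na(reversal_at) && n >= reversal_at + 4) break
      if (n >= max_steps) break
      if (y == 1) {
        if (i == 1) { if (is.na(reversal_at)) break else break }
        i <- i - 1
      } else {
        if (i == k) { if (is.na(reversal_at)) break else break }
        i <- i + 1
      }
    }
    data.frame(force_g = forces, response = resp)
  })
}

#' Simulate a complete recording session
#'
#' Builds the trial table (randomized filament order, jittered spacing),
#' draws withdrawal flags from the psychometric, synthesizes the LFP with
#' evoked band gains on withdrawal trials, and generates spike trains and
#' waveform templates for the configured units.
#'
#' @param config A [simulation_config()].
#' @param condition Condition label stored with the session.
#' @return Object of class `recording_session` with elements `lfp` (raw
#'   trace + `fs`), `units` (list of `spike_times`, `waveform`, `fs_wave`),
#'   `trials` (data frame `onset_s`, `force_g`, `withdrawal`, `latency_s`),
#'   `condition`, `duration`, `ground_truth`.
#' @export
simulate_session <- function(config = simulation_config(), condition = "naive") {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    forces <- sample(rep(config$filament_forces, each = config$n_trials))
    n <- length(forces)
    gaps <- config$trial_spacing + stats::runif(n, -0.5, 0.5)
    onsets <- config$session_lead_in + cumsum(gaps) - gaps[1]
    duration <- onsets[n] + config$session_lead_in + config$evoked_duration
    thr <- config$psychometric[["threshold"]]
    slope <- config$psychometric[["slope"]]
    pw <- if (is.infinite(slope)) as.numeric(forces >= thr)
          else stats::plogis(slope * (log10(forces) - log10(thr)))
    withdrawal <- stats::rbinom(n, 1, pw)
    latency <- ifelse(withdrawal == 1, stats::runif(n, 0.1, 1.0), NA_real_)
    trials <- data.frame(onset_s = onsets, force_g = forces,
                         withdrawal = withdrawal, latency_s = latency)
    ev_onsets <- onsets[withdrawal == 1]
    lfp_seed <- config$seed + 1000L
    lfp_cfg <- config; lfp_cfg$seed <- lfp_seed
    lfp <- simulate_lfp(lfp_cfg, ev_onsets, duration)
    units <- lapply(seq_along(config$unit_specs), function(j) {
      spec <- config$unit_specs[[j]]
      list(spike_times = simulate_spike_train(spec, ev_onsets, duration,
                                              seed = config$seed + 2000L + j),
           waveform = simulate_waveform(spec$waveform_class,
                                        config$waveform_noise_sd,
                                        seed = config$seed + 3000L + j),
           fs_wave = 32000,
           true_kind = spec$response_kind,
           true_class = spec$waveform_class)
    })
    structure(list(lfp = lfp, units = units, trials = trials,
                   condition = condition, duration = duration,
                   ground_truth = config),
              class = "recording_session")
  })
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("Recording session (%s): %.1f s, %d trials (%d withdrawal), %d units\n",
              x$condition, x$duration, nrow(x$trials), sum(x$trials$withdrawal),
              length(x$units)))
  invisible(x)
}
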