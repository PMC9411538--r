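# painephys

Event-locked LFP, single-unit and nociceptive behavior analysis for in-vivo
basal-forebrain (e.g. nucleus basalis) tetrode recordings during von Frey,
Hargreaves and capsaicin testing — plus a synthetic-data generator that
emulates the recording structure so the entire pipeline is testable without
any recordings.

## Who this is for

Labs quantifying how noxious mechanical/thermal stimulation modulates
basal-forebrain population activity (LFP band power) and single units, and
anyone who needs the accompanying behavioral readouts (50% withdrawal
thresholds, stimulus–response curves, thermal latencies, nocifensive
durations) and their statistical battery in reproducible, tested form.

## What it computes

**LFP.** Raw traces are low-passed with a 3rd-order Chebyshev type I filter
(0.5 dB ripple, 200 Hz edge, applied zero-phase) and decimated to 1 kHz.
Morlet wavelet power P(t, f) is computed on a 0.5-Hz grid (4–100 Hz, 1-ms
resolution, σ_f = f/n_cycles). Around each withdrawal-trial onset, every
frequency row is expressed as % change from its 1-s pre-onset baseline,

&nbsp;&nbsp;&nbsp;&nbsp;ΔP(t, f) = 100 · (P(t, f) − μ_f) / μ_f,

averaged across trials, and summarized per band (theta 4–8, alpha 8–14,
beta 14–30, gamma 30–100 Hz) over the 2-s post-onset window, as 100-ms time
courses, and per filament force.

**Units.** Spikes of each withdrawal trial are aligned to onset, binned at
250 ms over [−3, +3] s, averaged, and each post-onset bin is z-scored
against the 3-s baseline. A unit is *excited* (*inhibited*) if any post bin
exceeds +3.09 (−3.09), the P < 0.001 normal critical value; units with mean
rate < 1 Hz or < 3 withdrawal trials are excluded. Waveforms are typed into
class 1 (broad) vs class 2 (narrow, fast-spiking-like) by k-means on the
standardized (asymmetry, trough-to-return) pair, with an exploratory
six-feature t-SNE route.

**Behavior.** Dixon's up-down 50% threshold on the 7-filament set (probit
MLE with spread fixed at the mean log10 step δ = 0.2573, reported with its
equivalent k), per-force response curves, 30-s-censored Hargreaves
latencies, and merged-interval nocifensive durations.

**Statistics.** One-sample t, repeated-measures ANOVA with exact Dunnett
many-to-one adjustment, two-way ANOVA with gated Šidák comparisons,
Pearson chi-square (with pairwise-period mode), one-sample ROUT (Q = 0.5%)
and the critical-z correspondence.

## Worked example

```r
library(painephys)

cfg <- simulation_config(fs_raw = 4000, n_trials = 10,
                         filament_forces = c(0.6, 1.0),
                         band_gain_profile = c(gamma = 4),  # power x4 post-onset
                         trial_spacing = 7,
                         psychometric = c(threshold = 0.3, slope = 8),
                         seed = 7)
s <- simulate_session(cfg)
s
#> Recording session (naive): 149.1 s, 20 trials (19 withdrawal), 4 units

ns <- session_normalized_spectrogram(s)
for (b in band_table()$band)
  cat(sprintf("%-6s %+7.1f %%\n", b, band_power_change(ns, b)))
#> theta    +31.6 %
#> alpha    -11.1 %
#> beta      +9.4 %
#> gamma   +273.2 %

for (r in session_unit_responses(s))
  cat(sprintf("unit %d: %-12s z_max %.2f z_min %.2f\n",
              r$unit_id, r$label, r$z_max, r$z_min))
#> unit 1: excited      z_max 16.38 z_min NA
#> unit 2: inhibited    z_max NA z_min -6.30
#> unit 3: unresponsive z_max NA z_min NA
#> unit 4: unresponsive z_max NA z_min NA
```

Reading the numbers: the injected gamma amplitude step (power ×4) is
recovered as ≈ +273% rather than the idealized +300% — the wavelet's
band-edge leakage and its acausal smearing into the pre-onset baseline
systematically shave 20–25 points (quantified in closed form by
`expected_band_change(cfg)`; see the methods vignette). The unchanged bands
scatter around zero: a *single* session's low-band estimates are noisy
(theta here is +32% from one 19-trial session) because a 1-s theta baseline
contains only ~3 independent power samples per trial; multi-session
averages are the unit of inference. The excited/inhibited/unresponsive
labels match the generator's ground truth.

The up-down staircase:

```r
ud <- simulate_updown_responses(true_threshold = 0.4, slope = 5, seed = 7)
ud
#>   force_g response
#> 1    0.40        1
#> 2    0.16        0
#> 3    0.40        0
#> 4    0.60        1
#> 5    0.40        0
#> 6    0.60        0
updown_threshold(ud$force_g, ud$response)$threshold_g
#> [1] 0.5547233
```

A full report bundle (CSV tables + JSON summary stamped with version,
config hash and seed) comes from `run_pipeline(session_dir, out_dir)`, or
from the CLI installed at `exec/painephys`:

```sh
painephys simulate --out sess/ --seed 3 --gamma-gain 4
painephys report --session sess/ --out sess/out/
```

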