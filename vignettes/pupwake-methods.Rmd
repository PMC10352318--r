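---
title: "Arousal-state transitions and sensory-evoked hemodynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arousal-state transitions and sensory-evoked hemodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

In head-fixed neonatal mice, whisker stimulation often appears to drive a
*decrease* in cortical blood volume — the opposite of adult neurovascular
coupling.  The resolution is behavioral: neonates sleep most of the time,
cortical blood volume is much higher in NREM and REM sleep than in wake, and
a stimulus frequently awakens the animal.  The vasoconstriction that
accompanies awakening (tens of µM of total hemoglobin, ΔHbT) swamps the few
µM of genuine stimulus-evoked dilation.  Demonstrating this requires five
analysis stages operating on simultaneously recorded channels — ΔHbT from
530 nm intrinsic optical imaging, nuchal EMG, hippocampal LFP, treadmill
velocity, and stimulus times:

1. **hemo** — modified Beer–Lambert conversion of reflectance to ΔHbT, and
   evoked-response metrics (peak, time-to-peak, FWHM, early mean over
   [0.5, 3) s, undershoot mean over [5, 15) s).
2. **spectral** — multitaper power spectra of resting ΔHbT, `P = a f^-β`
   power-law fits on log-resampled spectra, pre-whitening, and vasomotion
   peak metrics.
3. **ephys** — zero-phase filtering, threshold spike detection with a 1 ms
   refractory rule, Gaussian-kernel rate estimation (σ = 100 ms),
   multitaper spectrograms (5 s windows, 0.5 s steps), EMG power
   (band-pass → rectify → square → 50 ms Gaussian), and laminar CSD.
4. **scoring** — rule-based arousal-state classification in 5-s bins, bout
   extraction, state fractions and bout-survival medians.
5. **transitions** — qualified state transitions (≥15 s on both sides),
   the baseline/response delta statistic (mean over [t+5, t+15) minus mean
   over [t−15, t−5)), evoked responses split by pre-stimulus state, and
   peri-stimulus awake probability.

Because the corresponding animal data cannot be regenerated at a desk, the
package is validated by *parameter recovery*: a seeded synthetic-session
generator (**synthgen**) produces recordings whose ground truth encodes the
published summary statistics, and each stage must recover those parameters
within stated tolerances.

# The synthetic-session generator

## Arousal dynamics

Arousal state follows a semi-Markov chain: bout states are drawn from an
embedded transition matrix (no self-transitions), bout durations from a
log-normal parameterized by its median.  The log-normal's heavy right tail
matches the shape of empirical bout-survival curves; its log-sd is fixed at
0.6 (a moderate tail) for every state, a choice made once and not revisited.

Per age group the *time-in-state fractions* and *dwell medians* are the
published values (P15: active awake 27.78%, quiescent awake 24.12%, NREM
39.9%, REM 8.17%, with dwell medians 21/17/24/34 s; P10 active sleep
57.19%, median 53 s; P10 fractions not published were set to plausible
values: 15/12.81/15%).  The embedded matrices are then *solved* so that the
stationary fractions of the semi-Markov process — `π_i m_i / Σ_j π_j m_j`
with `m = median · exp(σ²/2)` — equal those targets, under an allowed-edge
graph in which REM exits only to active wake and NREM is entered from
wakefulness via behavioral quiescence.  Where the balance equations leave
freedom (e.g. the NREM→quiescent-awake exit probability) a plausible value
is fixed and the rest solved exactly; the solution is verified by
eigen-decomposition in the test suite.

## Channels

* **ΔHbT** (30 Hz): per-state blood-volume offsets, smoothed by a single
  exponential kernel (τ = 3 s) toward the current offset — hemodynamic
  transitions take several seconds but no kernel is published, so a simple
  relaxation was chosen — plus `1/f^β` background noise synthesized in the
  frequency domain (amplitude ∝ `f^(-β/2)`, random phases, floored below
  the record's fundamental; exact target spectrum by construction), plus a
  narrowband Gaussian "vasomotion" bump, plus a gamma-variate template for
  every stimulus delivered in wakefulness.  The offsets anchor
  quiescent-awake at 0 µM and encode the published transition deltas
  (P15: NREM +12.35, REM +25.18, active awake −1.08 µM).  The published
  deltas are mutually inconsistent at the ±0.7 µM level (they come from
  different event sets), so the offsets reproduce the four transition types
  the recovery tests target exactly and the remainder approximately.
* **EMG** (1 kHz): Gaussian noise with per-state sigma (wake 0.6–1.0,
  sleep atonia 0.08–0.10), with 100-ms myoclonic twitches (Poisson,
  0.5 s⁻¹) during REM / active sleep whose amplitude reaches awake tone.
* **LFP** (1 kHz): band-limited noise components (delta 1–4, theta 4–10,
  gamma 40–100 Hz) scaled by per-state gains: delta dominates NREM,
  theta/gamma dominate REM, reproducing the scoring physiology.
* **Velocity** (30 Hz): 1-s locomotion epochs with probability 0.9 s⁻¹ in
  active wake only, speed ≈ 5 ± 1, plus a small encoder noise floor.
* **Spikes**: homogeneous Poisson at the published baseline rates (P10
  41.3, P15 58.6, adult 75.2 Hz), doubled during the 0.5-s stimulus (the
  published evoked/baseline ratio), thinned from a dominating rate.

Stimuli are spaced ≥60 s with uniform jitter (≤20 s) to prevent
entrainment.  A stimulus arriving in sleep awakens the animal with
probability 0.85 — derived from the published peri-stimulus awake
probability rising from ~65% to ~95%, i.e. `0.95 ≈ 0.65 + 0.35 p` — after a
1-s latency; the sleep bout is truncated and the chain regrown from active
wake, so the "response" to a sleep stimulus is the awakening
vasoconstriction itself, not an evoked template.

## What the generator does and does not emulate

It reproduces the *statistical* structure the analyses assume:
state-dependent channel statistics, bout-duration laws, 1/f background,
awakening dynamics.  It does not model vascular biophysics, image
formation (beyond flat ROI stacks for testing), respiration/heart-rate
artifacts, electrode drift, or inter-animal variability.  Passing recovery
tests therefore demonstrates that the estimators are unbiased under the
assumed signal model at realistic SNR — not that they are robust to every
artifact of real recordings.

# Estimator design choices

**Beer–Lambert.** `ΔHbT = −ln(I/I₀)/(X·ξ)` with `I₀` the temporal baseline
mean (the only self-consistent reading for a Δ quantity).  Defaults
`X = 0.1 cm`, `ξ = 0.039 µM⁻¹cm⁻¹` are representative 530-nm literature
values; every within-session comparison is invariant to the product `X·ξ`.
An absorption coefficient is sometimes listed alongside this formula but
does not appear in it; it is ignored.

**Multitaper spectra.** DPSS tapers are computed from the symmetric
tridiagonal form of the concentration problem; for records longer than 512
samples the eigenvectors are solved at reduced length, spline-interpolated,
re-orthonormalized, and weighted by concentrations measured directly from
each taper's spectrum.  Defaults TW = 3, K = 5.

**Power-law fitting.** The spectrum is resampled onto 64 log-spaced bins
(geometric-mean frequency, arithmetic-mean power) so OLS in log–log space
is not dominated by the dense high-frequency end; the fit band is
0.005–1 Hz after dropping the two lowest bins, where detrending and finite
record length suppress power.  On 300-s records the estimator carries a
known +0.08 bias at β ≈ 1.85 (multitaper smearing steepens the low band
edge), inside the ±0.15 recovery tolerance and stated here rather than
corrected.

**Pre-whitening and peak location.** The whitened spectrum is the ratio to
the fitted trend.  Two estimator refinements matter at low frequencies:
(i) the power law is *refit with the peak region excluded* once a peak is
found, because a strong bump inside the fit band otherwise inflates β̂ by
~0.2; (ii) the peak *location* is taken from the background-subtracted
spectrum (estimate minus the bandwidth-averaged trend) within one
estimator bandwidth of the whitened maximum.  A ratio maximum is pushed
toward the high side of a bump that is narrower than the taper bandwidth
sitting on a steep trend — ~+20% at the 0.018 Hz neonatal peak — while the
subtracted peak of a symmetric smeared bump is unbiased.  Peak *power* and
the no-peak flag (whitened maximum < 1.5) keep the ratio definition; a pure
power law whitens to exactly 1.  The reported peak fraction is the whitened
peak power divided by the summed whitened power — one concrete reading of
"normalized total power", flagged as such.

**Scoring.** Features are per-5-s-bin medians (EMG power, three LFP band
powers) plus the within-bin EMG maximum and moving fraction.  Medians make
boundary bins inherit the majority state's features, matching the
majority-label convention of the ground truth.  Thresholds are resolved
per session: manual scorers judge atonia against that animal's bimodal EMG
distribution, emulated by a deterministic 2-means split of log EMG power
with the threshold at the midpoint of the cluster centers.  A fixed
percentile (the simpler rule, retained as `method = "percentile"`) fails
whenever time asleep strays far from the percentile: at 50–72% sleep a
30th-percentile threshold sits inside the atonic mode.  REM vs NREM among
atonic bins uses the theta/delta median-power ratio (threshold 1); P10
active vs quiescent sleep uses twitches — within-bin EMG maxima reaching
awake amplitude while the median stays atonic.  Active wake requires a
moving fraction > 0.5, keeping bin labels majority-consistent so that
sleep→wake boundaries are not systematically pulled early (an asymmetry
that measurably biased peri-transition deltas).  Isolated single-bin
flickers are relabelled to their flanking state by default — a human
scorer does not end an active-sleep bout for one twitch-free 5-s window.
On degenerate generators with identical state parameters the classifier
drops to chance, confirming it uses no hidden truth.

**Transitions.** Events need ≥15 s in both flanking states, which also
guarantees the half-open windows [t−15, t−5) and [t+5, t+15) lie inside
those bouts (resolving the ambiguity of whether the baseline may span an
earlier micro-state: it may not).  Two small biases are accepted rather
than corrected, and are why the recovery tolerance is ±3 µM: the 3-s
transition kernel leaves ~6% of the offset difference unexpressed in the
response window, and 5-s boundary quantization adds ~2–3% shrinkage; the
recovered REM→active-awake delta is ≈ −24.4 µM against a configured
−26.26 µM.

**Pre-stimulus state** is the label of the bin *before* the bin containing
the onset, so stimulus-triggered awakening cannot contaminate its own
label.  State-split evoked averages require ≥3 stimuli per state; the
pooled average equals the count-weighted mean of the per-state averages by
construction (asserted to machine precision).

# Problem sizes and determinism

Recovery studies use 10,000-s sessions (three seeds) for sleep
architecture and transitions, 2,400-s stimulated adult sessions for evoked
metrics, and 300-s resting traces for spectra (ten for the exponent; three
averaged records for the adult vasomotion peak, six for the P10 peak,
whose 0.018 Hz location sits at the noisiest end of the spectrum).  These
sizes put Monte-Carlo error comfortably inside each tolerance.  Every
random quantity descends from a single session seed; a fixed seed
reproduces every channel bit-identically, and the full pipeline is
deterministic given the seed.

# Known limitations

* Scored state fractions inherit the sampling variability of long-dwell
  states (P10 active sleep: ~±2 pp per 10⁴-s session).
* The transition-delta estimator is a shrinking estimator of the true
  offset difference (see above); comparisons across transition types are
  unaffected.
* β̂ is slightly biased upward on short records; fits on session-averaged
  spectra with the peak region excluded remove most of it.
* The EMG band (300 Hz–5 kHz) is clamped to 300–499 Hz at the 1 kHz
  default sampling rate, with a warning; tests needing the literal band
  use short 20 kHz fixtures.
* No spike sorting, no HbO/HbR spectroscopy, no fMRI signal path, and no
  cross-animal mixed-effects statistics: the pipeline emits per-subject
  summaries only.
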