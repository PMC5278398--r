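---
title: "Classifying ingestive and facial behaviors from glasses-hinge forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying ingestive and facial behaviors from glasses-hinge forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The sensing principle

Chewing rhythmically thickens the temporalis muscle under the glasses
temple. The resulting outward force is small, but the temple acts as a
lever about the hinge joint: with the muscle contact at `L_temple` from the
joint and a load cell at `L_hinge`, moment equilibrium gives

```
F_hinge = (L_temple / L_hinge) * F_temple
```

`amplification_factor()` is exactly this arm ratio (7.67 for the default
69/9 mm geometry, the hinge arm being implied by that ratio). The bench
simulator `simulate_bench()` models the validation rig as a linear-elastic
contact — temple force grows as `stiffness * (displacement - d0)` past a
contact onset `d0` (default 0), hinge force is the transmitted temple force,
and both load cells carry independent Gaussian noise. Hinge friction and
temple weight are deliberately outside the model; they are the physical
reason a real rig reads a slightly smaller factor than the geometric one,
and including them would add parameters no bench datum here could constrain.
On noise-free sweeps the regression slope equals the geometric factor to
machine precision; with 2% noise it stays within a few tenths of a percent.
Regression p-values come from the two-sided t-test of zero slope (the F-test
of a one-predictor model is equivalent); a numerically perfect fit reports
the smallest positive double rather than 0 so p stays in (0, 1].

## The six behaviors and the synthetic generator

Human hinge-force recordings are not redistributable, so
`generate_recording()` synthesizes two-channel traces with the morphology
each behavior shows at the hinges:

* **NHM** — pre-load plus a slow random-walk drift (low-passed at 0.5 Hz)
  and sensor noise on both channels.
* **LC / RC** — a sinusoid plus a 0.3-weight second harmonic at the
  subject's chewing frequency, amplitude re-drawn every mastication cycle
  (texture-dependent jitter), with the named side
  `dominant_side_ratio` times louder than the other.
* **LW / RW** — one to three smooth Gaussian pulses of 100–300 ms per 3 s
  on the named side only.
* **TK** — low-amplitude broadband bursts (an envelope from rectified
  1.5 Hz-low-passed noise modulating 8 Hz-band noise), each channel mostly
  independent with a 0.3-weight shared component for weak inter-channel
  correlation.

Chewing frequency is constrained to 0.94–2.17 Hz, the 5th–95th percentile
range of human mastication; cohort profiles draw it uniformly from
1.0–2.0 Hz. Pre-loads (1–3 N per side), gain (0.8–1.25) and dominance ratio
(2.5–4) vary per subject so that leave-one-subject-out folds face genuine
inter-individual variability. Food texture enters as amplitude/irregularity
scalars (chip 1.3 > bread 1.0 > jelly 0.7, with matching jitter); the
textures are only described qualitatively in the source material, so these
are free parameters fixed once here. No sampling rate is stated either; the
default is 100 Hz, ten times the analysis filter cutoff, with 50 Hz as the
enforced minimum (Nyquist comfortably above 10 Hz).

A `confusability` dial (default 0) shrinks the left/right chewing asymmetry
and the talking-vs-NHM amplitude gap, mimicking the misclassification
structure seen in real data (LC↔RC and TK↔NHM confusions). The default
cohort is therefore *easy by construction*: passing classification tests on
it demonstrates the pipeline is correct and leakage-free, not that real
recordings — with uncontrolled bilateral chewing, walking artifacts, or
head-size effects the generator does not model — would reach the same
scores.

## Windowing and spectral chain

Recordings are cut into consecutive, non-overlapping 3-s windows; a window
is kept only if all its samples share one label (behavior transitions are
dropped rather than majority-voted — the emulated study recorded
homogeneous behavior blocks, and pure labels keep training honest).
Each window is:

1. **Median-centered** per channel, removing the subject's pre-load; this
   makes the chain offset- and unit-invariant (the hardware records voltage,
   the generator newtons — after centering the distinction is labeling).
2. **Low-pass filtered**: zero-phase (forward–backward) 5th-order
   Butterworth at 10 Hz. Chewing stays below ~3 Hz and higher frequencies
   carry little between-class variation. The filter runs on the time-domain
   signal; spectral features are additionally restricted to the 0–10 Hz
   band. Odd-reflection padding (150 samples per end) absorbs the
   forward–backward edge transients, so DC passes exactly and the measured
   response matches the bilinear-transform closed form
   `1/(1 + (tan(pi f/fs)/tan(pi fc/fs))^(2*order))` to ~1e-5.
3. **Hann-tapered and Fourier-transformed** into a single-sided amplitude
   spectrum and periodogram PSD. A 3-s window gives a 1/3 Hz bin grid, so a
   1.5 Hz tone straddles the 1.333/1.667 Hz bins — peak-location tests use
   bin-aligned tones where exactness is asserted. No Welch averaging: the
   3-s window is the atomic classification unit, so one periodogram per
   window is the estimator of record. Without the taper the periodogram
   satisfies Parseval's identity to 1e-9 relative, which is the unit test
   anchoring the scaling.

Temporal features use the filtered, untapered signal; the taper exists only
to control leakage in the spectral estimates.

## The 84 features

The exact historical feature list is not public; the registry here is a
documented reconstruction constrained by what is known — temporal plus
spectral statistics, sides computed separately, correlation coefficient and
signal magnitude area as named cross-channel features, 84 in total:

* 20 temporal per side: mean, median, SD, variance, RMS, mean absolute
  deviation, IQR, skewness, kurtosis, min, max, peak-to-peak, zero
  crossings, peak count, mean peak height, mean inter-peak interval (0 when
  fewer than two peaks), mean |Δx|, mean |Δ²x|, waveform length, energy.
* 20 spectral per side (0–10 Hz PSD): total power, peak frequency and
  power, centroid, spread, spectral skewness/kurtosis, normalized spectral
  entropy, median frequency, 95% spectral-edge frequency, 7 band powers
  (0–0.5, 0.5–1, 1–1.5, 1.5–2, 2–3, 3–5, 5–10 Hz), chewing-band
  (0.94–2.17 Hz) power fraction, peak-to-total ratio, count of spectral
  peaks above 10% of the maximum.
* 4 cross-channel: Pearson correlation of the filtered channels, signal
  magnitude area `mean(|left| + |right|)` (the common accelerometry
  definition; none is given in the source), log left/right RMS ratio, and
  the lag (s) of the maximum normalized cross-correlation within ±0.5 s.

Peak detection uses topographic prominence with threshold 0.1 × channel SD
(no threshold is stated anywhere; this scales with the signal and ignores
noise ripple). Degenerate windows are handled explicitly: zero-variance
channels give 0 skewness/kurtosis/correlation, no-peak windows give 0 peak
features, an all-zero PSD gives all-zero spectral features — every feature
is finite by contract. Swapping the channels swaps the per-side blocks,
preserves correlation and SMA, and negates the log RMS ratio and the
cross-correlation lag; this mirror symmetry is property-tested.

Feature vectors are z-scored. The scaler is fitted on training folds only
and applied frozen to the held-out subject — a deliberate tightening of
"scale over the whole set", since scaling across folds leaks the test
subject's distribution into training. Zero-variance features fall back to
unit scale with a warning instead of producing NaN.

## Classifier, grid search, evaluation

The classifier is a C-SVM with RBF kernel `exp(-gamma * ||u - v||^2)`,
one-vs-one multiclass voting (e1071/libsvm). The bespoke content of this
module is the protocol around the solver: leave-one-subject-out folds (one
fold per subject; window-level accuracy pooled over all held-out windows),
the two-step exponential grid search (default coarse lattice C = 2^-5…2^15,
γ = 2^-15…2^3 in octave-of-4 steps; fine lattice at quarter-octave steps
within ±2 octaves of the coarse optimum), and the leakage discipline above.
Grid ties break toward the smallest C then smallest γ — the simpler, flatter
model. Whether pooled or per-subject-averaged accuracy drove the original
model choice is unknowable from the published material; pooled window-level
accuracy is used because the evaluation matrix is also window-level.

`confusion()` counts predicted classes in rows and actual classes in
columns (NHM, LC, RC, LW, RW, TK); `behavior_metrics()` reports per-class
precision (row-normalized), recall (column-normalized), F1, their
arithmetic mean, and trace-over-total accuracy. Empty rows or columns yield
`NA` plus an explicit `undefined` flag — never a silent zero. Comparisons
against printed percentage tables use half-up rounding to one decimal
(`round_half_up()`), matching how such tables are typeset; base `round()`
rounds half to even and would disagree on exact .x5 boundaries.

The packaged reference matrix (`reference_confusion()`, 20,700 windows,
3,450 per class, 10 subjects) exercises the metric code at realistic scale:
it reproduces the associated study's per-class metric table and 94.0%
average F1, with one caveat — the counts imply an RC precision of
3084/3444 = 89.5%, while the published summary row shows 89.6% for that
single cell; the counts are taken as authoritative.

## Problem sizes and reproducibility

The shipped analyses and tests use a 10-subject cohort with 60 windows per
class per subject (3,600 windows) at 100 Hz, a reduced exponential grid,
and 5 seeds for the end-to-end benchmark; the window-count check that
reproduces the 20,700-window bookkeeping (10 subjects × 6 × 345) runs at
50 Hz, one subject at a time. These sizes give stable estimates for a
well-separated cohort — LOSO average F1 is ≥ 0.99 across seeds, so the
≥ 0.90 benchmark bound is far from the noise floor. Every stochastic step
takes an explicit integer seed and restores the caller's RNG state;
identical arguments and seed give bitwise-identical cohorts, sweeps, grids
and reports.

## Known limitations

* The generator omits walking/running artifacts, accelerometer channels,
  electromyographic detail and contact-area variation; conclusions about
  real-world robustness need real recordings.
* The feature registry is a reconstruction; an alternative 84-feature list
  would slot in by replacing the registry functions, but numbered results
  would shift.
* The real optimum (C, γ) = (16, 1) from the original voltage-scaled data
  is not expected to transfer to z-scored synthetic features; on these the
  accuracy surface saturates for C ≥ 2^10 and the tie-break prefers smaller
  C.
* Only non-overlapping windows are supported; streaming/online inference is
  out of scope.
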