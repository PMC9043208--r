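---
title: "Quantifying fragmented QRS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fragmented QRS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqrs)
```

## The problem

Fragmented QRS (fQRS) — extra notches or deflections inside the QRS complex
of a surface ECG — is a marker of myocardial scar and conduction
abnormality, associated with arrhythmic and mortality risk. In clinical
practice it is read visually per lead, which is slow and suffers from
substantial intra- and inter-observer variability: five trained observers
frequently disagree on the same trace, and different published criteria
(Das-style morphology lists, stricter pattern catalogues) disagree with
each other.

This package implements a fully automated per-lead fQRS *quantification*
pipeline for short (8–10 s) resting 12-lead ECG strips. For each of the 11
analysis leads (aVR is excluded; its information mirrors the other limb
leads) the output is a continuous score in [0, 1] — the calibrated
probability that the lead is fragmented — plus its binarization at 0.5.
The stages are:

1. **Pre-processing** — zero-phase Butterworth band-pass, 0.5–70 Hz
   (order 4 high-pass, order 6 low-pass), then per-lead z-normalization.
2. **Multi-lead QRS segmentation** — per-lead R-peak detection
   (Pan–Tompkins-family envelope detector), cross-lead consolidation of the
   beat count `n_R` (the mode of per-lead detection counts), wavelet-based
   per-lead QRS delineation, cross-lead median reallocation of onsets and
   offsets, template alignment within each lead, and a correlation quality
   filter (limit `q = 0.85`) that removes ectopic and mis-delineated beats.
3. **Per-lead features** — from each valid beat: centre frequencies and
   zero-crossing counts of modes 3–5 of a 5-mode variational mode
   decomposition (VMD), three phase-rectified signal averaging (PRSA)
   summaries (mean derivative, linear-fit slope and intercept), and the
   number of prominent peaks in the QRS; averaged across valid beats.
4. **Classification** — an SVM (linear, polynomial or RBF kernel) on the 10
   standardized features, with Platt scaling mapping the decision value to
   a probability.

The rationale for the multi-lead segmentation is that fragmentation
analysis is exquisitely sensitive to the segmentation window: clip the Q or
S wave and you delete the notches you are looking for; include too much
and baseline oscillations masquerade as fragmentation. Using all leads to
fix a common beat inventory and consensus boundaries, then repairing each
lead against that consensus, is much more robust than per-lead delineation
alone.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| band-pass edges | 0.5 / 70 | Hz | removes wander and EMG noise, keeps notch energy |
| filter orders | 4 (HP) / 6 (LP) | — | sharper roll-off at the top edge, where notch-adjacent noise lives |
| quality limit `q` | 0.85 | corr | beat removed iff > half its correlations to the lead's beats fall below `q` |
| VMD modes `K` | 5 | — | established choice for ECG; modes 3–5 carry fragmentation |
| VMD `alpha` | 2000 | — | bandwidth penalty; standard default |
| VMD `tau` | 0 | — | no exact-reconstruction dual ascent (noise tolerant) |
| VMD tolerance | 1e-7 | — | convergence of the ADMM iteration (max 500 iterations) |
| PRSA window | 40 | ms | `L = round(0.02 fs)` samples half-window |
| peak prominence | 0.05 | of R amplitude | operational definition of a "peak" |
| alignment lag bound | 25 | ms | template alignment search range |
| score threshold | 0.5 | — | binarization boundary (inclusive: 0.5 maps to class 1) |

Where the published operating point exists (band edges, `q`, `K`, 40 ms
PRSA window, 0.5 threshold, 11 leads) it is the default and surfaced in
`pipeline_config()`, never hard-coded inline. The remaining values are this
package's own documented choices.

## Decisions made where the design was open

* **Filter order assignment.** The source material states orders 4 and 6
  for the 0.5–70 Hz band-pass without assigning them to edges. We use
  order 4 for the high-pass and order 6 for the low-pass: the sharper
  roll-off is more valuable at 70 Hz, next to the band where fragmentation
  energy lives. Both edges are comfortably covered either way.
* **Zero-phase filtering.** Filters are applied forward–backward with
  odd-reflection padding and steady-state initial conditions, so notch
  timing and QRS morphology are not skewed by phase distortion.
* **R-peak detector.** The original detector is part of closed tooling and
  not re-derivable; only detection quality matters downstream. We implement
  an envelope detector in the Pan–Tompkins family (8–30 Hz band-pass,
  differentiation, squaring, 150 ms integration, adaptive signal/noise
  thresholds, 200 ms refractory, search-back), with the peak refined to the
  extremum of |signal| so inverted leads behave identically.
* **Delineation.** Quadratic-spline dyadic (à trous) wavelet transform with
  modulus-maxima search. The analysis level is chosen per sampling rate to
  match scale 2² at 250 Hz (level 3 at 500 Hz, level 4 at 1 kHz). The
  onset/offset walk hops over at most two further significant modulus
  maxima (a Q/S wave, then one notch); hop candidates must clear both a
  relative threshold (0.10 of the main modulus) and twice the recording's
  modulus noise floor (2 × median |w|) — without the noise-floor guard,
  chained hops onto noise maxima run away to the search cap. Implausible
  results (duration outside 40–250 ms) are flagged missing and repaired by
  the cross-lead median step; if a beat is missing everywhere, a fixed
  ±60 ms window applies.
* **Algorithm-2 ordering.** The per-lead post-processing runs
  normalize → template → align → quality-filter, following the prose
  sequence of the method description; correlations in the quality vector ρ
  are computed on the aligned beats (configurable in principle, aligned by
  default).
* **Self-correlation in ρ.** The quality vector compares a beat to *all*
  `n_R` beats of the lead, which includes itself — one guaranteed entry of
  1.0. The `include_self` switch isolates this choice.
* **Negative correlations** in ρ are floored at zero: an anti-correlated
  beat is no more similar than an uncorrelated one, and the `q = 0`
  boundary then keeps every beat, as documented.
* **Beat-count ties.** When two detection counts are equally common, the
  larger wins: recovering a missed beat is cheaper than discarding a real
  one (the recovery search is a 40 ms |signal| maximum around the
  cross-lead average position).
* **Feature aggregation.** Features are computed per beat and averaged
  across the lead's valid beats (a template-only switch exists). VMD on
  concatenated beats would mix inter-beat baseline into the modes.
* **Hyperparameter search.** The original work tuned the SVM by Bayesian
  optimization, to which no claims are attached. We substitute a seeded,
  grouped, cross-validated grid search (C over 1e-3…1e3, RBF gamma over
  1e-3…1e1, polynomial degree 2–4), selecting by out-of-fold ROC AUC —
  deterministic and dependency-light. Folds are grouped by recording so no
  patient straddles a fold boundary.
* **Calibration.** Platt's sigmoid is fitted by the regularized Newton
  method on *out-of-fold* decision values (internal 5-fold CV), avoiding
  calibration-on-training bias.
* **Feature standardization** (z-score with training statistics) precedes
  the kernel: Hz-scaled centre frequencies and unit-free slopes would
  otherwise be weighted arbitrarily.
* **Kappa sweep grid.** 100 uniform thresholds in [0, 1] with the point
  nearest 0.5 snapped to exactly 0.5, so the fixed-threshold metric is one
  grid case of the sweep (a uniform 100-point grid cannot otherwise contain
  0.5). Ties resolve to the lowest threshold.
* **Undefined rates** (e.g. PPV with no positive predictions) are reported
  as missing, never as zero.

## What the synthetic generator emulates — and what it does not

No clinical data ships with this package; every test runs against
synthetic multi-lead ECG with analytic ground truth. The generator's
defaults are a *stated world*, chosen once:

* **Beats** are Gaussian sums (P, Q, R, S, T) whose centres and widths
  scale with the requested QRS duration, so true R location, QRS support
  and notch positions are exact by construction. 10 s at 500 Hz.
* **Rhythm**: sinus RR is Gaussian with CV 0.03; AF-like RR is lognormal
  with CV 0.2, independent draws, no periodicity. Cohorts default to 10%
  AF and 50% broad QRS (125–165 ms), echoing the mix reported for ICD
  cohorts.
* **Fragmentation** is injected as narrow Gaussian deflections (6 ms FWHM)
  that deflect *against* the local waveform — a dip carved into an upright
  wave — because that is how visible fragmentation presents. For
  full-agreement ("clearly fragmented") leads, notch amplitude is drawn
  from 0.18–0.32 of the R amplitude and placements are chosen greedily so
  each notch creates a distinct prominent turning point; this encodes the
  premise that unanimous labels correspond to *visible* notching. Notch
  patterns are fixed per lead across beats (fragmentation is a stable
  conduction property).
* **Ambiguous leads** (default 20% of fragmented leads in a cohort) get
  sub-threshold amplitudes (0.07–0.155) and emulated ordinal labels 1–4
  from a noisy 5-observer threshold model; 0 and 5 occur exactly when the
  amplitude is outside the ambiguity band. This is an emulator of observer
  disagreement, not a model of any real panel.
* **Ectopics** replace a beat (all leads) with a widened, inverted
  morphology at a configurable per-beat probability.
* **Noise**: white (sd 0.03 of R amplitude), baseline wander (0.1 at
  0.3 Hz), and 50 Hz powerline (0.02) — European mains.

Not emulated: a physiologically consistent vectorcardiographic projection
across leads (each lead is an amplitude/polarity-scaled copy plus noise),
P/T-wave pathology, rhythms beyond AF-like irregularity, electrode
artefacts, and notch-location correlations with coronary territories.
Consequently a green end-to-end test establishes that the pipeline's
machinery — segmentation under irregular rhythm and ectopy, feature
directionality, learning, calibration — behaves as designed on data whose
difficulty is controlled; it does *not* establish clinical performance,
which the original study measured on private multi-centre data.

## Numerical notes

* **VMD** runs entirely in the frequency domain after an even ("mirror")
  extension of half the signal length on each side; reconstruction error
  concentrates at the crop boundaries where the mirror kink leaves
  broadband energy no narrowband mode can absorb. The error therefore
  shrinks with signal length; the two-tone correctness check uses a
  recording-length (10 s) probe, where the mode sum reconstructs within
  5%. (An anti-symmetric extension was evaluated and is worse: it trades
  the derivative kink for a wrap-around step.) Centre frequencies are
  initialised uniformly over (0, 0.5) cycles/sample, making the
  decomposition deterministic.
* **PRSA** windows that would overrun the segment are discarded, not
  padded; ties (`x_i = x_{i-1}`) are not anchors. On a pure ramp every
  window is a shifted copy, so the curve reproduces the ramp slope to
  machine precision — this closed form is frozen into the tests at 1e-9.
* **Peak counting** uses topographic prominence on the amplitude-normalized
  beat (threshold 0.05 of R), counting maxima of the waveform and of its
  negation.
* **SMO** (sequential minimal optimisation) solves the SVM dual with
  deterministic working-set heuristics; two runs that differ only in row
  order select identical hyperparameters and agree in score to ~1e-2
  (iteration order perturbs the support-vector set at bound tolerance).
* **Alignment ties** in the template cross-correlation resolve toward zero
  lag; the binarization boundary is inclusive (score 0.5 → class 1).

## Known limitations

* The features describe whether a lead is fragmented, not where the
  notches sit; criteria that weight notch location (terminal S-wave
  notching, for instance) are outside what this feature set can express —
  a property shared with the method this package implements.
* Very narrow QRS at low sampling rates (250 Hz) leaves few samples per
  wave; delineation errors of 1–2 samples are then a large fraction of the
  QRS and scores become less reliable.
* Scores are calibrated against the synthetic world of the training
  cohort. Retraining (or at minimum recalibration) is required before any
  use on real recordings, and the package makes no clinical claims.
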