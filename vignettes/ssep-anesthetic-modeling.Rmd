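---
title: "Modeling anesthetic dose effects on SSEP waveforms with ssepml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling anesthetic dose effects on SSEP waveforms with ssepml}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssepml)
```

## The problem

During spine surgery, somatosensory evoked potentials (SSEPs) — scalp
responses to peripheral nerve stimulation, averaged over many stimulation
sweeps — are monitored continuously to detect impending neurological
injury. Volatile anesthetics confound this surveillance: with rising
end-tidal sevoflurane concentration, evoked-component amplitudes shrink and
latencies lengthen, so a pharmacological effect can masquerade as a
surgical one. `ssepml` implements a complete pipeline for quantifying that
dose effect the other way around: treating the anesthetic concentration as
the regression *target* ("reverse regression") and predicting it from a
rich set of waveform features, so that the share of waveform change
attributable to the anesthetic can be modeled explicitly.

Because intraoperative recordings cannot be redistributed, the package is
built around a fully seeded synthetic-session generator with known,
controllable concentration effects. Every downstream stage — feature
extraction, normalization, feature selection, model comparison — is
testable against the generator's closed forms.

## The synthetic generator

A session is four monitored nerves (left/right ulnar, left/right posterior
tibial), three recording montages each, sampled across a surgery, plus a
per-minute end-tidal sevoflurane series. A trial waveform is a sum of
Gaussian bumps, one per named evoked component, with additive white and
1/f noise:

$$ w(t; c) \;=\; \sum_i p_i\, A_i\, e^{-k_A c}\,
   \exp\!\left(-\frac{(t - L_i - k_L c)^2}{2 s_i^2}\right) \;+\;
   \varepsilon_\text{white}(t) + \varepsilon_{1/f}(t), $$

where $c$ is the concentration (%), $p_i \in \{\pm 1\}$ the component
polarity, $A_i$ and $L_i$ the base amplitude (µV) and latency (ms), and
$s_i$ the width (ms). Cortical ulnar channels carry N20/P30, the
subcortical (CS5–Fpz) ulnar channel N13/P14, and all tibial channels
P37/N45, each at its nominal latency. The dose effect is
multiplicative-exponential in amplitude ($e^{-k_A c}$) and linear in
latency ($+k_L c$ ms): the simplest forms that keep amplitudes positive
and reproduce the known directions (amplitude down, latency up). Gaussian
bumps were chosen because their peak locations, scale laws, and overlap
corrections are available in closed form, which the test oracles exploit.

Key defaults, chosen once:

| parameter | default | unit | rationale |
|---|---|---|---|
| `sample_rate` | 5000 | Hz | clinical-range sampling; 0.2 ms latency grid |
| `window_ms` | 100 | ms | contains the latest component (N45) with margin |
| `amp_atten_k` ($k_A$) | 0.3 | per % | ≈ 45% amplitude loss at 2% et-sevo |
| `lat_shift_k` ($k_L$) | 0.8 | ms per % | ≈ 1 ms prolongation near 1 MAC, a modest, physiologic effect |
| `noise_sd`, `pink_noise_sd` | 0.005 | µV | post-averaging noise level (see below) |
| `trials_per_nerve` | 30 | – | acquisition cadence is site-specific; configurable |
| `session_minutes` | 120 | min | typical lumbar-fusion monitoring span |

The concentration profile is piecewise: a linear induction ramp (default
10 min, 0 → maintenance mean), an AR(1) maintenance plateau (mean 2.0%,
stationary SD 0.25%, lag-1 correlation 0.8 — slow drift around the
anesthesiologist's set point), and an exponential emergence decay (rate
0.35/min over the last 10 min). Most concentration variability therefore
sits at the start and end of the session, as it does in practice.

**Noise calibration.** The feature set uses the first three principal
components of each channel's trial matrix, and the generator is required
to emulate data in which those three components carry ≈ 95% of the
waveform variance. Two generator terms inflate the effective rank: the
noise floor (variance spread over *all* components) and the latency-shift
family (a shifted bump sweeps a continuum of directions; only its first
two to three Taylor terms are low-rank). The defaults above — a modest
latency coefficient and a noise SD of 0.25% of the largest component
amplitude — were fixed from this variance budget at design time and then
left alone. They are defensible physically because each "trial" is
already an average of hundreds of stimulation sweeps, so its residual
noise is far below raw-EEG level. At these defaults the canonical
cortical channel carries ≈ 99% of variance in three components and the
worst channel (the subcortical N13/P14 pair, whose opposed bumps overlap
and partially cancel) ≈ 95–96%.

What the generator deliberately does **not** model: volume conduction and
electrode geometry, surgical insults or positioning artifacts, drifting
baselines, inter-patient morphology differences beyond the seeded noise,
and any modality other than SSEP. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline recovers a dose effect *of the
assumed form* from data *with this structure* — they do not certify
performance on real operating-room recordings.

## Feature extraction

Eleven features per channel, in five categories (3 channels × 11 = 33 per
nerve; 4 nerves × 33 = 132 per patient):

1. **Phase-space-curve area** (1): the waveform is delay-embedded as
   $[x(t), x(t+\tau), x(t+2\tau)]$ with $\tau$ = 2 ms, the trajectory is
   projected onto its first two coordinates, and the absolute shoelace
   area of the closed projected polygon is returned. The area scales as
   amplitude squared; a sinusoid with $\tau$ = quarter period traces a
   circle of area $\pi A^2$ per traversal — both used as oracles. The
   embedding is built within a trial; a cross-trial variant (connecting
   corresponding points of successive trials) is a possible alternative
   reading of the construction and was considered but not implemented.
2. **Evoked latencies** (2): strict argmax (peak) and argmin (valley)
   inside per-component search windows, ties toward the earlier sample.
   Windows extend ±5–10 ms around the nominal latencies (N20: 15–25 ms,
   P30: 25–40 ms, N13: 10–16 ms, P14: 11–18 ms, P37: 30–45 ms, N45:
   40–55 ms) — wide enough to track dose-driven prolongation, narrow
   enough not to capture a neighboring component; all config-exposed.
3. **Evoked amplitudes** (2): waveform values at those two latencies.
4. **Time-frequency peak** (3): Hann-windowed short-time spectrogram
   (20 ms window, 50% overlap, 10–500 Hz band), returning the frequency,
   power, and window-center time of the global in-band maximum. An
   all-zero signal returns the documented degenerate triple (band
   minimum, 0, 0) with a warning.
5. **PCA scores** (3): per patient × channel, the trial-by-sample matrix
   is mean-centered across trials and each trial's scores on the first
   three principal components are kept; each component's sign is fixed so
   its largest-magnitude loading is positive. PCA is fitted per patient
   (never pooled across the cohort) so that test patients can never leak
   into training-feature construction; the alternative — pooled PCA —
   was rejected for exactly that reason.

## Normalization and problem framing

Features are rescaled by $(x - \mathrm{median})/\mathrm{IQR}$ with
linear-interpolation quartiles, which bounds the influence of outlying
trials. In the default leakage-safe mode the normalizer is fitted on the
training patients' rows only and applied unchanged to the test patients;
a `fit_on_all` switch reproduces a consolidated-cohort fit for
compatibility with analyses that normalize before splitting. Zero-IQR
(constant) features are flagged and dropped. The target is *never*
normalized: it stays in physical % units. Notably, the conventional
automatic constants of support-vector regression — box constraint
$\mathrm{IQR}(y)/1.349$ and epsilon $\mathrm{IQR}(y)/13.49$ — evaluate to
0.7413 and 0.0741 exactly when the response has unit IQR, so reported
constants of that size in an analysis indicate a unit-IQR-normalized
response; this package instead derives both constants from the response
spread at training time.

## Feature selection

Greedy quotient MRMR: relevance is the plug-in mutual information between
a feature and the target on equal-frequency bins
($\min(10, \lceil\sqrt{n}\rceil)$ per variable); the first pick maximizes
relevance and each later pick maximizes
relevance ÷ (mean MI with the already-selected set). The quotient scheme
and the binned plug-in estimator are deterministic and cheap enough to
verify against an exhaustive greedy oracle. A feature whose relevance is
exactly zero after binning (in practice: a constant) is insignificant;
the selection keeps at most the top ten significant features. The
importance-score scale of other MRMR implementations differs; behaviour,
not score values, is what this module documents.

## The model bank and evaluation

Ten presets under one train/predict contract, in canonical order: linear
least squares; fine/medium/coarse regression trees (MSE split criterion;
minimum leaf 4/12/36 with minimum parent 2× the leaf size — only the
coarse pair 36/72 is a published convention, the finer sizes follow the
usual preset ladder); linear/quadratic/cubic ε-insensitive
polynomial-kernel SVMs (predictors standardized; kernel scale "auto" =
median pairwise Euclidean distance among standardized training rows, an
explicit stand-in for undocumented vendor heuristics; automatic C and ε
as above); and narrow/medium/wide single-hidden-layer networks (10/25/100
sigmoid units via `nnet` — the classical single-layer tool in R, which
offers logistic rather than rectified activations — linear output,
responses standardized internally, iteration cap 200, which is past the
convergence plateau at these data sizes, seed-deterministic
initialization). Trees support a `max_splits` cap implemented by growing
with complexity cost zero and pruning back along the complexity table;
the default is uncapped, since published split counts are data-size
artifacts.

Evaluation holds out two patients (splits are patient-level and
seed-deterministic), five-fold cross-validates the remaining patients'
trials, and reports RMSE, MSE, MAE and R² on the *pooled* out-of-fold
predictions (per-fold averaging is the alternative; pooled was chosen and
is what the metric identities in the tests assume — pooled R² can be
negative). Folds are drawn at the trial level by default; `grouped_cv`
gives patient-grouped folds for comparison. The preset with the lowest
validation RMSE wins (ties break toward the earlier preset in listing
order) and only the winner is refitted on all training rows and scored on
the held-out patients. A no-leakage audit — deleting the test patients'
rows and recomputing — changes no fitted parameter in default mode.

## Numerical choices and degenerate inputs

* Latency grid: 5 kHz sampling puts detected latencies on a 0.2 ms grid;
  all nominal component latencies are grid points. Component widths are
  narrow relative to separations, so overlap shifts true extrema by
  < 0.05 ms for the cortical and tibial pairs — below half a grid step —
  which is what makes the exact latency calibrations (20/30, 37/45 ms)
  stable. The subcortical N13/P14 pair genuinely overlaps; its detected
  extrema sit near 12.6/14.4 ms, inside their windows.
* Synchronization matches each trial to the nearest reading within a
  60 s tolerance (one sampling interval); exact midpoints resolve to the
  earlier reading; no interpolation between readings is ever performed —
  a matched concentration is always a verbatim series member.
* Constant response: every model family returns the constant.
  Constant features: MI 0, flagged by the normalizer, insignificant to
  MRMR. All-identical trial matrices: zero PCA scores, variance
  fractions reported as undefined.
* Ties everywhere break deterministically toward the earlier index
  (samples, readings, columns, presets).

## Problem sizes used in the shipped checks

The package's own test suite runs desk-scale problems chosen to exercise
every contract: cohorts of 3 patients × 8 trials per nerve for structural
checks, and a 20-replicate recovery study at the full 10-patient cohort
with 12 trials per nerve and one nerve modeled, in which the tournament
winner's holdout RMSE must beat the constant predictor in at least 90% of
replicates. The acceptance script reports the three-component variance
share (median over 20 seeded single-patient replicates of the canonical
cortical channel) and the two noiseless latency calibrations.

## Known limitations

* The generator's dose-effect forms are exactly the forms the feature
  set is good at detecting; real dose responses are noisier, partially
  confounded (blood pressure, temperature, other agents), and not
  time-invariant.
* The MI estimator's plug-in bias is positive and grows with bin count;
  rankings are comparable within a table, not across sample sizes.
* `nnet`'s sigmoid hidden layer is the one deliberate departure from a
  rectified-unit design; at these widths and data sizes the function
  class is comparably expressive.
* The session JSON dialect is this package's own; it does not parse
  vendor exports.
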