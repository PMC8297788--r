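---
title: "Detecting cow behavior from reticular pressure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cow behavior from reticular pressure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rumipress` detects cow behaviors — rumination, eating, drinking, sleeping —
from pressure measured in the reticulum every 0.5 s. This vignette is the
package's account of the science: the signal model behind the synthetic
generator, the two detection algorithms, the parameters that matter, the
numerical conventions, and what the synthetic results do and do not show
about real data.

## The signal model

The reticulorumen's primary contraction cycle (A-wave) begins with a
biphasic reticular contraction — two sharp pressure peaks a few seconds
apart — and propagates caudally over the cranial, dorsal and ventral rumen
sacs. During rumination a third reticular contraction joins the cycle,
giving a triphasic signature; the regurgitation cycle also paces the
contractions differently. Between cycles the reticulum is quiescent.

The generator (`generate_session()`) renders this as:

- **Cycle waveform.** Each peak is a Gaussian bump; a cycle is 2 or 3 bumps
  (`contraction_template()`). Defaults: amplitude 1.0 pressure unit with
  ±10% per-peak uniform jitter, 2.0 s full width at half maximum, apices
  4.0 s apart. The waveform's support is truncated 1.5 × FWHM beyond the
  outer apices, where the Gaussian has decayed below 0.2% of its amplitude;
  ground-truth cycle start/end times refer to these support edges. Real
  contraction waveforms are asymmetric and variable in shape; published
  traces are qualitative, so a symmetric bump with amplitude jitter is the
  most defensible minimal model.
- **Inter-cycle intervals.** The peak-free gap between the end of one cycle
  and the start of the next — *not* apex-to-apex — is drawn from a Normal
  distribution truncated below at 5 s, with behavior-specific mean (SD):
  rumination 48 (12.1) s, eating 34 (12.7) s, drinking 35 (12.9) s,
  sleeping 41 (11.4) s, other 40 (23.1) s (`default_interval_params()`).
  Observed interval tables report mean/SD and median/IQR with mild skew but
  no distributional family; the truncated Normal is the simplest choice that
  prevents negative gaps. Cycle placement restarts at each behavior-segment
  boundary, so no cycle straddles two behaviors.
- **Noise.** Additive white Gaussian measurement noise (SD 0.05 pressure
  units, i.e. 5% of peak amplitude) plus a Gaussian random-walk baseline
  drift (per-sample SD 0.002), emulating the slow baseline wander a pressure
  apparatus is designed to minimize but never eliminates.
- **Labels.** Generated directly on the 0.5 s grid. Field data scored from
  video at 1 s resolution can be brought onto the grid with
  `expand_labels()`.
- **Multi-compartment option.** `generate_multicompartment()` shifts the
  noise-free reticular cycle train by strictly increasing per-compartment
  lags (defaults 0, 3, 8, 14 s) and adds independent noise, reproducing the
  caudal propagation order of the A-wave. Only generation is supported;
  detection always runs on the reticulum trace.

Not modelled: secondary (B-wave) eructation contractions, disease states
(ruminal stasis, acidosis), diet or production-stage effects, and any
behavior-dependence of waveform shape beyond the third rumination peak.

## The peak-detection algorithm

All detection runs on the per-session z-scored trace (`normalize_trace()`):
working on raw data makes the threshold sensitive to gain and baseline, and
is a known source of false positives.

1. **Sharp peaks** (`detect_peaks()`). A sample is an apex if it is a local
   maximum (earliest sample on plateaus) whose value exceeds some sample in
   the preceding `rise_timespan` (3 s) by at least `rise_threshold`, and
   likewise some sample in the following 3 s. Every qualifying local maximum
   is emitted; this makes the peak count provably non-increasing in the
   threshold. The onset is the earliest qualifying rise start in the
   timespan and the offset the latest qualifying fall end; overlapping
   supports of consecutive peaks are trimmed at the interior valley.
   `rise_threshold` defaults to 1.5 normalized units: contraction peaks on a
   z-scored session sit near 3–3.5 units while the measurement noise is
   ~0.2 units, so 1.5 is ≥ 7 noise SDs (noise and drift fail the rule) yet
   less than half the contraction amplitude (real peaks pass even with
   amplitude jitter).
2. **Cycles** (`group_cycles()`). Maximal runs of peaks with apex-to-apex
   gaps ≤ 12 s form one cycle (intra-cycle apices are ~4 s apart,
   inter-cycle gaps tens of seconds, so the rule is insensitive to the exact
   cut in between). `intercycle_intervals()` returns the peak-free gaps
   between consecutive cycles.
3. **Rumination rule** (`classify_rumination()`). A 0.5 s timepoint is
   flagged when its trailing 75 s window overlaps at least one qualifying
   cycle: any three-peak cycle, or a two-peak cycle whose span is within 20%
   of the running median three-peak span — the occasional rumination cycle
   whose middle peak is missed still has three-peak timing. The running
   median initializes after five three-peak cycles; before that the
   exception is inactive, so purely biphasic (eating) sessions are never
   flagged through it. Windows are trailing (causal) and clipped at the
   session start.

The onset/offset convention deserves a note: because the rise is referenced
to the *earliest* qualifying sample within the timespan, detected supports
extend to where the signal is indistinguishable from baseline, and the
detected peak-free gap matches the generator's ground-truth gap with no
systematic offset — the 4 h parameter-recovery analyses recover the 48 s
(rumination) and 34 s (eating) means well within ±2 s.

## The spectral-feature random-forest pipeline

The normalized trace is cut into 120 s windows of 240 samples sliding by one
sample (119.5 s overlap); each window is labeled by its final timepoint (a
causal convention; the matching timepoint is otherwise arbitrary) and
reduced to 30 features:

- **Fourier magnitudes** (10): amplitudes `2|X_k|/n` of discrete-Fourier
  bins 1–10 of the mean-removed window. The bin spacing is 1/120 Hz, so the
  contraction fundamentals (1/48 ≈ 0.021 Hz, 1/34 ≈ 0.029 Hz) fall in bins
  2–4: the band is informative by construction.
- **Band power** (10): a Hann-tapered modified periodogram of the full
  240-sample window, averaged over ten equal-width bands covering
  (0, 0.1] Hz. A single full-window periodogram (rather than averaging
  shorter segments) keeps the frequency grid at 1/120 Hz so every band
  contains at least one bin; with 120-sample segments, four of the ten bands
  would be empty. The periodogram is normalized so that with a rectangular
  taper the bin powers sum to the window variance (Parseval), which the test
  suite verifies at 1e-6 relative tolerance.
- **Autocorrelations** (10): sample autocorrelation at lags 5, 10, …, 50 s,
  straddling all behaviors' mean gaps. Matches `stats::acf` exactly.

Zero-variance windows yield an all-zero feature vector by convention rather
than an error. `build_feature_matrix()` computes all windows via rolling
sums and sliding dot products — algebraically identical to the per-window
reference `extract_features()` (the suite checks agreement at 1e-6) but
O(n·p), about 3 s for a 4 h session.

Classification is one-vs-all: each behavior is predicted against the union
of the others (`train_one_vs_all()`), with multiclass combination left to
the user. Forest defaults are conventional — 500 trees, ⌊√30⌋ = 5 features
per split, minimum node size 1 — exposed in `forest_spec()`, with
`auc_sweep()` available to choose sizes by inspecting out-of-sample AUC.
Vote ties predict negative: for a monitoring alarm a missed half-window is
cheaper than a spurious alert.

**Rebalancing** (`balance_classes()`): positives may be replicated
(`upsample_factor`, 3 mirroring the treatment of rare classes like drinking
and sleeping; one full copy is always kept so no positive is lost) and
negatives are down-sampled without replacement to a 1:1 ratio. The default
is factor 1 — down-sampling only — applied to the whole set before
splitting; published resampled test counts are most consistent with
positives not being replicated into the evaluated set. Both orderings are
reachable through the exported functions.

**Validation** (`make_split()`, `run_validation()`): 70/30 label-stratified
hold-out, label-stratified 5-fold cross-validation (each row in exactly one
test fold) and leave-one-animal-out (one fold per cow). Splits are row-level
by design fidelity: overlapping windows make neighbouring rows share 239 of
240 samples, so hold-out and SCV estimates are optimistic leakage-inflated
numbers, while LOOA is the honest between-animal generalization probe. The
default cohort therefore generates its last cow with interval means
multiplied by 1.2, and LOOA degrades visibly while SCV stays near-perfect —
the qualitative pattern expected from animal-heterogeneous data.

## Evaluation conventions

`confusion()` tallies per-timepoint (or per-window) TP/FP/TN/FN;
`metrics()` computes Se, Sp, PPV, NPV, F1 (harmonic mean of PPV and Se) and
Acc at full precision, with any zero-denominator metric reported as `NA`
(undefined) rather than silently coerced to 0 or 1 — degenerate folds should
be visible, not distorting. Tables are rendered with counts first and the
six metrics in the order Se, Sp, PPV, NPV, F1, Acc, rounded to 2 decimals
only at the reporting layer. Interval summaries use the sample SD (n−1) and
linear-interpolation (type-7) quartiles.

## Problem sizes and determinism

The package's own analyses run at desk scale, chosen to keep a full run in
minutes on one CPU while leaving Monte-Carlo error far inside the tolerances
checked:

- Parameter recovery: five 4 h single-behavior sessions per behavior
  (~230 rumination or ~310 eating cycles each; pooled standard error of the
  gap mean ≈ 0.35 s against a ±2 s check).
- Classifier bounds: 2 h sessions for the rule-based detector; the default
  `run_experiment()` cohort is 4 cows × 1 h with 200-tree forests
  (~28,000 windows), enough for the leakage/LOOA contrast above.

Every stochastic step takes an explicit seed (sessions, balancing, splits,
forests via `ranger`'s seeded, single-threaded mode), and the full
experiment writes byte-identical output files when rerun with the same
configuration.

## Known limitations

- The generator's cycle shapes, noise levels and schedule structure are
  idealized; passing the synthetic performance bounds shows the algorithms
  implement their rules correctly and recover the generating parameters, not
  that they would reach the same numbers on sensor data from real animals,
  where waveform variability, eructation contractions, posture artifacts and
  label noise all intrude.
- The exact threshold/timespan constants, the identities of the 30 spectral
  features, and forest hyperparameters used in any particular field study
  are rarely published; the defaults here are principled stand-ins and all
  are configuration-exposed.
- Rule-based detection covers rumination only — the other behaviors show no
  comparably distinctive peak pattern, which is precisely the niche of the
  feature-based classifier.
- Four-compartment data can be generated but not analysed; detection always
  uses the reticulum.
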