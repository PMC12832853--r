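---
title: "Methods: semi-supervised balance assessment from plantar pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-supervised balance assessment from plantar pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantarssl)
```

## The problem

The Berg Balance Scale (BBS) is a 14-item clinical balance assessment, each
item scored 0–4 for a total of 0–56 points. Administering it requires a
trained evaluator and substantial time, and scores at the low end of the
scale are known to be less reliable — they are more sensitive to the
subject's momentary state and to assessor judgment. `plantarssl`
implements a pipeline that predicts BBS scores from pressure-sensing
insoles worn during ordinary walking: 8 piezoresistive sensors per foot
(hallux, three metatarsal heads, medial/lateral midfoot, medial/lateral
heel), sampled at 20 Hz in Newtons, 16 channels in total.

The pipeline has five stages: (1) gait-cycle detection, (2) extraction of
a 156-dimensional biomechanical feature vector, (3) screening of the
training labels for anomalies by a multi-model error consensus, (4)
two-step feature selection, and (5) a consistency-regularized
semi-supervised linear regression whose supervised loss uses only the
samples that survive screening, while the flagged samples contribute
unlabeled consistency information.

Because clinical cohorts of this kind are private, the package ships a
synthetic gait generator with a known ground truth, so every stage is
testable end to end.

## Gait-cycle detection

Each foot's eight channels are summed into one load signal. After mean
subtraction, the magnitude spectrum restricted to the physiological gait
band 0.3–3.0 Hz yields a candidate stride frequency (the band excludes DC
leakage and out-of-range rates; the spectral peak must also exceed 3× the
median in-band magnitude, otherwise the signal is treated as aperiodic).
The candidate lag `P0 = round(fs / f*)` is then refined with the unbiased
autocorrelation.

A subtlety drives the refinement design: the within-stride load pattern of
a foot is double-bumped (heel strike, then push-off), so the largest
spectral peak frequently sits at the *second harmonic* of the stride rate.
A refinement window of ±50% around `P0` alone can then never reach the
true lag. The package therefore searches ±50% windows around integer
multiples `k·P0` (k ≤ 3) and keeps the smallest lag whose autocorrelation
comes within 5% of the best window's maximum — the standard octave-error
resolution, still preferring the spectral estimate. On noiseless
synthetic gait this recovers every stride period from 16 to 30 samples
exactly, which the test suite asserts.

Left and right periods are unified: adopted directly when equal, otherwise
averaged and rounded half-up (base R's `round()` is half-to-even, so the
package pins the conventional rule explicitly).

## The 156 features

The feature vector decomposes over the named families as
6 × 16 + 4 × 2 + 6 × 8 + 4 = 156:

* **Per sensor (6 × 16):** peak pressure PPP (N); pressure–time integral
  PTI by the trapezoidal rule (N·s); maximum and minimum pressure
  gradients by forward first difference × fs (N/s); full width at half
  maximum FWHM of the pressure pulse (s); and area-based average pressure
  AP, the mean over samples above 5% of the cycle peak (N). Each is
  computed per gait cycle and averaged over the recording's complete
  cycles; an all-zero cycle contributes zero to every feature.
* **Per foot (4 × 2):** total average pressure TAP (time mean of the
  8-sensor sum); forefoot/rearfoot peak ratio F/R (summed sensors 1–4
  over summed 7–8, 0 when the rearfoot never loads); and the total
  per-axis centre-of-pressure displacement COPX/COPY, normalised per
  complete cycle, using only frames carrying at least 1% of the foot's
  maximum load.
* **Symmetry indices (6 × 8 + 4):** for each sensor pair and each
  whole-foot feature, `SI = |vL − vR| / ((|vL| + |vR|)/2) × 100`,
  defined 0 when both sides are 0. Absolute values in the denominator
  keep the index defined for the signed gradient features; SI always lies
  in [0, 200].

Two numerical conventions deserve note. FWHM is the width of the
*contiguous* half-height region containing the peak, with linearly
interpolated crossings; where the region touches the cycle boundary
without crossing, the boundary extends half a sample past the end sample,
so a constant cycle has FWHM equal to the full cycle duration. And cycle
segmentation is *phase-aligned per foot*: the cycle boundary of a cyclic
waveform is arbitrary, so the package folds each foot's load signal over
the period and cuts at the quietest seam (the phase minimising the load
on the segment between consecutive windows). This keeps each stance pulse
contiguous inside one window and makes the cycle-averaged features
invariant to the stride phase at which the recording happens to start —
without it, a pulse straddling the cut is split and the two feet (which
walk half a stride apart) would receive different feature values even
for perfectly symmetric gait.

The exact sensor-to-index map and coordinates are a reconstruction
(configurable via a layout JSON): 1 = hallux through 8 = lateral heel,
with normalised coordinates whose only role is the relative geometry of
the COP path.

## Z-score normalization

Features are standardized as `z = (x − μ)/σ` with mean and sample
standard deviation fitted on the *training group only*; test data reuse
the training parameters, so no information leaks across the split.
Constant features receive σ := 1 (standardizing to zero) with a warning.
Normalization is fitted before label screening, which consumes the
standardized matrix.

## Label-noise screening

Three probe regressors — ordinary least squares, linear-kernel SVR, and
RBF-kernel SVR (C = 1, ε = 0.1, γ = 1/(d · var(X)); SVR via `e1071`) —
are each run in 4 randomised replicates. Within a replicate, each
sample's label-quality score is its mean absolute prediction error over 3
random 5-fold partitions, where the probe is refitted on each 80%
complement and every sample is scored by the refit that held it out.
Scoring out-of-fold is essential here: with 156 features and ~105
training rows every linear probe interpolates its training rows, so an
in-sample error would be numerically zero and carry no information about
label quality.

Each of the 12 model-replicate error vectors is thresholded at its 50th
percentile (linear interpolation between order statistics); samples
*strictly above* the threshold form a candidate set — exactly
⌊131/2⌋ = 65 candidates when errors are distinct. A sample flagged in at
least 8 of the 12 sets is declared anomalous; a strict mode that
intersects the three models' aggregate sets is available as an option.
Flagged samples keep their feature rows but lose their labels: they move
to the unlabeled set and their original scores are never used again.

A counting consequence worth understanding: because every candidate set
holds exactly half the cohort, the frequency consensus cannot produce an
arbitrarily small anomaly set. Even if error rankings were pure noise
across replicates, about 19% of samples would reach 8 of 12 by chance;
any stable component in the errors (label noise, but also systematic
model misfit) pushes the yield toward 50%. On cohorts with strong
injected label noise the consensus concentrates on the truly corrupted
labels — the suite asserts ≥ 80% recall of 42 large injected corruptions
at the cohort scale of 131 — but the flagged set also retains a margin
of clean, hard-to-fit samples. This is inherent to the
median-threshold/consensus design, not a tuning artifact, and it is the
main limitation discussed at the end.

## Two-step feature selection

First, features whose names match configurable exclusion patterns are
dropped; the default removes the minimum-pressure-gradient family
(`*_minPG`, `*_minPG_SI`, 24 of 156), whose sign conventions make them
poor candidates as biomechanical predictors. Second, Pearson-correlation
pruning: pairs with |r| > 0.8 on the training data are resolved greedily
in decreasing |r| order, dropping the member with the larger mean
absolute correlation to the remaining features (ties drop the later name
in canonical order), re-evaluating after each drop; survivors satisfy the
pairwise bound by construction. Third, an L1-penalised path (`glmnet`)
with the penalty chosen by 5-fold cross-validated MSE on the labeled
samples (folds shuffled under the run seed); the 10 features with the
largest absolute coefficients at that penalty are selected, relaxing the
penalty down the path if fewer than 10 are active at the optimum.

## Consistency-regularized semi-supervised regression

The model is affine in the selected standardized features,
`f(x) = w·x + b`, trained by full-batch gradient descent on

    L = 1/Nl · Σi (f(xi) − yi)²  +  λu · 1/Nu · Σj (f(xj) − f(xj + δj))²

with the supervised sum over the labeled samples and the consistency sum
over the unlabeled (screened-out) samples, each perturbed by a fresh
zero-mean Gaussian draw δj (sd σδ per coordinate) at every iteration from
a seeded stream. For an affine model the consistency term reduces to
(w·δ)², with expectation σδ²‖w‖² — an isotropic ridge penalty whose
strength is λu·σδ². Defaults: λu = 1, σδ = 0.1, learning rate 0.01, at
most 5000 iterations, stopping early when the relative change of the
total loss falls below 1e-8. With λu = 0 the trainer provably converges
to the least-squares solution, which the suite checks against the
normal-equations oracle to 1e-6; the analytic gradient is verified
against central finite differences; and the Monte-Carlo mean of the
consistency term is checked against σδ²‖w‖² within three standard
errors.

Predictions can be clamped to the BBS range [0, 56]; the clamp is on by
default in `predict()` but off in the pipeline's evaluation metrics,
which characterise the unconstrained regression behaviour. RMSE, MAE and
R² are reported per split, with R² undefined (NA) for a zero-variance
target.

## The synthetic cohort

Each subject carries a latent balance score b ∈ [0, 1], drawn uniformly
on [0.15, 1], with true BBS = round(56·b). Every sensor emits one
raised-cosine pulse per gait cycle inside a region-specific stance-phase
window (heel 0.05–0.35 of the cycle, midfoot 0.25–0.55, metatarsal
0.45–0.80, hallux 0.60–0.90), amplitude proportional to a 600 N body
weight times a per-region load share; the feet alternate by half a
stride. Degraded balance (low b) adds, in proportion to 1 − b:
per-cycle period jitter (gain 0.04), left/right amplitude asymmetry
(gain 0.5), sensor noise (1 N at full degradation), stance broadening
(pulse widths up 25%), and a forefoot-to-rearfoot load shift (25%) —
slower, noisier, more asymmetric, heel-loaded gait. Per-subject
log-normal sensor gains (sd 0.15) and pulse-width multipliers (sd 0.10),
shared between feet so bilateral symmetry stays governed by the
asymmetry gain alone, give subjects individual pressure signatures; they
are what keeps the 156 features from collapsing into a few perfectly
correlated blocks, as the correlation-pruning stage requires of
realistic data.

Label noise is injected into exactly round(ρ·n) training labels:
± a uniform integer magnitude (default 5–15 BBS points), clamped to
[0, 56]. An optional score-dependent mode draws the corrupted subjects
with probability ∝ (56 − BBS + 1) and scales magnitudes with
(56 − BBS)/56, emulating the lower reliability of low BBS scores; the
suite verifies that under this mode the screen preferentially flags
low-scored subjects.

What the generator does *not* emulate: pathology-specific gait patterns,
stance/swing sub-phase structure beyond the pulse windows, footwear or
calibration effects, and any nonstationarity within a recording. Passing
tests on this cohort therefore demonstrate the pipeline's mechanics and
its behaviour under controlled label noise, not clinical validity.

## Study-scale defaults and runtimes

The end-to-end configuration mirrors the cohort scale the method was
designed around: 131 training recordings, 29 test recordings, 60 s at
20 Hz each, ρ = 42/131 injected label noise. One pipeline run takes a few
seconds; the 20-seed replication used by the test suite takes about two
minutes. The smaller cohorts used in some unit tests (40 subjects, 30 s)
exercise identical code paths.

## Known limitations

* **Screening precision bounds the semi-supervised gain.** With an oracle
  anomaly mask, the screened semi-supervised pipeline beats naive full
  supervision on every seed tried (mean test RMSE roughly 1.5 vs 2.7 at
  study scale). The implemented screen, faithful to the
  median-threshold/12-set-consensus design, flags ~50 samples of which
  ~30–35 are truly corrupted; masking the clean remainder discards
  informative samples and largely cancels the benefit of removing the
  corrupted labels when the corruption is zero-mean and moderate
  (±5–15 points on a third of the cohort). Under those conditions the
  semi-supervised arm wins only a minority of seeded runs. The
  `replicate_experiment()` harness exposes exactly this comparison.
* **The consistency term is a weak, isotropic regularizer for a linear
  model.** Its expectation is a ridge penalty λu·σδ²‖w‖²; with collinear
  selected features it can shift predictions materially in poorly
  determined directions, helping on some cohorts and hurting on others.
  A nonlinear predictor could draw more from the unlabeled feature
  distribution; the loss machinery is written model-agnostically to
  allow that extension.
* Period detection assumes a quasi-stationary stride rate per recording;
  event-level timing (heel-strike instants) is out of scope at 20 Hz.
* The sensor map and coordinates are a documented reconstruction; COP
  features should be interpreted in relative, not anatomical, units.
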