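---
title: "Scoring mood-scale items from wristband physiology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring mood-scale items from wristband physiology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`wearmood` infers the full 28-item profile of the two standard
clinician-rated mood scales — HDRS-17 (depression, total 0–52) and YMRS
(mania, total 0–60) — from five wristband channels recorded at their
native Empatica-E4 rates (ACC 32 Hz ×3 axes, BVP 64 Hz, EDA 4 Hz, HR
1 Hz, TEMP 1 Hz; the inter-beat-interval stream is excluded because of
its long missing runs on wrist recordings). This vignette documents the
modelling choices, the tunable parameters, the synthetic test bed, and
the numerical conventions, so that a reader can judge what the package's
tests do and do not establish.

## The task and its structure

Every recording session carries one set of 28 clinician scores taken at
an interview; every τ-second window ("segment") cut from that session
inherits those scores. The learning problem is therefore multi-task
(28 ordinal targets sharing one input), ordinal (ranks are ordered, and
four YMRS items — Y5, Y6, Y8, Y9 — are double-weighted, printing ranks
0, 2, …, 8), heavily imbalanced (acute states are short-lived, so rank 0
dominates most items), and plagued by subject-level confounding: with
cohorts of dozens of subjects, a flexible model can score segments by
recognising *who* is wearing the device rather than *how unwell* they
are. The package's design addresses each of these in turn.

Internally all items live on a 0-based unit-step index scale; printed
rank values (steps of 2 for the double-weighted items) appear only at
I/O boundaries (`labels.csv`, prediction tables, totals).

## Preprocessing

**Quality control.** Wrist-worn EDA and TEMP are screened with published
plausibility rules — EDA outside [0.05, 60] µS, |dEDA/dt| > 10 µS/s,
TEMP outside [30, 40] °C, each violation dilated by ±5 s — plus a range
rule for the device's derived HR stream (25–250 bpm, no dilation). The
cited rule set is not printed in the primary literature on this task, so
the constants are fixed to the published values and kept configurable
(`qc_rules()`). Cross-channel alignment is done at a wall-time
resolution of 1 s (the coarsest native rate): an invalid second in any
channel invalidates that second in all channels. This is unambiguous
across heterogeneous rates and is the granularity at which discard
fractions are reported.

**Segmentation.** Half-open windows `[t, t + τ)` tile each region with
no overlap (so the model cannot exploit shared motifs across segments);
windows containing any invalid second are dropped whole rather than
gap-shifted, preserving the strict tiling. τ defaults to 16 s, the
window length that performs best for this task; the encoder handles any
τ divisible by the frame count `L`.

**Close/far partition.** The first 5 h after the interview ("close")
form the train/validation/test pool, split 70-15-15 at segment level
stratified by recording session. Segments from each subsequent 30-min
interval ("far") are reserved for drift evaluation: both the symptoms
and the physiology distribution move away from interview-time
conditions, making the far intervals a natural out-of-distribution test.
Whether the original study kept subjects disjoint across splits is not
derivable from its text, and the critic design implies training subjects
recur; the default split is therefore session-stratified, with a
subject-disjoint mode available (`make_splits(by = "subject")`).

**Resampling label.** For severity-bin resampling a single label per
segment is needed. The HDRS and YMRS totals are binned (defaults below)
and the pair is collapsed to its more severe non-remission component,
ties resolved towards HDRS; double remission maps to `"remission"`. The
collapse rule is the package's own reconstruction — only the existence
of a bin-derived label is documented in the literature.

**Severity bins.** The canonical bin tables are cited but not printed in
the source literature; the defaults are an editorial reconstruction
anchored at the two anchors that are printed (remission at total ≤ 7 for
both scales; YMRS [20–25] and HDRS [19–22] as tight named bands): HDRS
0–7 / 8–13 / 14–18 / 19–22 / 23+, YMRS 0–7 / 8–14 / 15–19 / 20–25 /
26+. The edges are configurable in `build_schemas()`.

## The classifier–critic model

The architecture follows the published module contract — encoder `EN`,
representation `RM`, 28 item predictors `IP_j`, subject critic `CR` —
whose internals are not public; the realization here is deliberately the
smallest family that satisfies the contract and trains on one CPU:

* `EN`: per modality, the raw window is cut into `L = 8` equal frames
  and each frame is linearly projected to `d = 8` features (this is a
  strided 1-D convolution whose stride equals its kernel), then ReLU.
  Every modality — tri-axial ACC enters as one modality with three
  features per time step — thus becomes an `L × d` block regardless of
  its native rate.
* `RM`: global average pooling over the `L` frames, concatenation of
  the five pooled blocks, and one dense ReLU layer to the shared
  representation `h` (`D = 32`).
* `IP_j`: one affine + softmax head per item with that item's number of
  ranks. Heads are independent given `h`.
* `CR`: a one-hidden-layer MLP (width 32) + softmax over the training
  subject inventory.

Inputs are standardized per modality by a single global mean/scale
computed on the training features and stored with the model. Weights
use He initialization; optimization is Adam (learning rate 0.01, batch
128) with all randomness (init, batch order, resampling) derived from
one seed, so training is exactly reproducible.

**Adversarial game.** The critic descends its subject cross-entropy on
`h`; the feature extractor receives the task gradient *minus* λ times
the critic gradient (gradient reversal), i.e. it ascends subject
confusion while descending the scoring loss. Two conventions had to be
fixed where the source is silent: (i) the reversal realization itself
(the standard one for "a critic penalty added to the main objective");
(ii) the multi-task aggregation. The package uses the **mean** of the 28
item losses rather than their sum: under Adam the two are nearly
equivalent for the task parameters (per-parameter step sizes are
scale-normalized), but the mean keeps λ = 0.07 weighed against a
single-loss-scale objective instead of being diluted 28-fold, which is
the only reading under which a "small" penalty of that magnitude can
influence the representation at all. The critic additionally takes
`critic_steps = 3` update steps per minibatch — a standard stabilization
that keeps the critic near its best response, sharpening the reversed
gradient.

**Losses.** Three per-item losses are available:

* `cce` — categorical cross-entropy with optional per-rank weights;
* `focal` — `−α_y (1 − p_y)^γ log p_y` with inverse-frequency α
  normalized to mean 1 and γ = 2 by default, focusing training on
  confidently wrong predictions of under-represented ranks;
* `qwk` (default) — a differentiable batch-level surrogate of
  `1 − quadratic Cohen's κ`: with `w_jk = (j − k)² / (K − 1)²`,
  `O_soft = Σ_n w_{y_n k} p_{n k}` and
  `E_soft = Σ_k (Σ_j w_jk h_j)(Σ_n p_nk) / N` where `h_j` counts true
  ranks in the batch; the loss is `O_soft / (E_soft + ε)`. On one-hot
  predictions this equals `1 − κ_quadratic` exactly (the test suite
  verifies this against a brute-force confusion-matrix oracle). Because
  κ is a batch-level quantity the loss is computed per minibatch; the
  default batch of 128 keeps the chance term `E_soft` stable. A batch
  whose true ranks are all identical would make `E_soft` collapse
  towards 0; the ε-guard (1e−10) keeps the value finite rather than NaN.

**Imbalance strategies** are an orthogonal configuration axis
(`imbalance`): `focal` (loss-side), `threshold` (inference-side
rescaling `p'_k ∝ p_k / (f_k + ε)` by training rank frequencies),
`resample-ros` / `resample-rus` (severity-bin resampling; each
segment's loss is re-weighted by `original/resampled` count of its bin
so every bin's expected total loss contribution is unchanged; for the
batch-level κ loss the weights enter `O_soft`, the rank counts and `N`).
Whether the best published configuration combined the κ loss with a
second imbalance device is not recoverable from the main text, which is
precisely why the axes are kept orthogonal here.

## Evaluation suite

* **QCK** `= 1 − Σ w O / Σ w E`, `w_jk = (j−k)²`, on the unit-step
  scale; values in [−1, 1]. When both raters are constant and identical
  the statistic is degenerate; it is defined as 1 with a warning — the
  alternative (undefined) would punch holes in drift curves whose
  far-interval segments are sometimes unanimous.
* **Macro F1** averages per-rank F1 over the ranks *present* in truth or
  prediction. Averaging over all schema ranks instead would let
  never-occurring ranks of wide items (0–8) drag the score by
  construction; the choice is documented because the source is silent.
* **Entropy correlation**: plain Pearson R between per-item QCK and
  per-item ℋ. Entropy uses the natural log; any base change is a
  positive rescaling, which Pearson R is invariant to, so the base is a
  pure convention.
* **Drift curves**: per-item QCK and per-scale item averages for each
  30-min far interval, in time order; empty intervals are recorded as
  missing, not zero.
* **Residual network**: signed errors (prediction − truth) on the
  unit-step scale, Pearson correlations, and a graphical lasso. No
  graphical-lasso implementation ships with the environment's R
  packages, so the estimator is implemented in the package: Friedman-style
  block coordinate descent (each column update an L1 regression),
  penalized diagonal, EBIC model selection with γ = 0.5 over a 20-point
  log-spaced penalty grid from the empty-graph penalty down to 1% of it
  — mirroring the defaults of the psychometric-network R ecosystem this
  analysis normally runs in; those exact supplementary settings are not
  in the main text, so they are flagged as reconstructions. Node
  predictability is `1 − 1/Θ_ii` (variables standardized), the R²-like
  share of a node's variance explained by its neighbours. Optional
  bootstrap (500 draws by default) reports edge-inclusion frequencies at
  the selected penalty. Unit tests check the estimator's KKT conditions
  and its λ→0 agreement with the analytic inverse.
* **Subject screens**: per-subject item-average macro F1, Pearson tests
  against continuous covariates, a two-sample t-test against sex,
  Bonferroni-corrected over the screens performed. Subjects with fewer
  than two segments are excluded with a warning.
* **Ablations**: leave-one-channel-out retraining with identical seed
  and configuration, reporting per-item ΔQCK against the all-channel
  baseline.

## The synthetic test bed

The clinical recordings behind this task are not public, so every
downstream stage is exercised on a generator with known ground truth
(`synth_config()`, `sample_cohort()`, `render_session()`).

Defaults encode study-like conditions: 75 subjects with ≈2 sessions
each, 48 h sessions, drift onset at 5 h. Subjects carry latent
depression/mania traits drawn from a right-skewed Beta(0.7, 2.2);
session states jitter around the trait (s.d. 0.12). Item scores come
from a graded-response-like discretizer: `z_j = latent + ε_j`
(ε Gaussian, s.d. 0.08) cut at thresholds evenly spaced over
[0.25, 0.95] in latent units — chosen so that rank 0 is the majority
rank for most items (matching the empirical skew of acute-care
cohorts) while a latent of 1 saturates the item. HDRS items load on the
depression latent, YMRS items on mania, and the two insight items
(H17, Y11) on `max(d, m)` since insight degrades at either pole.

Signals carry the statistical structure the pipeline exploits and no
more: ACC is zero-mean burst noise whose envelope rises with mania and
falls with depression; EDA is a subject baseline plus an anxiety-linked
tonic level (items H10/H11) plus capped phasic deflections; HR is a
baseline plus an activity load term; TEMP a slow sinusoid; BVP a
harmonic pulse at the instantaneous HR frequency (consistent with the
device's HR being PPG-derived). Values are clamped inside the QC
plausibility ranges so that artifact-free sessions never trip the rules
(QC specificity is a testable contract). After `drift_onset_h` the
activity envelope, EDA tonic and HR shift by `drift_mag` (default 0.4),
emulating the post-interview distribution drift. **Not** emulated:
realistic PPG morphology, validated actigraphy spectra, circadian
structure beyond the TEMP sinusoid, missing data. Passing tests
therefore demonstrate that the pipeline recovers planted, monotone,
physiologically arranged signal under realistic imbalance — not
clinical-grade performance on real patients.

**Confound mode** plants the shortcut the critic is designed to defeat:
for a configurable fraction of subjects (intended as the training
subjects) the EDA/HR baselines are made informative of the subject's
severity; for the remaining (held-out) subjects baselines are
independent. A model free to exploit baselines then fails on held-out
subjects, and the adversarial penalty — which punishes exactly the
subject-identifying features — should close part of that gap. The test
suite asserts the two directional consequences over five paired seeds:
held-out-subject QCK with λ = 0.07 is at least that with λ = 0 in the
median, and the critic's own hold-out accuracy is lower.

**Artifact injection** replaces a configurable fraction of samples with
implausible values (EDA outside range, abrupt EDA jumps, TEMP and HR
outside range) and returns the exact mask, giving QC a ground truth for
recall/specificity tests.

## Problem sizes and numerical conventions

Test and example cohorts are deliberately desk-scale: minutes-long
sessions, 6–20 subjects, ≤ 10 epochs — enough for the planted signal to
be recovered well above a session-permutation null (the suite requires
the held-out item-average QCK to beat the null's 95th percentile, and in
practice it clears 0.3), while the whole suite runs in a few minutes on
one CPU. The drift property uses 6.5 h sessions so that three 30-min far
intervals exist; the glasso recovery test plants a two-block sparse
precision matrix over the 28 items (n = 5000) and requires edge-set
F1 ≥ 0.8.

Numerical defaults: ε = 1e−8 for probability thresholding, 1e−10 for
log clamps and the `E_soft` guard; probabilities validated to sum to 1
within 1e−6; glasso convergence at 1e−5 relative to the mean
off-diagonal; argmax ties broken towards the lower rank. Master seeds
fan out to stage/session seeds via a stable 31-bit polynomial string
hash, so cohorts are byte-reproducible and stages are independently
seeded.

## Known limitations

* The architecture is the minimal contract-satisfying family; no claim
  is made that it matches the (non-public) original internals, and its
  capacity is sized for the synthetic test bed.
* The adversarial benefit is real but small at λ = 0.07, consistent
  with a "small penalty"; on the synthetic confound it shows up as a
  median, not a per-seed, improvement.
* The generator's signal-to-label pathways are monotone and low-rank;
  real symptom–physiology coupling is noisier, subject-specific and
  time-varying, so synthetic QCK values should not be compared with
  clinical ones.
* Severity-bin edges, the Kleckner rule constants, the resampling-label
  collapse and the glasso settings are documented reconstructions where
  the primary sources do not print the values; all are configurable.
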