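---
title: "Methods: decoding assistive-chair control from sit-to-stand muscle activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding assistive-chair control from sit-to-stand muscle activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A two-degree-of-freedom assistive chair supports sit-to-stand (STS) motion
by moving its seat forward and upward during the rising phase. The seat
motion is commanded by four binary control variables: forward and upward
speed (fast, 0.22 m/s, vs slow, 0.08 m/s) and forward and upward onset
timing (immediate vs a 0.3 s wait after the torso starts tilting), giving
2^4 = 16 control conditions. Because the chair perturbs whole-body
dynamics, different commands leave different signatures in the activity of
the leg and trunk muscles.

This package implements the offline analysis that exploits those
signatures in the inverse direction: given a *target* muscle-activity
pattern, which chair command would best induce it? The approach is
statistical. Four L1-regularized (lasso) logistic classifiers are trained
to predict each control bit from a 100-dimensional muscle-activity feature
vector; running them on a target feature vector yields a candidate
command, and the mean training feature vector of trials recorded under
that command (its *prototype*, the classifier-inferred muscle activity) is
compared against the target in feature space.

## Processing chain

1. **Activation envelopes** (`emg_to_activation`). Raw EMG (mV) is
   band-pass filtered 40–400 Hz, full-wave rectified, low-pass filtered at
   4 Hz, all with fourth-order Butterworth filters, and clipped at zero.
   Filtering is zero-phase (forward–backward, odd-reflection padding):
   cutoffs and order leave phase handling open, and zero-phase is chosen
   because a causal 4 Hz fourth-order low-pass delays envelopes by ~100 ms, enough
   to smear activity across the phase boundaries that the features are
   aligned to. A consequence is that each pass squares the magnitude
   response, so the effective band edges are slightly narrower than the
   nominal cutoffs (a 100 Hz test tone recovers a mean envelope of 0.631
   rather than the ideal 2/pi = 0.637).

2. **Phase segmentation** (`segment_phases`). The STS interval is the
   period during which trunk tilt exceeds 10 degrees above the seated
   baseline (mean tilt over the first 0.5 s); crossing times are linearly
   interpolated, and if several disjoint supra-threshold episodes exist
   the longest wins (robust to pre-motion fidgeting). Seat-off is the
   first time inside that interval at which the seat reaction force drops
   below 5% of its pre-onset mean. Five boundaries define four phases:
   onset, peak forward tilt, seat-off, tilt half-decay (tilt falling below
   threshold + 0.5 x (peak − threshold)), and completion. Onset, seat-off
   and completion are threshold-defined; the two intermediate landmarks
   have no standard numeric definition, so this package uses
   deterministic, kinematics-only landmarks consistent with conventional
   four-phase STS descriptions (forward lean, ascent around seat-off,
   extension, stabilization). Degenerate geometries are clamped:
   a tilt peak at or after seat-off moves t1 to the midpoint of (t0, t2),
   and a missing half-decay crossing moves t3 to the midpoint of (t2, t4).
   Phases are half-open intervals `[t_k, t_{k+1})` so every sample belongs
   to exactly one phase.

3. **Features** (`extract_features`). Per phase: its duration (s), plus
   the mean, standard deviation and peak-to-peak amplitude (mV) of each
   muscle's envelope — 1 + 3 x 8 = 25 features per phase, 100 per trial,
   ordered durations-first then muscle-major. The standard deviation is
   the sample (n−1) statistic. Features are standardized to zero mean and unit variance
   using statistics fitted on the training split only, so no test
   information leaks into the scaling; zero-variance features map to
   constant zero with a warning rather than dividing by zero.

4. **Classification** (`run_sts_analysis`). One lasso-logistic model per
   control variable, fitted per participant (muscle-activity scales and
   geometries differ between individuals; performance is then reported as
   mean ± sd across participants). The
   objective is the total negative log-likelihood plus λ Σ|β_j| with an
   unpenalized intercept, solved by `glmnet` (λ is converted to glmnet's
   per-observation scale). λ is a free parameter, selected by
   stratified 5-fold cross-validation maximizing the mean
   held-out F-score over the grid `10^seq(-1, 1.3, length 8)` (total-loss
   scale), with ties broken towards the larger λ — the sparser model.
   Probabilities at exactly 0.5 classify as fast (1), an explicit tie
   rule. Precision, recall and F treat fast as the positive class.

5. **Separability** (`separability`). For each feature a fitted model
   actually selected (nonzero coefficient), the class-separability
   η = σ_B²/σ_W² is computed on the training split, with
   σ_W² = (σ_0² + σ_1²)/2 and σ_B² = ((μ_0 − μ)² + (μ_1 − μ)²)/2, using
   sample (n−1) variances (which make the closed-form test cases exact).
   η < 1 means
   within-class spread dominates.

6. **Inverse evaluation** (`evaluate_inverse`). Prototypes are the
   per-condition means of the standardized training vectors, built per
   participant (consistent with per-participant classifiers; pooling
   across participants would mix inter-individual offsets into every
   prototype). For each test trial, the four classifiers infer a
   condition; the Euclidean distances from the trial's feature vector to
   all 16 prototypes are normalized by their sum, giving S_INF (the
   inferred condition's normalized distance) and S_NT (the mean of the 15
   non-target normalized distances). By construction the 16 normalized
   distances sum to one, so S_INF + 15 · S_NT = 1 per trial and an
   uninformative inference sits at 1/16 = 0.0625. Distances are taken in
   standardized feature space so that heterogeneous feature types
   contribute on a comparable scale. Pooled S_INF and S_NT samples are
   compared with a two-sided Wilcoxon rank-sum test (exact p for small
   tie-free samples, normal approximation with tie and continuity
   correction otherwise; the z statistic is always reported from the
   normal approximation).

## The synthetic study

Suitable public recordings of chair-assisted STS with commanded control
conditions are not available, so a first-class generator
(`generate_trial`, `simulate_manifest`) emulates the statistical
structure of such a study: 6 participants x 16 conditions x 10 trials,
EMG at 2000 Hz and kinematics at 100 Hz (conventional surface-EMG
practice).

Each trial is built from a latent geometry: trunk tilt rises along a
raised-cosine to a peak (38 ± 2.5 deg between participants, ± 1.5 deg
between trials) and falls back, which fixes the five ground-truth
boundaries analytically; seat-off sits at 40% of the way from peak tilt to
the half-decay landmark, and the seat force (baseline = body weight, drawn
from 75.0 ± 12.2 kg) decays sigmoidally through exactly 5% of baseline at
seat-off. Each muscle's envelope is a sum of four Gaussian bursts, one per
phase, with per-muscle per-phase baseline amplitudes following the usual
STS recruitment sequence (TA/ES lead, knee extensors dominate around
seat-off, SO late). Raw EMG is a 40–400 Hz Gaussian carrier, normalized to
unit mean rectified amplitude, multiplied by the envelope — so the
preprocessing chain approximately recovers the envelope (r > 0.95), making
the whole chain testable end-to-end.

Condition effects follow the intended physiological structure: **speed**
variables act multiplicatively on burst amplitudes, concentrated on
TA/SO/VM/RF (fast assistance unloads the agonists — factors 0.72–0.95 —
and raises SO, 1.22–1.25, for stabilization against the imposed inertia);
**timing** variables act mainly on phase durations (immediate onset
shortens the assisted phase by 0.12–0.15 s, against trial-to-trial
duration noise of 0.10–0.12 s) with only weak amplitude factors
(0.95–0.97). Amplitude noise is lognormal and mean-one: CV 0.15 per burst,
0.08 per trial, 0.15 per participant-muscle. These defaults are the study
conditions of every full-scale test and of `scripts/acceptance.R`; they
were fixed from the qualitative structure above, and they deliberately
make timing harder to decode than speed — the amplitude-dominated feature
set carries only indirect information about *when* assistance begins.

Seeding is hierarchical and fully deterministic: the config seed derives
per-participant seeds (latent gains, body mass), per-participant condition
order, and per-trial seeds recorded in the manifest, so any single trial
can be regenerated in isolation and identical seeds reproduce datasets
bit-for-bit.

**What the generator does not emulate:** real EMG nonstationarity,
electrode artifacts, crosstalk between channels, within-trial co-variation
of muscles beyond the shared trial gain, inter-muscle timing shifts,
fatigue across the session, and any biomechanical coupling between tilt,
force and muscle activity beyond the shared phase clock. Passing tests
therefore demonstrate that the pipeline recovers the structure it assumes,
not that real recordings contain that structure.

## Problem sizes and run times

The full-scale checks (acceptance tests and `scripts/acceptance.R`) use
the default study — 960 trials, ~2–3 minutes on one core, dominated by
per-trial filtering; trials are streamed one at a time
(`extract_dataset_features`) so memory stays flat. Unit tests use one
participant at 4 trials per condition (64 trials) or single trials.
Envelope-only generation (`include_emg = FALSE`) skips carrier synthesis
and is used where only kinematics or ground-truth envelopes matter.

## Worked example

```{r example}
library(stschair)

res <- run_sts_pipeline(generator_config(n_participants = 1,
                                         trials_per_condition = 4,
                                         seed = 3))
print(res)
```

At this deliberately small scale (64 trials, 16 test targets) the
qualitative results already appear: speed variables decode better than
timing variables and S_INF sits significantly below S_NT; the
selected-feature η ordering between speed and timing stabilizes only at
the full 6-participant scale, where each model's cross-validated penalty
is estimated from 112 training trials.

## Known limitations

* The generator's effect structure is multiplicative and phase-locked; it
  cannot express waveform-shape changes within a phase, so waveform-level
  claims are outside the test surface.
* η is undefined (reported as `Inf` with a warning) for features with zero
  within-class variance, and such features are excluded from η summaries.
* With per-participant prototypes, a condition absent from a participant's
  training split would make the 16-way normalization impossible; the
  stratified split guarantees every condition appears, and
  `build_prototypes`/`similarity` refuse (rather than impute) if that
  guarantee is broken.
* The rank-sum comparison pools test trials across participants into a
  single statistic; within-participant dependence between trials is
  ignored.
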