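# stschair

Offline analysis linking surface-EMG muscle activity during sit-to-stand
(STS) motion to the four binary control variables of a two-degree-of-freedom
assistive chair — and evaluating, in the inverse direction, whether the
control condition inferred from a target muscle-activity pattern selects a
muscle-activity prototype closer to that target than all 15 non-target
conditions.

**Who it is for:** researchers in rehabilitation biomechanics and
myoelectric interfacing who want a reproducible, fully tested reference
implementation of this decoding-and-inversion protocol, runnable end-to-end
on synthetic data with the study's statistical structure.

## The method

A chair command is four bits `y = (fwd_speed, up_speed, fwd_timing,
up_timing)`, each fast (1) or slow (0), giving 16 conditions. Each STS trial
is reduced to a feature vector `x ∈ R^100`: the trial is segmented into four
phases from trunk tilt (10° onset/completion threshold, peak, half-decay)
and seat reaction force (seat-off at 5% of seated baseline), and each phase
contributes its duration plus the mean, SD and peak-to-peak amplitude of
each of 8 muscle-activation envelopes (40–400 Hz band-pass, rectification,
4 Hz low-pass; 4th-order zero-phase Butterworth). Features are standardized
on the training split.

Per control variable *i*, a lasso-logistic model

    P(y_i = 1 | x) = 1 / (1 + exp(-(β0 + xᵀβ))),
    (β0, β) = argmin  NLL(β0, β) + λ Σ_j |β_j|

is fitted per participant (`glmnet` backend, λ by stratified 5-fold CV on
F-score, ties to the sparser model). Class separability of each selected
feature is scored as η = σ_B²/σ_W². For the inverse evaluation, each test
trial is a target: the four classifiers infer a condition, and the
Euclidean distances from the target to all 16 per-condition prototype
vectors (means of standardized training trials) are normalized to sum to
one. `S_INF` is the inferred condition's normalized distance, `S_NT` the
mean of the 15 others (so `S_INF + 15·S_NT = 1`, chance level 1/16 =
0.0625); pooled populations are compared with a Wilcoxon rank-sum test.

Because suitable public recordings of chair-assisted STS with commanded
control conditions are not available, the package ships a first-class
synthetic-trial generator (6 participants × 16 conditions × 10 trials by
default) whose condition effects follow the intended physiological
structure: speed bits modulate burst amplitudes of TA/SO/VM/RF,
timing bits mainly shift phase durations. See
`vignettes/sts-chair-methods.Rmd` for the model, all defaults, and what the
generator does and does not emulate.

## Worked example

```r
library(stschair)
res <- run_sts_pipeline(generator_config(n_participants = 1,
                                         trials_per_condition = 4,
                                         seed = 3))
print(res)
#> <sts_pipeline_result> 64 trials, seed 3
#>   F-scores: fwd_speed 0.89  up_speed 0.88  fwd_timing 0.71  up_timing 0.71
#>   selected-feature eta: speed 0.21, timing 0.46
#>   S_INF 0.052 +/- 0.010 vs S_NT 0.063 +/- 0.001 (|z| = 3.52, p = 0.00019)
#>   boundary recovery 100.0%; pooled STS RMS 0.111 mV
```

Reading: on this small single-participant dataset the speed bits are
decoded from the test split with F ≈ 0.89 while the harder timing bits
reach F ≈ 0.71; every phase boundary was recovered within 2 kinematic
samples of the generator's ground truth; and the inferred conditions'
prototypes sit significantly closer to their targets (S_INF ≈ 0.052) than
the non-target baseline (S_NT ≈ 0.063, chance 0.0625). At the full default
scale the separability ordering (speed η > timing η) emerges as well.

## The analysis workflow

Numbered drivers under `analysis/` run the full default study and write
tables under `results/`:

| step | what it does | main outputs |
|---|---|---|
| `01_simulate.R` | plan the 960-trial study; export demo trials as CSV | `results/manifest.csv`, `results/data/` |
| `02_features.R` | envelopes → segmentation → 100 features (streamed) | `results/features.csv`, `results/segmentation_qc.csv` |
| `03_classify.R` | per-participant lasso classifiers, metrics, η, coefficients | `results/metrics_*.csv`, `results/coefficient_matrix.csv`, `results/separability.csv`, `results/models/*.json` |
| `04_inverse.R` | condition inference and S_INF vs S_NT evaluation | `results/similarity.csv`, `results/inverse_summary.csv` |

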