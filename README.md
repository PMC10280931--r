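# jaeknee

Joint acoustic emission (JAE) analysis for knee arthritis screening.

Knees make sounds. During flexion-extension, the articulating surfaces of
the knee emit broadband vibrations that can be recorded on the skin with
miniature accelerometers (vibroarthrography). In juvenile idiopathic
arthritis (JIA) the joint surfaces and synovium change, and with them the
acoustic emissions — making JAEs a candidate non-invasive digital
biomarker for screening and monitoring affected knees.

`jaeknee` implements the complete analysis chain from raw two-channel
accelerometer waveforms to a per-knee **joint score** in [0, 1]
(interpretable as the probability of JIA involvement):

1. **Synthetic cohort generator** — damped-sinusoid click trains with
   Poisson counts per flexion-extension cycle, wrapped-normal click
   timing, log-normal subject- and leg-level random effects, a
   controllable class effect size, and the sensor noise floor
   (0.0007 g-rms). Emulates the acquisition protocol: 10 cycles at one
   per 4 s, two channels per knee, up to 100 kHz sampling.
2. **Preprocessing** — wavelet shrinkage denoising (periodized db4, soft
   universal threshold σ̂√(2 ln N)), zero-phase Butterworth band-pass
   (100 Hz–12 kHz), fixed-grid cycle segmentation, 200-ms frames with
   50% overlap (39 frames per channel per cycle).
3. **Features** — a versioned 273-entry frame-level catalogue
   (time-domain statistics, spectral shape, log-spaced band energies,
   MFCCs with deltas, wavelet-packet energies), aggregated per knee as
   the mean and population SD of each feature over all pooled frames.
4. **Model** — standardization → PCA (smallest k reaching 95% cumulative
   variance, capped at 60 components) → XGBoost logistic booster, fitted
   as one unit; leave-one-leg-out cross-validation (LOLO-CV) refits the
   entire pipeline inside every fold.
5. **Evaluation** — confusion matrices, accuracy / sensitivity /
   specificity, ROC/AUC (trapezoidal = normalized Mann-Whitney), and a
   two-sample Kolmogorov-Smirnov comparison of active vs inactive
   joint-score distributions.

The study split is built in: training = all clinically *active* JIA knees
plus 80% of control subjects (both knees together); testing = all
*inactive* JIA knees plus the remaining controls.

## Worked example

```r
library(jaeknee)

cfg <- run_config(
  sim  = sim_config(n_jia_subjects = 20L, n_control_subjects = 10L,
                    fraction_active_knees = 43/172,
                    fs = 25000, n_cycles = 3L, effect_size = 2, seed = 1L),
  seed = 1L)
run <- jae_run(cfg)
print(run)
```

```
End-to-end run (config 1caf7546, seed 1)
JAE classification report
  training (LOLO-CV): accuracy 1.000, sensitivity 1.000, specificity 1.000, AUC 1.000
  test set: accuracy 0.324, sensitivity 0.233, specificity 1.000
  active scores: n = 10, median 0.874
  healthy scores: n = 20, median 0.072
  inactive scores: n = 30, median 0.120
  KS active vs inactive: D = 0.767, p = 0.000296
```

Reading the output: the 60-knee synthetic cohort (20 JIA subjects, 10
controls, 10 active knees) is featurized and split; LOLO-CV on the
26-knee training set (10 active + 16 control knees) separates active
from healthy knees perfectly at this effect size (AUC 1.0); the model
fitted on the full training set then scores the 34 test knees
(30 inactive + 4 control). Healthy knees score near 0 and active knees
near 1. Inactive knees are simulated, by default, at exactly half the
active shift on the log scale — the midpoint between the two training
classes — so their test-set calls depend on where the classifier places
its boundary inside the empty margin between clusters and hover around
chance (compare seeds: median inactive score 0.12 at seed 1, 0.48 at
seed 7), while the KS test still cleanly distinguishes the active from
the inactive score distribution. Individual stages are available as plain
functions (`simulate_cohort()`, `preprocess_recording()`,
`extract_features()`, `fit_pipeline()`, `lolo_cv()`, `roc_curve()`,
`ks_two_sample()`, ...), and `fit_pipeline()` returns a classed model
with `print()`, `summary()` and `predict()` methods.

A thin CLI over the same functions lives at `inst/cli/jae.R`
(`simulate | featurize | train | crossval | evaluate | run-all`, each
with `--config <yaml>` and `--out <dir>`).

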