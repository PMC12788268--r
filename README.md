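# jugglekit

Tools for decomposing early three-ball cascade juggling skill into three
measurable components and modelling how they jointly determine day-level
performance:

- **Sequencing (S)** — how well the three balls hold the ideal 120°
  phase relationship of the cascade. Each ball's smoothed, mean-subtracted
  vertical position ỹ_b(t) is converted to an instantaneous phase via the
  analytic signal, φ_b(t) = arg(ỹ_b(t) + i·H{ỹ_b(t)}), and windows spanning
  three consecutive apexes from three distinct balls are scored

      S_w = (1/K) Σ_k [ 1 − (δ12 + δ13 + δ23) / (3·180°) ],

  where δ_ij is the circular deviation of the pairwise phase difference
  from the ideal 120° offset. The day index S is the mean of all pooled
  window scores; days with too few valid windows (below the
  exp(mean log N − 3 sd log N) count threshold) are excluded.
- **Prediction (P)** — the fraction of valid two-ball visual-occlusion
  trials on which both hands complete the second catch,
  P = N_succ / N_valid, probing state estimation of the ball while the
  shutter glasses are closed for 0.5 s from the ball's apex.
- **Accuracy (A)** — the geometric mean over hands and blocks of the 95%
  probability-ellipsoid volume of hand-centred second-catch positions,
  V = (4/3)·π·c^{3/2}·√det(Σ̂) with c = χ²₃(0.95) ≈ 7.8147; smaller is
  tighter, i.e. more accurate.

Day-level performance (Perf, the mean successful-catch count over a day's
ten best trials) is then modelled with a self-implemented Gamma GLM with a
log link,

    Perf ~ Gamma(μ, φ),  log μ = β0 + βP·Z_P + βA·Z_A + βS·Z_S,

on logit-, negative-log- and robust-z-transformed indices, against a
Normal-Identity reference model, with Wald inference, likelihood-based fit
metrics (log-likelihood, AIC, Cox–Snell pseudo-R²), day-wise metrics, and
leave-one-subject-out cross-validation (LOSO-CV).

Because the motivating study's recordings are not public, the package
includes a first-class synthetic-data generator: ballistic three-ball
cascade kinematics with per-throw phase jitter and trial-ending drops,
frame-wise detection tables with dropout/false positives, occlusion
sessions with apex-locked shutter scheduling, and a Gamma generative twin
of the performance model — all with full ground truth, so every pipeline
stage is testable end to end. It is aimed at motor-learning researchers
who want a tested reference implementation of phase-based coordination
scoring, occlusion-based prediction/accuracy indices, and positive-outcome
GLM evaluation.

## Worked example

The `analysis/` scripts run the whole study as a sequence of stages
(simulate → indices → models → sensitivity), writing tables under
`results/`:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_compute_indices.R
Rscript analysis/03_fit_models.R
Rscript analysis/04_sensitivity.R
```

Stage 2 reconstructs ball tracks from the corrupted detection tables and
prints, for the default 20-participant synthetic study:

```
Computed indices for 60 participant-days.
Sequencing windows per day: median 22 (range 0-88).
Window-count exclusion rule removed 3 day(s).
57 complete participant-days enter the modelling stage.
```

Stage 3 fits both models on the standardized indices:

```
== gamma_log ==
        term  beta     se     z         p  ci_lo ci_hi exp_beta
 (Intercept) 1.747 0.0534 32.74 4.71e-235 1.6425 1.852     5.74
         Z_P 0.230 0.0878  2.62  8.80e-03 0.0579 0.402     1.26
         Z_A 0.188 0.0716  2.63  8.51e-03 0.0481 0.329     1.21
         Z_S 0.360 0.0713  5.06  4.23e-07 0.2208 0.500     1.43
logLik -121.46 | AIC 250.92 | Cox-Snell 0.758 | R2 0.662 | RMSE 3.04 | LOSO R2 0.601
```

Read: with the synthetic study's generating structure (sequencing
contributing most to performance), a one-robust-SD increase in Sequencing
multiplies expected performance by exp(0.360) ≈ 1.43, and the Gamma-Log
model beats the Normal-Identity reference on every criterion
(AIC 250.9 vs 301.1, LOSO R² 0.601 vs 0.565), the same qualitative pattern
the method is designed to expose. Numbers vary with the study seed in
`results/study_config.yaml`.

The same machinery is available programmatically:

```r
library(jugglekit)
report <- run_pipeline(study_config(seed = 1))
report$models$gamma_log$coefficients
```

## Layout

- `R/` — package code: synthetic generators (`synth-*.R`), tracking and
  event labelling (`tracking.R`), phase/sequencing scoring
  (`sequencing.R`), occlusion indices (`occlusion.R`), index transforms
  (`transforms.R`), the GLMs (`glm-*.R`) and orchestration (`pipeline.R`).
- `analysis/` — numbered narrative drivers over the package functions.
- `vignettes/skill-decomposition.Rmd` — the methods vignette: model
  assumptions, parameter choices, and what the synthetic study does and
  does not show.
- `tests/testthat/` — unit, property and end-to-end tests.
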