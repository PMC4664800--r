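# apneaface

Craniofacial and acoustic estimation of obstructive sleep apnea (OSA)
severity.

OSA is diagnosed by overnight polysomnography, which produces the
Apnea-Hypopnea Index (AHI): apnea + hypopnea episodes per hour of sleep
(AHI < 10 conventionally non-OSA, ≥ 30 severe). Because polysomnography
is expensive and waiting lists are long, cheap proxies computed from a
frontal/profile photograph and a short speech recording are attractive
for triage. `apneaface` implements such a pipeline end to end, for
methodologists who want every stage explicit, tested, and reproducible:

- **Craniofacial module** — three uncalibrated measurements from facial
  landmarks (pixel coordinates, no metric calibration):
  - *cervicomental contour area*: the area enclosed by the chin–neck
    contour (profile points 11, 12, 20–23) against the rectangle spanned
    by points 23 and 11, normalized by that rectangle's area; 0.5 for a
    straight diagonal contour, smaller as anterior-neck fat bulges the
    contour;
  - *face width ratio*: midface width / interocular width (Euclidean
    distances between role-mapped frontal landmarks);
  - *tragion-ramus-stomion angle*: the angle at the ramus between rays to
    the stomion and the tragion, a mandibular-retraction proxy, via
    `atan2(|v1 × v2|, v1 · v2)`.
- **Acoustic module** — MFCC+Δ features (20 + 20 dims), diagonal GMM-UBM
  trained by EM, Baum-Welch statistics, MAP-adapted supervectors, and a
  total-variability factor model `m = μ + T w`; the i-vector of an
  utterance is the exact posterior mean
  `w = (I + TᵗΣ⁻¹NT)⁻¹ TᵗΣ⁻¹F`.
- **Regression module** — ε-SVR (linear kernel) estimating AHI under
  leave-one-out cross-validation with an inner 5-fold grid search over
  (C, ε) scored by MAE; metrics are MAE, Pearson CC, and OSA
  classification (accuracy / sensitivity / specificity / rank-statistic
  ROC AUC) at the AHI = 10 boundary applied to the estimated AHI.
- **Synthetic cohort generator** — clinical marginals matching the
  285-male clinical population the method targets, landmark sets with
  planted measurement–AHI correlations, and speech feature streams drawn
  from a GMM whose means are shifted along a known low-rank subspace by a
  latent correlated with AHI. It also knows its own noise-free regression
  ceiling, so the pipeline's recovery can be judged against the best
  achievable.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()` / `glance()` methods and `autoplot()` plots.

## A worked example

```r
library(apneaface)

config <- cohort_config(n_subjects = 120, seed = 20,
                        acoustic_params = list(n_components = 16L,
                                               feature_dim = 12L,
                                               true_rank = 3L,
                                               frames_per_utterance = 200L,
                                               latent_ahi_correlation = 0.2))
report <- run_pipeline(config,
                       sources = c("clinical", "craniofacial",
                                   "craniofacial+clinical"),
                       grid = svr_grid(C_values = c(0.5, 4),
                                       epsilon_values = c(0.25, 1)),
                       seed = 1)
report
#> <pipeline_report> 120 subjects, seed 1
#>                 source   n  mae    cc accuracy sensitivity specificity   auc
#>               clinical 120 8.78 0.672    0.833        0.98      0.1429 0.839
#>           craniofacial 120 9.80 0.598    0.800        0.96      0.0476 0.683
#>  craniofacial+clinical 120 7.36 0.779    0.842        0.96      0.2857 0.827
```

Reading the numbers: each row is one leave-one-out experiment over the
120 synthetic subjects. `mae` is the mean absolute error of the
estimated AHI in events/hour, `cc` the Pearson correlation between true
and estimated AHI, and the remaining columns classify OSA (true AHI ≥ 10
vs estimated AHI ≥ 10). Combining craniofacial measurements with
clinical variables (age, BMI, cervical perimeter) beats either source
alone — the qualitative signature this methodology predicts. Specificity
is low at this cohort size because few synthetic subjects fall below
AHI 10 (the class boundary sits deep in the lower tail of the configured
AHI marginal).

Per-subject predictions and a truth-vs-prediction plot:

```r
tidy(report$evaluations[["craniofacial+clinical"]])
autoplot(report$evaluations[["craniofacial+clinical"]])
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "apneaface", package = "apneaface")` with
subcommands `synth`, `facial-features`, `train-ubm`, `train-tv`,
`ivectors`, `evaluate`, `full-run`.

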