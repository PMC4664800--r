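---
title: "Estimating sleep apnea severity from craniofacial landmarks and speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sleep apnea severity from craniofacial landmarks and speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Obstructive sleep apnea (OSA) is diagnosed by overnight polysomnography,
which yields the Apnea-Hypopnea Index (AHI): the average number of apnea
and hypopnea episodes per hour of sleep.  An AHI below 10 is conventionally
read as non-OSA, 10–30 as mild-to-moderate, and above 30 as severe.
Polysomnography is costly and waiting lists are long, so cheap,
non-invasive proxies are valuable for triage: craniofacial morphology
(neck fat deposition, mandibular retraction, facial widths) and speech
(the upper airway is also the vocal tract) both carry information about
the anatomy that predisposes to airway collapse.

`apneaface` implements a complete, testable version of such a pipeline:

1. three **uncalibrated craniofacial measurements** computed from facial
   landmarks on frontal and profile photographs,
2. an **i-vector acoustic front-end** (MFCC features, GMM universal
   background model, Baum-Welch statistics, MAP-adapted supervectors, and
   a total-variability factor model),
3. **support-vector regression** of AHI under a leave-one-out protocol
   with an inner 5-fold hyperparameter grid search, plus OSA
   classification at the AHI = 10 boundary, and
4. a **synthetic cohort generator** that reproduces the statistical
   structure the analysis assumes, so every downstream stage can be
   exercised and audited without access to clinical data.

## The craniofacial measurements

All three measurements are ratios or angles, computable from pixel
coordinates without metric calibration.  Coordinates follow the image
convention: origin top-left, y increasing downward, 640x480 frames.

**Cervicomental contour area.**  Six profile landmarks (points 11, 12,
20–23 in the profile numbering) trace the chin–neck outline.  An
axis-aligned rectangle is spanned by point 23 (bottom-left) and point 11
(upper-right).  The closed polygon formed by the contour, the rectangle's
low side, and its right side is measured by the shoelace formula and
normalized by the rectangle area.  A straight-diagonal contour gives
exactly 0.5; the value decreases monotonically as the contour bulges
toward the bottom-right corner, i.e. as anterior-neck fat increases.
Because the rectangle is axis-aligned, this measurement assumes an
upright head: it is invariant to translation and uniform scaling but
deliberately *not* to image rotation.  That is a real limitation for
carelessly captured photographs, and the similarity-invariance tests
treat it accordingly (rotation invariance is asserted only for the other
two measurements).

**Face width ratio.**  Midface width divided by interocular width, both
as Euclidean distances between role-mapped frontal landmarks.  Using
Euclidean rather than horizontal distances makes the ratio robust to
small head tilt, and a ratio of distances is invariant to translation,
rotation and scaling.  The exact frontal indices carrying these roles are
not fixed by any published numbering, so they live in a configurable
index map (`landmark_index_map()`) with documented defaults tied to the
package's schematic templates.

**Tragion-ramus-stomion angle.**  The angle at the ramus (posterior
mandible) between rays toward the stomion (lip midpoint) and the tragion
(upper ear), a proxy for mandibular retraction.  The contract is the
arccosine of the normalized dot product; the implementation uses the
numerically stable two-argument arctangent of cross and dot products,
which agrees with the arccos form to far better than the 1e-9 degrees the
tests demand and does not lose precision near collinear configurations.

One reading ambiguity is worth recording: the cervicomental polygon is
closed through the explicit bottom-right corner vertex, which is the only
reading under which both the "right" and "low" sides of the rectangle
participate in the boundary.  Under it the two anchor cases come out
exactly: diagonal contour 0.5, corner-path contour 1.0.

## The acoustic representation

Speech is represented frame-by-frame by 20 MFCCs (c0 replaced by
log-energy) plus first-order deltas over a +-2-frame regression window:
40 dimensions at a 100 Hz frame rate (25 ms windows, 10 ms hop, 26 mel
filters).  The exact recipe (order, window, energy handling) is a
package default, declared rather than inherited from any reference;
recordings are expected as 16-bit PCM mono WAV, resampled to 16 kHz on
load.

Utterances of different lengths are mapped to fixed-length vectors by the
total-variability model over a diagonal-covariance GMM-UBM: the adapted
mean supervector of an utterance is modeled as `m = mu + T w` with `w`
standard normal and `T` a tall low-rank matrix.  The i-vector of an
utterance is the posterior mean of `w` given its Baum-Welch statistics,

```
w = (I + T' Sigma^-1 N T)^-1  T' Sigma^-1 F,
```

with `N` the component occupancies and `F` the centered first-order
statistics.  `T` is trained by EM on a collection of statistics; the
package monitors the marginal log-likelihood (up to terms constant in
`T`) and the tests assert it never decreases.  Supervectors via mean-only
MAP adaptation (relevance factor 16) are provided for completeness.

Numerical choices: variance flooring at 1e-3 of the global per-dimension
variance prevents component collapse on small data; UBM EM starts from a
seeded k-means partition; `T` starts from seeded Gaussian noise with
standard deviation 0.1; no minimum-divergence re-estimation step is
applied.  The default scale — 64 components, 40 dimensions, ranks up to
50 — is a desk-scale working point chosen so the full pipeline trains in
seconds to minutes on one CPU; production speaker-characterization
systems use 512–2048 components and development corpora of hundreds of
speakers, and the configuration accepts such values unchanged.

## The regression protocol

AHI is estimated by epsilon-SVR with a linear kernel (an RBF option
exists behind a flag, but linear is the primary contract).  The optimizer
is delegated to libsvm via `e1071`; everything around it — nesting,
standardization, selection, metrics — is implemented and tested here.

The evaluation protocol is leave-one-out: for each subject, the remaining
n − 1 form the training set; feature standardization (z-scoring) is
fitted on those n − 1 only; an exhaustive grid search over (C, epsilon)
is scored by 5-fold cross-validated MAE *within* the training set; the
SVR is refitted with the winning pair and predicts the held-out subject.
Ties in the grid break toward smaller C, then smaller epsilon —
deterministic and regularization-preferring.  The default grid is C in
2^-5..2^9 and epsilon in 2^-6..2^0 (steps of 2^2), a standard
power-of-two layout; the underlying study names the search procedure but
not its grid, so this is a package default, and several tests and the
acceptance runs use smaller grids to keep wall-clock time proportionate.
Whether to standardize features at all is likewise undocumented in the
source study; the package standardizes inside every training fold because
it mixes features on wildly different scales (ratios near 0.5, angles
near 40 degrees, i-vector coordinates near 0, ages near 50).

Reported metrics are MAE (events/hour) and the Pearson correlation
between true and estimated AHI, plus classification metrics at the
AHI >= 10 boundary applied to both truth and prediction: accuracy,
sensitivity, specificity, and a rank-statistic ROC AUC (ties credited
0.5) treating the estimated AHI as a continuous score.

The leakage contract is explicit and tested: a subject's prediction is
unchanged by arbitrary perturbation of its own label, grid selection
equals an exhaustively recomputed oracle, and a stub regressor that
predicts the training mean reproduces its closed-form LOOCV predictions
exactly.

## What the synthetic cohort emulates

The generator is first-class, tested code, and its defaults *are* the
study conditions of the package's acceptance runs.

**Clinical variables.**  Weight, height, age and cervical perimeter are
drawn by rejection from truncated normals matching the descriptive
statistics of the 285-male clinical population the analysis targets
(e.g. AHI mean 21.7, SD 17.4, range 0–84.4 events/hour; BMI 30.0 +- 5.0).
The truncation-bound parameters are those of the parent normal, so
realized moments are slightly shifted (the tests check against the
analytic truncated moments, e.g. a realized AHI mean near 25.3).  BMI is
recomputed as weight/(height in m)^2 rather than sampled, preserving its
arithmetic identity.

**The AHI link.**  AHI must depend monotonically on its anthropometric
risk factors while matching its configured marginal.  The generator
builds a latent index from standardized BMI, age and cervical perimeter
(weights 0.5, 0.25, 0.35) plus Gaussian noise (SD 0.88), standardizes it
across the cohort, and maps it through the Gaussian-copula quantile
transform onto the configured truncated-normal AHI marginal.  Any
monotone link would serve; the quantile link was chosen over a softplus
because it reproduces the target marginal exactly in distribution while
remaining strictly monotone in every driver.  The empirical cohort-level
standardization step matters: BMI is a nonlinear function of two
truncated draws, so an analytic standardization leaves the latent
slightly off-scale and visibly biases the AHI marginal at large n.

**Landmarks.**  Each subject starts from fixed schematic templates (52
frontal, 24 profile points inside the 640x480 frame, the profile contour
lying exactly on its rectangle diagonal).  Only the point groups entering
the three measurements are perturbed, each driven by
`effect * z_AHI + sqrt(1 - effect^2) * noise`: the contour points blend
toward the bottom-right or top-left rectangle corner, the midface pair
slides along its own axis (exactly linear in the driver), and the tragion
rotates about the ramus (exactly linear in degrees).  Isotropic 1 px
jitter is then added to all points.  Default planted correlations are
-0.45 (cervicomental), +0.40 (face width), +0.45 (angle) — magnitudes in
the 0.4–0.5 range reported for the strongest craniofacial correlates of
AHI in photogrammetric studies, with the cervicomental sign negative
because the normalized area shrinks as neck fat grows.  A measurement
with effect size exactly 0 is left at the template (up to jitter): with
zero effects and zero jitter every subject receives the templates
verbatim, which pins the generator's zero case in tests.  Calibration is
a tested contract: at n = 2000 each empirical measurement-AHI correlation
lands within +-0.1 of its configured target.

**Speech features.**  The generator inverts the total-variability model:
a ground-truth UBM (64 components, 40 dims by default) and a random
ground-truth `T` of rank 30 are built deterministically from the seed;
each subject's latent `w` is standard normal with its first coordinate
tilted toward standardized AHI by a configurable correlation (default
0.2, deliberately weak — speech is the weaker modality in this problem);
frames are then sampled from the GMM with means shifted by `T w`.  300
frames per subject by default, a desk-scale stand-in for several read
sentences.  The planted latent is stored on the cohort so recovery tests
can compare extracted i-vectors against it after orthogonal Procrustes
alignment (i-vectors are identifiable only up to rotation).

**The ceiling oracle.**  The generator knows its own noise-free signal:
the measurements computed from pre-jitter geometry, and the link drivers
for the clinical channel.  `signal_ceiling()` reports the multiple
correlation of a linear fit of AHI on those noise-free signals — the best
any regression could do under the planted structure.  The acceptance
tests demand that the full LOOCV pipeline lands within +-0.15 of this
ceiling and that combining facial and clinical features never does
materially worse than either alone.

**What passing these tests does and does not show.**  The synthetic
cohort has linear-in-driver effects, Gaussian noise, a single fixed
template face, and no capture-process artifacts (pose, illumination,
landmarking failures).  Passing shows the machinery is correct and
leakage-free and that planted signal of realistic strength survives the
whole pipeline; it does not certify accuracy on real photographs or real
speech, where effect shapes, noise, and confounding are unknown and where
published craniofacial-plus-clinical models reach correlations near 0.45
rather than the synthetic ceiling of roughly 0.77.

## Problem sizes used in the packaged checks

The test suite and the acceptance script run at sizes chosen to exercise
every contract on one CPU in minutes: cohorts of 285 (the emulated study
size) for end-to-end properties, 2000–20000 for calibration and
moment checks, a 64-component/40-dimension/rank-2 simulation with 500
utterances of 1000 frames for subspace recovery (principal angle below
15 degrees after 10 EM iterations), and reduced SVR grids (2x2 or 4x2)
for the LOOCV loops.  All randomness flows from explicit seeds; two runs
with the same configuration and seed produce byte-identical reports, and
the cohort writer emits no timestamps for exactly that reason.

## Known limitations

- The cervicomental measure is not rotation-invariant (axis-aligned
  rectangle); head tilt biases it.
- The landmark templates are schematic, not anatomical averages; only
  the role-mapped geometry is meaningful.
- The i-vector front-end omits channel compensation and
  minimum-divergence re-estimation; both are standard extensions.
- Truncated-normal parameters describe the parent distribution;
  realized moments are biased by truncation (documented, tested
  analytically).
- The MAE-selected grid search inherits libsvm's convergence behavior at
  extreme C; the default grid caps C at 2^9.

## A worked run

```{r, eval = FALSE}
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
report$summary
autoplot(report$evaluations[["craniofacial+clinical"]])
```
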