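---
title: "Sum-of-sigmoids risk models from boosted-stump ensembles"
author: "PolarSOS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sum-of-sigmoids risk models from boosted-stump ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PolarSOS)
library(SummarizedExperiment)
```

## The problem

Quantitative PET myocardial perfusion imaging renders rest and
pharmacological-stress myocardial blood flow (MBF, mL/g/min) as circular
polar maps, with the flow reserve (MFR) map as their pixelwise ratio.
Predicting which patients will suffer a major adverse cardiovascular event
(MACE) within a two-year follow-up from these maps is a strongly
imbalanced binary classification problem (roughly one patient in eight has
an event), and the models that do it well — convolutional networks, deep
boosted-tree ensembles — are hard to justify case by case in a clinical
setting.

PolarSOS implements an interpretable alternative: a *sum-of-sigmoids*
classifier that is **constructed**, not trained. An ensemble of N
gradient-boosted models of maximum depth one is fit first; because every
tree in such a model is a decision stump, the ensemble's raw margin is an
exactly additive function of the individual input variables. Averaging each
variable's stump contributions over the ensemble gives a piecewise-constant
*score curve* per variable; each curve is then approximated by a
four-parameter sigmoid, and the final predictor is the Heaviside step of
the sum of a few top-ranked sigmoids. Every prediction decomposes into k
per-variable scores that can be read directly off k monotone curves.

## The model

Each member model is a boosted collection of stumps: tests of the form "is
variable x at least θ? add v_right, else add v_left". The score curve of
variable i is

s_i(x) = (1/N) Σ_models Σ_stumps-on-i [ v_right · H(x − θ) + v_left · (1 − H(x − θ)) ],

with H the Heaviside step, H(x) = 1 for x ≥ 0. Each curve is approximated
by least squares with

f_i(x) = A_i / (1 + exp(k_i (x − t_i))) − m_i,

which is monotone (decreasing in x for k_i > 0, the expected direction for
flow statistics: higher flow, lower risk). The classifier is

ŷ = H( Σ_{i=1..k} f_i(x_i) ),

predicting an event exactly when the summed score is nonnegative. Features
enter by their summed split gain across the ensemble (descending); k is
chosen by inspecting the accuracy-versus-k curve (`accuracyVsK()`) and
picking a value on its stable part.

Two conventions matter and are applied consistently: H(0) = 1, so a zero
sum predicts an event and a value exactly at a stump threshold takes the
right (x ≥ θ) leaf; and score curves are right-continuous at their
breakpoints for the same reason. The boosted models are fit with exact
split enumeration so thresholds are midpoints between observed values and
the x ≥ θ reading of a stump is faithful to the fitted trees
(`extractStumps()` verifies the reconstruction against the booster's own
margins).

## Feature extraction

`segmentStatistics()` partitions each polar map into the standard AHA 17
segments — rings at normalized radii 0.25/0.5/0.75/1 with 6 basal, 6 mid
and 4 apical sectors plus the apical cap; angles run counterclockwise from
12 o'clock and the apical ring is rotated by 45° — and computes 13
statistics per segment: mean, SD, minimum, maximum and the nine deciles
(linear interpolation between closest order statistics, the convention of
`quantile(type = 7)`). Pixels on a radial boundary belong to the outer
ring and pixels on an angular boundary to the counterclockwise-later
sector, so the segments partition the disc exactly for any raster. Three
maps × 17 segments × 13 statistics give the 663-feature vector with
canonical names such as `STRESS_S14_MIN`. Rasters of any size ≥ 32 pixels
are accepted; map resolution, vendor layout and any pre-normalization are
deliberately left to the data as given.

## Cohort handling

`splitTrainTest()` draws a random 3:1 split (test size
`round(0.25 · n)`: 1079 patients give 809/270) and validates it:
every feature's train and test marginals are compared with a two-group
Kruskal–Wallis test, Benjamini–Hochberg corrected, at α = .05, and the
outcome prevalence ratios r1 (event-free) and r2 (event) must satisfy
1/1.1 < r < 1.1. A failing draw is redrawn with seed + 1, up to 100
attempts. The ratio bound is strict at these event counts: a single random
draw of a 2000-patient cohort at 20% prevalence violates it about a third
of the time by hypergeometric arithmetic alone, which is precisely why the
redraw loop is part of the procedure. Features constant across both sets
get p = 1 (no evidence of shift) with a message.

Because only ~1 patient in 8 is positive, each ensemble member trains on a
*stratified undersample*: all positives are kept and
`round(n_pos (1 − p)/p)` negatives are drawn without replacement for a
target positive fraction p = 0.4 (102 positives keep 153 negatives). The
target deliberately stays below 0.5: near-balance for the loss, but more
negatives retained. Every member model uses its own draw (model j derives
its seed as master + j), which is what makes the averaged score curves
robust to any single unlucky stratification — the package's tests verify
that predictions vary less across ensembles with different master seeds
than across single stratified models.

## Numerical choices

* **Sigmoid fitting.** Curves are sampled at 200 uniform points over the
  feature's observed training range and fit with Levenberg–Marquardt
  (`minpack.lm::nlsLM`), equal weights, initialised at A₀ = curve range,
  m₀ = −min, t₀ = gain-weighted median of the stump thresholds, and
  k₀ = ±4/range with the sign of the overall trend; A is bounded below by
  0. Up to five jittered restarts follow a failed fit, and if the gradient
  is singular throughout — typical when the curve is one sharp step and A
  and k are jointly unidentifiable — a Nelder–Mead simplex on the same
  least-squares objective finishes the job. A curve with range below
  1e−12 short-circuits to the degenerate flat fit A = 0, m = −c.
  Non-monotone curves are still fit (the sigmoid is then the best monotone
  approximation) and the RMSE is recorded on the fit object.
* **Evaluation outside the training range** extrapolates the sigmoid
  naturally; the functional form is globally defined and monotone, so no
  clipping is applied.
* **Pruning.** `pruneSmallRange()` drops sigmoids whose output range over
  their domain falls below a threshold; a near-flat term moves the summed
  score by at most its range, so removal changes predictions only for
  cases whose |sum| was below that. At least one term must survive.
* **Display rounding** is half-up to two decimals and happens only in
  `show()`; internal metrics are never rounded.
* **Serialization** writes 17 significant digits so models and ensembles
  round-trip through JSON bit-exactly.

## The synthetic cohort generator

The clinical data behind the method are not redistributable, so the
package ships a generator that emulates their shape at the level the
model family cares about:

* `generateCohort()` draws per-patient segment mean flows around 0.9
  (rest) and 2.2 (stress) mL/g/min with between-patient SDs of 0.15/0.45,
  adds within-segment pixel noise (SD 0.15, floored at 0.05 mL/g/min so
  the pixelwise stress/rest reserve stays finite), extracts the 663
  features through the real pipeline, and assigns outcomes by a logistic
  model on standardized causal statistics (default: effects of −1 per SD
  on the four stress/reserve minimum statistics) whose intercept is solved
  numerically so the expected event rate equals the target prevalence
  0.126 ≈ 102/809.
* `groundTruthSOS()` + `sampleFromGroundTruth()` generate cohorts labelled
  by a *known* sum of sigmoids for recovery experiments. The defaults are
  four steep decreasing terms (k = 50–70 per mL/g/min, i.e. an abrupt
  ischemic flow threshold ~0.07 mL/g/min wide) sampled uniformly over a
  fixed 2 mL/g/min window with 35% of mass below the transition, and
  offsets m = 0.6 A. By construction the noiseless rule then fires when at
  least 3 of the 4 flows are low, i.e. for P(Binom(4, 0.35) ≥ 3) ≈ 12.7%
  of patients, matching the emulated training prevalence; the default 5%
  label flips raise the observed rate to about 0.16. Steep, well-separated
  terms are the regime in which structure recovery is well-posed; with
  wide transition zones the decision threshold bias discussed next
  dominates.

What the generator does *not* emulate: PET noise physics, attenuation and
scatter artifacts, perfusion-defect shapes, inter-segment correlation
structure, or clinical covariates. Passing recovery tests therefore show
that the construction recovers additive monotone structure under honest
noise and imbalance — not that it attains any particular accuracy on real
perfusion data.

## Known limitations

* Thresholding the bias-free score sum at zero inherits the training
  class balance: models trained at 40% positives predict positively for
  cases whose true event probability is well below one half. On cohorts
  with ~15% prevalence this produces FP-heavy confusion matrices — the
  same signature the reference clinical results show — and costs a few
  points of raw accuracy relative to an optimally shifted threshold. The
  construction keeps the published decision rule; no recalibration is
  applied.
* The surrogate assumes effects are additive and monotone per variable.
  Depth-one models cannot represent interactions, and a genuinely
  non-monotone score curve is approximated by its best monotone sigmoid.
* Sum gain is used for selection because it is the established ranking,
  but it is not proportional to a term's output range; a variable can
  rank fourth yet carry the widest score range.

## Experiment sizes used by the test suite

The package's own experiments (tests and `scripts/acceptance.R`) run the
full pipeline at a "small" preset chosen once: ground-truth cohorts of
n = 2000 with 4 causal + 50 nuisance features, ensembles of 20 models ×
30 rounds (the construction is insensitive to ensemble size beyond ~20
members on these cohorts), 100 seeds for the end-to-end recovery medians
in the test suite and 25 in the acceptance script, and rasters of 32–64
pixels for image-level tests. Full-scale settings (N = 100 models, 50
rounds, 663 features, 128-pixel rasters) remain the package defaults.

## A worked run

```{r pipeline, eval = FALSE}
gt <- groundTruthSOS()
d  <- sampleFromGroundTruth(gt, 2000, seed = 1)
sp <- splitTrainTest(d$features, 0.25, seed = 2)
ens <- trainStumpEnsemble(sp$train, ensembleConfig(20, 30), seed = 3)
mod <- buildSOSModel(ens, k = 4)
pred <- predict(mod, sp$test)
mean(pred$prediction == colData(sp$test)$MACE)
```

The same steps drive `scripts/acceptance.R`, which recomputes the
package's headline numbers from scratch; see the README for how to run it.
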