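# PolarSOS

Interpretable sum-of-sigmoids risk models from boosted-stump ensembles on
myocardial perfusion polar maps.

## What it is for

Quantitative PET myocardial perfusion imaging (MPI) produces rest, stress
and reserve polar maps of myocardial blood flow (mL/g/min). Predicting
two-year major adverse cardiovascular events (MACE) from these maps is a
strongly imbalanced classification problem, and the models that do it well
are hard to justify case by case. PolarSOS is for researchers and
methodologists who want a competitive *and* auditable predictor: every
prediction decomposes into a handful of per-variable scores read off
monotone sigmoid curves.

The core construction (no gradient descent, no surrogate training):

1. Train N gradient-boosted models of **maximum depth one** (decision
   stumps) on independently stratified undersamples of the training set
   (all events kept, non-events discarded to ~40% positives).
2. For each input variable, average its stump contributions across the
   ensemble into a piecewise-constant **score curve**
   `s_i(x) = (1/N) Σ [v_right·H(x−θ) + v_left·(1−H(x−θ))]`.
3. Rank variables by **summed split gain**, keep the top k, and fit each
   curve with a sigmoid `f_i(x) = A_i / (1 + exp(k_i (x − t_i))) − m_i`.
4. Predict `ŷ = H(Σ f_i(x_i))` — an event exactly when the summed score
   is nonnegative (H(0) = 1).

Around the core, the package provides AHA 17-segment feature extraction
(3 maps × 17 segments × 13 statistics = 663 features), a validated 3:1
train/test split (FDR-corrected Kruskal–Wallis feature check plus outcome
prevalence ratio bounds 1/1.1 < r < 1.1, with redraws), confusion-matrix
evaluation with support-weighted averages, a lasso-logistic baseline, and
a synthetic cohort generator so the whole pipeline is testable without
clinical data.

## Worked example

A synthetic cohort labelled by a known 4-term sum of sigmoids with 5%
label noise, rebuilt end to end:

```r
library(PolarSOS)
library(SummarizedExperiment)

gt  <- groundTruthSOS()                               # known generating model
d   <- sampleFromGroundTruth(gt, 2000, seed = 1)      # 4 causal + 50 noise features
sp  <- splitTrainTest(d$features, 0.25, seed = 2)     # validated 3:1 split
ens <- trainStumpEnsemble(sp$train, ensembleConfig(20, 30), seed = 3)
gainRanking(ens)[1:5, ]
#>           feature   gain
#> 1  STRESS_S15_MIN 4184.5
#> 2  STRESS_S14_MIN 3169.6
#> 3  STRESS_S10_MIN 3153.1
#> 4 RESERVE_S14_MIN 3073.3
#> 5     REST_S3_P90  200.5

mod <- buildSOSModel(ens, k = 4)
mod
#> SumOfSigmoidsModel with 4 sigmoid terms:
#>   STRESS_S15_MIN       A=1.584 t=0.9482 k=35.16 m=0.9234 (range 1.584)
#>   STRESS_S14_MIN       A=1.351 t=0.9953 k=70.44 m=0.7086 (range 1.351)
#>   STRESS_S10_MIN       A=1.301 t=1.111 k=104.1 m=0.7038 (range 1.301)
#>   RESERVE_S14_MIN      A=1.317 t=1.514 k=95.53 m=0.7331 (range 1.317)
#> prediction: event iff sum of sigmoid scores >= 0

pred <- predict(mod, sp$test)          # per-feature scores, sum, 0/1 prediction
mean(pred$prediction == colData(sp$test)$MACE)
#> [1] 0.936

metricsFromCounts(confusionCounts(colData(sp$test)$MACE, pred$prediction))
#> ConfusionReport (n = 500): TN=408 FP=7 FN=25 TP=60
#>                                Precision Recall f1-score
#>   Patients without an event         0.94   0.98     0.96
#>   Patients with an event            0.90   0.71     0.79
#>   Accuracy                                          0.94
#>   Weighted averages                 0.93   0.94     0.93
```

The gain ranking recovers the four causal flow statistics ahead of the 50
noise features, the fitted sigmoids are steep and decreasing (higher flow,
lower risk), and the rebuilt model classifies held-out patients at 0.94
against a noise ceiling of 0.95. `accuracyVsK()` traces accuracy against
model size; `pruneSmallRange()` drops near-flat terms;
`caseScoreFigureData()` returns the per-case curve/score/segment-overlay
data used for case-level visual explanations. A thin command-line wrapper
over these functions is in `inst/scripts/polarsos.R`.

The methods vignette (`vignettes/sum-of-sigmoids.Rmd`) documents the
model, the conventions (H(0) = 1, right-continuous curves, type-7
percentiles), the sigmoid-fitting numerics, what the synthetic generator
does and does not emulate, and known limitations.

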