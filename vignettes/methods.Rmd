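---
title: "Two-step longitudinal biopsychosocial phenotyping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step longitudinal biopsychosocial phenotyping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlbpsp)
```

## The problem

Chronic-disease cohorts — the motivating case is people with HIV followed
with repeated neurocognitive, mood and daily-functioning assessments — are
heterogeneous in both the *level* and the *course* of their problems. A
participant with moderate depression that resolves over 18 months is
clinically different from one whose depression persists, even if their
baseline scores coincide. `mlbpsp` identifies such multidimensional
longitudinal phenotypes by clustering participants on the *parameters of
their individual trajectories* rather than on raw visit values.

## The two-step model

**Step one — per-feature trajectory mixed models.** Each feature
$y$ (non-negative, right-skewed raw scores are square-root transformed
first) observed at visit times $t \in \{0, 1, 2, 3\}$ (one unit = 6 months)
is modelled as

$$y_{ij} = \beta_0 + \beta_1 t_{ij} + \beta_2 t_{ij}^2
  + b_{0i} + b_{1i} t_{ij} + b_{2i} t_{ij}^2 + \varepsilon_{ij},
  \qquad b_i \sim N(0, G),\ \varepsilon_{ij} \sim N(0, \sigma^2),$$

fitted by maximum likelihood on all observed rows. Likelihood-based fitting
is valid under missing-at-random visits without imputation. The
participant-level summary of each feature is the empirical-Bayes (BLUP)
prediction of the three random effects,
$\hat b_i = G Z_i^\top V_i^{-1} (y_i - X_i \hat\beta)$ with
$V_i = Z_i G Z_i^\top + \sigma^2 I$ — a shrinkage estimate of the
individual's deviation from the population intercept, slope and curvature.
With $F$ features this yields an $N \times 3F$ matrix (17 features give the
51 columns used throughout the documentation).

**Step two — compression and clustering.** The random-effect columns are
z-scored, compressed by PCA to the smallest number of leading components
reaching a cumulative explained-variance threshold (default 0.85), and
clustered by k-means (k-means++ seeding, 50 restarts, best of by WSS). The
number of clusters is chosen by the elbow of the WSS curve over
$k = 1..9$, operationalized as the point of maximum perpendicular distance
to the chord joining the curve's endpoints, ties broken toward smaller $k$;
a forced `k` bypasses selection. Clusters are then relabelled 1..k by
ascending severity (mean of z-scored baseline GDS, BDI-II total, PAOFI
total and IADL total over members), so label 1 is always the healthiest
phenotype and labels are comparable across runs.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| time coding | `visit_month / 6` | keeps the quadratic term well conditioned; coefficients are per 6-month visit unit |
| transform | square root for all default features | raw deficit/symptom scores are non-negative counts with right skew; the transform is part of the model contract, so the generator produces data Gaussian on exactly that scale |
| estimation | ML, not REML | fixed effects stay comparable across models; variance components are mildly biased downward, which is immaterial for clustering on BLUPs |
| random-effect covariance | unstructured 3×3, diagonal fallback on non-convergence | four observations per subject make an unstructured G only marginally identified; the fallback is flagged in the fit object |
| PCA threshold | 0.85 | the retained count is data-dependent and reported, never asserted |
| k-means | 50 restarts, k-means++ seeding, fixed seed | mitigates local minima; deterministic given the seed |
| elbow scan | k = 1..9 | selection needs at least 3 points; `k` can be forced |
| BH families | k = 3 (each phenotype vs P1) or k = 6 (all pairs) | mirrors the comparison families used in baseline tables |
| selection thresholds | screen p ≤ 0.10, retain p ≤ 0.05 | inclusive boundaries; screening uses the likelihood-ratio p of the whole predictor block (df = K−1), retention the minimum Wald contrast p |

## Standardizing before PCA

Whether the random-effect columns should be standardized is genuinely open:
intercept effects are an order of magnitude larger than quadratic-slope
effects, so unstandardized PCA would be intercept-dominated and the
"longitudinal" part of the phenotype would barely enter the clustering.
We z-score all columns. This is a design choice of this package, documented
here rather than attributed to anyone.

## The multinomial predictor models

Phenotype membership is regressed on baseline predictors with
baseline-category multinomial logit (reference = phenotype 1), fitted by
Newton–Raphson on the exact likelihood; standard errors come from the
inverse observed information, so the 95% intervals are Wald intervals
$\exp(\hat\beta \pm 1.96\,\mathrm{se})$. For a binary predictor the
univariable model is saturated, hence the fitted contrast ORs equal the
2×2 contingency-table sample odds ratios — this identity is what makes the
published odds-ratio table exactly recomputable from its printed counts,
and it is the package's acceptance check. Multivariable selection is
iterative backward elimination: repeatedly drop the non-forced
predictor whose best contrast p is largest and above 0.05, refit, stop when
all retained predictors have some contrast p ≤ 0.05. Education is forced.
(A single-pass elimination would also have been defensible; the iterative
rule is this package's choice.) Complete separation is detected (diverging coefficients or exploding
standard errors) and flagged on the result rather than raised as an error.

## The synthetic cohort: what it emulates, what it does not

The generator is a stated world, not a tuning dial:

* N = 506 participants, visits at months 0/6/12/18, four archetypes with
  mixture weights 45.6/21.3/19.2/13.8%.
* Latent trajectories are drawn on the transformed scale and squared
  (negative latent values clamped at zero first, since raw scores are
  non-negative counts), so the pipeline's square-root transform recovers
  Gaussian structure *by construction* — the generator guarantees the
  model's assumption instead of approximating a named skew distribution.
* Visit-level missingness 8.3% at month 12 and 19.4% at month 18, baseline
  never deleted; the item-level rate defaults to
  $1-(1-0.283)^{1/68}$ so that about 28.3% of participants miss at least
  one of the 17 × 4 feature cells. Participants left with fewer than two
  observed visits are removed and counted.
* Baseline covariates are drawn per phenotype: Bernoulli comorbidities at
  the published group prevalences (e.g. chronic pulmonary disease
  5.63/8.33/11.34/20%), Poisson medication counts with rates
  (1.3, 2.3, 2.3, 3.3) chosen so the Poisson medians equal the published
  medians (1, 2, 2, 3), and Gaussian labs/demographics at the published
  mean/sd pairs.
* The default 17-feature roster (7 neurocognitive domain deficit scores,
  4 BDI-II subscales, 5 PAOFI components, 1 IADL total) is an informed
  guess: the exact roster behind the published analysis is not enumerated
  anywhere, so it is configurable and none of the tests depend on its
  identity.
* Two archetype sets ship: `default_archetypes()` (study-like separation)
  and `separable_archetypes()` (stronger mean separation, smaller
  subject-level noise). End-to-end recovery tests run on the separable set;
  a green recovery test establishes that the pipeline machinery is correct
  on data satisfying its assumptions, *not* that real cohorts are this
  separable — the published membership counts, 18 retained components and
  60.5%/82.6% classifier accuracies depend on the restricted study data
  and are treated as reference values, never as test assertions.

What the generator does not emulate: antiretroviral regimens and
viral-load dynamics, item-level instrument responses, informative (MNAR)
dropout, and the numeric shapes of the published trajectory figures.

## Numerical choices

* LMM optimizer: `bobyqa` with `maxfun = 1e5`; singular fits (variance
  components on the boundary) are accepted, genuine optimizer failure
  triggers the diagonal-G refit, and failure of both is a hard error naming
  the feature. A perfectly constant feature short-circuits to the
  degenerate fit (β = (c, 0, 0), G = 0, all BLUPs 0).
* With four timepoints the unstructured-G model saturates the 4×4 marginal
  covariance, so individual variance components can trade off against each
  other (large slope variance with near-±1 correlations) while the implied
  marginal covariance $Z G Z^\top + \sigma^2 I$ — the identified quantity —
  stays stable. Tests assert the identified quantity.
* Multinomial Newton–Raphson: step-halving line search, convergence on
  relative log-likelihood change < 1e-10, max 100 iterations; rank
  deficiency of the design is an error that names a perfectly collinear
  pair when one exists.
* Participants never observed for a feature receive that feature's prior
  mean (0, 0, 0) as their empirical-Bayes effect — the exact EB prediction
  given no data — and are recorded in the matrix's provenance attribute.
* Cluster agreement between two labelings is the assignment-problem
  (Hungarian) matching of the confusion matrix divided by the number of
  common ids; the adjusted Rand index is reported alongside. "Percent
  agreement" between partitions has no canonical definition; this is ours.
* WSS curves are forced non-increasing by a running minimum before elbow
  selection (restart noise can produce tiny inversions).
* All stage-level randomness derives child seeds from one root seed, so
  every artifact is reproducible bit-for-bit from the manifest.

## Classifier stage

The four-class random forest (500 trees, $\sqrt p$ candidate features per
split, unlimited depth, grown to purity) and the binary
healthy-vs-less-healthy logistic regression are evaluated by stratified
10-fold cross-validation (stratification is our choice, motivated by the
45.6% vs 13.8% class imbalance); folds shrink with a warning when the
smallest class has fewer members than folds. Reports carry the pooled
out-of-fold confusion matrix, accuracy, misclassification and
per-predicted-class misallocation rates.

## Known limitations

* Wald normal-approximation p-values are used for mixed-model contrasts
  (no denominator-df correction) and multinomial coefficients; at the
  cohort sizes targeted (hundreds) this is standard, at small n it is
  anti-conservative.
* The unstructured-G fit is only marginally identified with four visits;
  interpret individual variance components with care (the BLUPs used for
  clustering are stable).
* Backward elimination inherits the usual instabilities of stepwise
  selection; the selection trace is persisted so runs can be audited.
* The elbow criterion is a heuristic; on curves without a clear knee it
  legitimately returns small k, and forcing `k` is the supported remedy.
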