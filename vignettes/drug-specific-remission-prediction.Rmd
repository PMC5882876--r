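---
title: "Drug-specific prediction of antidepressant remission: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-specific prediction of antidepressant remission: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxremit)
```

## The problem

Patients with major depression differ widely in their response to
antidepressants, and no single clinical or genetic variable predicts who
will remit on which drug. `rxremit` implements a statistical-learning
pipeline for *drug-specific* outcome prediction in a randomized two-arm
pharmacogenetic trial: participants are randomly allocated to one of two
antidepressants, genotyped for common variants, and assessed on standard
depression scales; the goal is a per-drug model of remission (HRSD-17
total of 7 or less at end of treatment) that validates in participants
never touched during derivation, and that predicts *specifically* — a
model derived on one drug should not predict outcomes under the other.

The pipeline has four stages, each exposed as ordinary R functions and
orchestrated by `run_full_study()`:

1. **Preprocessing** (`preprocess_cohort()`): genotype QC (minor allele
   frequency strictly above 0.01, per-SNP completeness at least 99%,
   greedy LD pruning at squared correlation 0.8), bagged-tree imputation
   of clinical predictors with categorical rounding, remission derivation
   from HRSD totals, and a single pooled 65/35 outcome-by-drug stratified
   split (`split_train_validation()`).
2. **Variable selection** (`stability_select()`): correlation-adjusted
   t-scores (CAT) with a local false discovery rate (LFDR), voted over 20
   repetitions of 5-fold cross-validation; a feature is kept when its LFDR
   falls below 0.8 in strictly more than half of the 100 rounds.
3. **Modelling** (`tune_enet()`, `fit_enet_logistic()`): elastic-net
   logistic regression on the retained features, hyperparameters tuned by
   mean out-of-fold AUC over 100 repetitions of 5-fold cross-validation.
4. **Evaluation** (`evaluate_predictions()`): AUC with DeLong confidence
   interval and test against chance, sensitivity/specificity at a
   threshold frozen on training data, and Nagelkerke pseudo-R².

## The selection statistic

For a binary outcome the per-feature standardized mean difference is

$$\delta_k = \frac{\bar x_{k,1} - \bar x_{k,0}}{m\, s_k},
\qquad m = \sqrt{1/n_1 + 1/n_0},$$

with $s_k$ the pooled within-group standard deviation (floored at
$10^{-8}\times$ the median $s$ so that near-constant but perfectly
separating features are scored rather than dropped; truly constant
features are flagged and scored 0). The CAT score decorrelates these:

$$\tau = R_{\text{shrunk}}^{-1/2}\,\delta, \qquad
R_{\text{shrunk}} = \lambda I + (1-\lambda) R_{\text{emp}},$$

where $R_{\text{emp}}$ is the empirical correlation of the group-centered
residuals and $\lambda$ is the analytic shrinkage intensity
$\sum_{k<l}\widehat{\mathrm{Var}}(r_{kl}) / \sum_{k<l} r_{kl}^2$ (clamped
to $[0,1]$), with $\widehat{\mathrm{Var}}(r_{kl})$ the empirical variance
of the per-observation products of standardized residuals scaled by
$n/(n-1)^3$. At $\lambda = 1$ the CAT score equals $\delta$ exactly. The
inverse square root is computed through the SVD of the $n \times p$
residual matrix, so the cost is $O(p n^2)$ and the $p \times p$
correlation matrix is never formed; for $p \le 200$ the result agrees
with a dense eigendecomposition to $10^{-8}$ (this is a unit-tested
invariant). One SVD serves both the shrinkage intensity and the
decorrelation. $\lambda$ is floored at $10^{-6}$ when inverting so the
square root stays defined for rank-deficient residuals.

### Local false discovery rate

Scores are modelled as the two-component mixture
$f(s) = \eta_0 f_0(s) + (1-\eta_0) f_1(s)$. The null scale is estimated
robustly as $\sigma_0 = \mathrm{median}|\tau| / \Phi^{-1}(0.75)$, the
marginal $f$ by a Gaussian kernel density with Silverman bandwidth $h$,
and $\eta_0 = \min(1, \hat f(0)/f_0(0))$. Two numerical subtleties
matter for calibration. First, the kernel estimate of the marginal
carries variance $\sigma^2 + h^2$, so the null component is evaluated at
the same kernel resolution, $f_0 = N(0, \sigma_0^2 + h^2)$; without this
the ratio $f_0/\hat f$ decays spuriously with $|s|$ under a *pure null*,
letting 1–2% of null features pass the 0.8 threshold in every round and
inflating null retention several-fold. Second, the marginal at each
score excludes that score's own kernel (a leave-one-out evaluation):
the self-kernel mass $K(0)/p$ is negligible where the density is large
but roughly doubles $\hat f$ at an isolated tail score, spuriously
halving its LFDR — exactly where retention decisions are made. With both
corrections the null LFDR is roughly flat at $\eta_0$ and only genuine
local density elevations — signal clusters — pull it down. LFDRs are clamped to $[0,1]$ and made non-increasing in $|\tau|$ by
isotonic regression, so they read as "probability this feature is
non-informative given its score". Estimation requires at least 50 scores;
an all-equal score vector yields LFDR 1 everywhere with a warning.

The 0.8 threshold is deliberately liberal — the vote across 100
cross-validation rounds, not the single-round threshold, provides the
stringency. "More times than not" is read as strictly more than half of
the *executed* rounds; rounds whose in-fold data lose an outcome class are
skipped and removed from the denominator.

## The elastic net

`fit_enet_logistic()` minimizes, on internally standardized features with
an unpenalized intercept,

$$\frac{1}{n}\sum_i -\left[y_i \eta_i - \log(1 + e^{\eta_i})\right]
 + \lambda\left(\alpha \|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\right),$$

by coordinate descent inside an IRLS loop (compiled code), stopping when
the objective changes by less than $10^{-8}$ between sweeps; a
step-halving safeguard keeps the objective non-increasing, which is a
tested invariant together with the KKT conditions at every zero
coefficient. Coefficients are reported de-standardized (log-odds per
allele or per unit), and the JSON export carries both per-unit and
per-standard-deviation odds ratios since published model tables are
ambiguous between the two scalings.

Tuning maximizes mean out-of-fold AUC over a grid of 3 mixing weights
$\alpha \in \{0.1, 0.55, 1\}$ and 12 penalties per $\alpha$, log-spaced
four decades down from $\lambda_{\max}$ (the smallest penalty zeroing all
coefficients). The tuning metric is not named in the original design;
AUC matches the reporting metric and is the package default. Exact ties
break toward larger $\lambda$, then larger $\alpha$ — the parsimony
direction. Folds are outcome-stratified; folds with a single class on
either side are skipped.

## Evaluation

The AUC is the Mann–Whitney probability with ties counting one half —
exactly equal (to $10^{-12}$, tested) to exhaustive pair enumeration and
to trapezoidal integration of the empirical ROC. Confidence intervals and
the test against AUC = 0.5 use the DeLong placement-value variance with a
Wald interval truncated to $[0,1]$; with zero placement variance (perfect
separation, or an intercept-only model's constant predictions) the
interval collapses to the point, the report is flagged, and the p-value is
the machine floor (or 1 at an AUC of exactly 0.5). The classification
threshold maximizes Youden's J on *training* predictions and is frozen in
the model before any validation use — the original reports give
sensitivity and specificity without stating a threshold rule, so this is
the central documented assumption behind those two numbers. The
Nagelkerke pseudo-R² uses an intercept-only null refitted to the
evaluated labels by default (configurable to a frozen training
prevalence), so a model predicting the observed prevalence scores exactly
0.

## Study orchestration

`run_full_study()` performs the 65/35 split once on the pooled cohort and
intersects it with the drug arms (per-arm training sizes then match the
published two-arm design of 430 → 280/150), rather than splitting within
each arm. Everything derivation-side — selection votes, tuning, fitting,
threshold choice — sees only training-partition participants; this is
enforced structurally (derivation functions receive training indices
only) and tested by deleting a validation participant and hashing the
derivation artifacts. Cross-drug specificity applies the frozen model,
including its frozen threshold, to validation participants of the other
arm with no refitting. When selection retains nothing the pipeline fits
an intercept-only model and reports chance-level metrics with a warning
instead of failing. Artifact writing (votes, model JSONs at full
17-digit precision, per-context reports, ROC tables, manifest) is
deterministic: the manifest records the resolved configuration, seeds,
package version and a cohort content hash, but no wall-clock timestamp,
so two runs from one configuration are byte-identical.

All randomness flows from one master seed through a documented counter
scheme (`derive_seed()`): distinct offsets for genotypes, clinical
variables, arm assignment, outcomes, missingness, the split, selection
rounds and tuning folds. Derived seeds stay below $2^{31}-1$.

## The synthetic cohort generator

Because the motivating trial data are licensed, the package ships a
first-class generator (`simulate_cohort()`) with known ground truth, and
the whole pipeline is exercised against it.

* **Genotypes.** Each SNP draws a MAF uniformly from (0.05, 0.5) — the
  lower bound sits above the 0.01 QC filter so simulated variants survive
  QC by construction. LD is induced by thresholding latent AR(1)
  Gaussians (correlation 0.3, blocks of 5) at Hardy–Weinberg quantiles;
  blocks are independent. This construction was chosen over haplotype
  copying because the implied dosage correlation of a within-block pair
  is computable by bivariate-normal quadrature, giving an exact oracle
  for tests.
* **Clinical variables.** A cycling mix of 0–4 and 0–2 ordinal items,
  binary indicators, and age-like/BMI-like continuous measures, each with
  declared type and admissible range so categorical rounding after
  imputation is testable. Defaults: 20 columns with 5% MCAR missingness.
* **Outcomes.** Per drug arm, a sparse logistic model on that arm's
  causal set. Causal columns enter centered at their cohort means, so
  `plogis(intercept)` is the arm's marginal remission prevalence
  regardless of the causal allele frequencies; the default intercept 0
  gives ~50% prevalence, an arbitrary but documented choice since per-arm
  prevalence is not published for the motivating trial. In HRSD mode the
  integer total is `clip(7 + ceiling(6 (w - eta)), 0, 52)` with
  `w ~ Logistic(0,1)`, which is monotone decreasing in the linear
  predictor and satisfies `P(score <= 7) = plogis(eta)` exactly, so the
  remission-threshold operation is exercised at a known prevalence.
* **Missingness** is MCAR only, confined to clinical columns. Arm
  assignment is an independent coin flip, emulating randomization.

What the generator does *not* emulate — population structure,
relatedness, genotyping error, haplotype-scale LD decay, MNAR
missingness, item-level correlation structure within scales — bounds what
green tests mean: they certify the statistical machinery under clean
randomized conditions, not robustness to the messiness of real cohort
data.

### Test-bench conditions

The heavier accuracy tests run the full pipeline at two canonical
designs, sized so the whole suite completes comfortably on one CPU: a
power/specificity bench (n = 2000, 500 SNPs, ten causal SNPs per drug on
disjoint sets at per-allele OR 1.8, 10–20 replicate seeds) and a null
bench (280 participants per arm, 500 SNPs, no effects anywhere, 10
seeds). On the null bench, selection retains at most a handful of
features and validation AUC stays at chance; on the power bench the
majority of causal variants are recovered, same-drug validation AUC
clears 0.70 on average, and cross-drug AUC stays near 0.5 — the
qualitative signature of drug-specific prediction.

## Known limitations

* LD pruning is greedy left-to-right in a 50-column window on r²; the
  published filter says only "LD over 0.8", so measure, window and
  which member of a pair is kept are implementation choices, all
  configurable.
* Whether the original split or folds were stratified is not published;
  both are stratified here (configurable off) for stability at these
  sample sizes.
* Clinical and genetic features are scored jointly in one matrix during
  selection; the original report does not say whether they were pooled.
* The bagged-tree imputer (25 rpart trees per incomplete column,
  bootstrap resamples, ensemble mean / plurality vote with ties toward
  the smaller level) names only the method class in the original; its
  parameters are package choices.
* The DeLong-based p-values are one concrete choice; the original does
  not state how its AUC p-values were computed.
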