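---
title: "Genomic prediction of longitudinal lipid levels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction of longitudinal lipid levels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidprs)
```

## The problem

Serum lipids — HDL cholesterol, LDL cholesterol, total cholesterol and
triglycerides — are measured repeatedly over a patient's life, and a large
set of common genetic variants with small per-allele effects on each of them
is known from genome-wide association studies. This package asks, on
longitudinal cohort data: *how much does genomic information improve the
prediction of a person's lipid levels over a model using only age, sex and
BMI?* It provides the full machinery to answer that question with
leave-one-subject-out cross-validation: a random-intercept mixed-model
engine, four families of genomic risk models, and a synthetic-cohort
generator with a recorded generative truth so that every stage can be tested
end to end without access to any individual-level human data.

## The base model

All analyses are built on the random-intercept linear mixed model

$$y_{it} = \mathbf{w}_{it}^\top \theta + u_i + \varepsilon_{it}, \qquad
u_i \sim N(0, \sigma^2_u), \quad \varepsilon_{it} \sim N(0, \sigma^2_e),$$

where $y_{it}$ is the lipid value of subject $i$ at visit $t$ (mg/dL) and
$\mathbf{w}_{it}$ contains an intercept, a transformed age, sex
(0 = female, 1 = male) and BMI. The subject intercept $u_i$ absorbs the
within-person correlation of repeated visits. Fixed effects are the
generalized-least-squares estimator
$\hat\theta = (W^\top V^{-1} W)^{-1} W^\top V^{-1} y$ at the
variance-component optimum, with
$V = \sigma^2_u Z Z^\top + \sigma^2_e I$.

`lmm_ri()` implements this directly: the fixed effects and the residual
variance are profiled out of the (restricted) likelihood, and the single
variance ratio $\gamma = \sigma^2_u/\sigma^2_e$ is optimized by bounded 1-D
search on the log scale. Because $V$ is block-diagonal by subject and each
block is an identity plus a rank-one term, every block inverse is analytic
($V_i^{-1} \propto I - \frac{\gamma}{1+\gamma k_i} J$), so the cost is
linear in the number of observations while remaining *exactly* equal to the
dense-matrix GLS solve — a property the test suite asserts against a
brute-force oracle at 1e-10, and against lme4 for the estimates,
likelihoods and standard errors. AIC is computed as
$2(p+2) - 2\ell$ (fixed effects plus two variance components).

When a subject has a single observation the ratio is unidentifiable; the
fit collapses to ordinary least squares with the subject variance pinned at
zero and flagged (`boundary = TRUE`).

### Modelling age

Lipid levels follow a sigmoidal trend over the lifespan. Instead of a
linear age term the covariate used everywhere is

$$f(a) = \sin\!\Big(\tfrac{\pi}{2}\,
  \frac{2a - a_{max} - a_{min}}{a_{max} - a_{min}}\Big),$$

which is $-1$ at the study minimum age, $+1$ at the maximum, strictly
increasing, and steepest in the middle of the span. (The sign convention in
the numerator is the unique one satisfying those extremes.)
`compare_age_models()` fits the non-genetic model under both age codings by
maximum likelihood and reports both AICs; the models have equal dimension,
so the comparison is a pure likelihood comparison. Inside cross-validation
$(a_{min}, a_{max})$ are always taken from the training split, and held-out
ages just outside the span are clamped to the boundary.

## The four genomic risk-model families

Let $x_{ij} \in [0,2]$ be subject $i$'s dosage of the effect allele at
marker $j$. Two marker sets are used per trait: **R** (markers previously
reported for that trait) and **A** (all catalogued lipid markers).

1. **Published-weight score (NCBI).** The weighted allele count
   $\mathrm{score}_i = \sum_j x_{ij} w_j$ with $w_j$ the published
   per-allele estimate (mg/dL) from the marker catalog, restricted to the R
   set. When several studies report the same marker the estimate from the
   largest study is used (`dedup_largest_study()`). The score enters the
   mixed model as a fifth fixed covariate.

2. **Within-cohort score (BHS).** Instead of published weights, each
   subject's weights are single-marker effects estimated *from the other
   subjects*: $\hat\beta_{-i,j}$ is the marker coefficient of the
   random-intercept model `y ~ marker + f(age) + sex + bmi` fitted without
   any of subject $i$'s observations, and
   $\phi_i = \sum_j x_{ij}\hat\beta_{-i,j}$. `loo_marker_effects()`
   supports an exact mode (a full REML refit per subject-marker pair, the
   reference implementation) and a fast mode that estimates the variance
   components once per left-out subject from the covariate-only model and
   then obtains every marker's GLS coefficient *exactly* at those
   components by cross-product downdating; the two agree within a few
   percent on test cohorts, and the fast mode preserves the exclusion
   guarantee because nothing derived from subject $i$'s phenotypes enters
   row $i$.

3. **Bayesian lasso (BLR) and 4. Bayesian ridge (BRR) whole-genome
   regression.** All markers of the set enter simultaneously:
   $y = W\theta + X\beta + Zu + e$ with flat priors on $\theta$, a
   double-exponential (lasso, via per-marker latent scales $\tau_j^2$ and a
   regularization parameter $\lambda$) or common-variance Gaussian (ridge)
   shrinkage prior on $\beta$, and scaled-inverse-chi-square priors on all
   variances. The Gibbs sampler is written in C++ but draws from R's RNG,
   so runs are exactly reproducible under a seed. Predictions for unseen
   subjects are the posterior-mean linear rule
   $\hat y = X\bar\beta + W\bar\theta$.

### Prior elicitation for the whole-genome models

With training phenotypic variance $V(y)$, assumed lipid heritability
$h^2 = 0.5$, prior degrees of freedom $df = 5$ (finite mean and variance,
weak influence), and $MS_x = \sum_j \overline{x_{ij}^2}$ the average sum of
squares of the training genotypes, `wgr_priors()` sets

* $S_E = V(y)(1-h^2)(df-2)$, so the residual-variance prior mean
  $S_E/(df-2)$ is the non-genetic variance share $(1-h^2)V(y)$;
* $S_U = V(y)\,h^2(df-2)$ for the subject-intercept variance;
* ridge: $S_B = V(y)h^2(df-2)/MS_x$, putting the prior-mean total marker
  variance at $h^2 V(y)$;
* lasso: $\lambda$ centred at $\sqrt{2(1-h^2)MS_x/h^2}$ (the value at which
  the implied genomic variance equals $h^2V(y)$), with a
  Gamma(shape = 2, rate = $1/\lambda^2$) prior on $\lambda^2$ whose mode
  sits at that centre — flat over a wide range.

These scales were chosen so that every prior *mean* equals its natural
variance-partition target; this is the internally consistent reading of the
recipe, and the package implements it uniformly.

## Cross-validated evaluation

`loso_cv()` implements leave-one-subject-out ("n-fold") cross-validation:
all of a subject's observations are removed together, the model is fitted
on the remainder, and the subject's visits are predicted through the fixed
(population-level) part only — the random intercept of an unseen subject
has expectation zero. Accuracy is $R^2$, the squared Pearson correlation
between observed and predicted values pooled over all observations, with a
**subject-level (cluster) percentile bootstrap** for its 95% interval
(observations within a subject are dependent, so resampling subjects is
the defensible unit). The gain of a genomic model is
$\Delta R^2 = R^2_{model} - R^2_{non\text{-}genetic}$; the significance
attached to a score is the Wald p-value of the score coefficient in the
full-cohort mixed model (`score_significance()`), not a test on the $R^2$
difference itself — the two presentations are deliberately kept distinct.

Leak-freedom is treated as a contract and enforced by mutation tests: for
every model family, altering a held-out subject's phenotypes must leave
that subject's predictions bit-identical. Two design choices follow from
it:

* Missing dosages are mean-imputed per marker **from the training split
  only** (`impute_missing_dosages()`).
* Inside a CV fold the BHS builder uses *nested* leave-one-out: training
  subjects' scores use effects excluding both the training subject and the
  held-out subject (cheap via rank-one downdating of the GLS
  cross-products), and the held-out subject's score uses effects from the
  full training split. The single-level $\phi_i$ of the field's standard
  presentation remains available through `loo_marker_effects()` +
  `bhs_score()` on the full cohort and is what `score_significance()`
  uses.

### Age-window analyses

`age_window_analysis()` evaluates a score at a target age (10, 20, 30, 40):
each subject contributes at most one observation — the one closest to the
target within ±2.5 years. With one observation per subject the random
intercept is unidentifiable, so ordinary linear models are used, with exact
leave-one-out predictions obtained from the hat matrix. Optionally the
subject's most recent lipid measurement *strictly before* the selected
observation (regardless of window) enters as a covariate; subjects with no
earlier measurement are dropped with a reported count. Because the previous
measurement carries the subject intercept and the genetic signal, strong
phenotype tracking attenuates the score's $\Delta R^2$ — a qualitative
pattern the acceptance tests reproduce.

## The synthetic cohort generator

`simulate_cohort()` generates data with exactly the structure the analysis
assumes:

$$y_{it} = \mu + a\,f(\mathrm{age}_{it}) + s\,\mathrm{sex}_i +
  b\,\mathrm{BMI}_{it} + \textstyle\sum_j x_{ij}\beta_j + u_i +
  \varepsilon_{it}.$$

Defaults emulate a longitudinal cardiovascular cohort of 523 subjects
surveyed from age 4 to 48: visit counts $k_i = 4 + \mathrm{Bin}(9, 0.411)$
(mean 7.7 by construction, 4–13 per subject), first visit uniform over the
childhood entry window (ages 4–17), later visits ~3 years apart with
jitter, male fraction 0.455, BMI linear in age with subject-level random
intercept and slope. Genotypes are Binomial(2, MAF) with MAF uniform on
(0.1, 0.5) and 1% missingness. Causal effect sizes follow the standard
polygenic convention $|\beta_j| \propto (2\,\mathrm{MAF}_j(1-\mathrm{MAF}_j))^{-1/2}$
with random signs, scaled so the genetic variance is exactly the target
fraction (default 0.5) of the non-covariate variance
($\sigma^2_u = \sigma^2_e = 15^2$ mg/dL² by default). The emitted marker
catalog carries $\beta_j + N(0, 1.5^2)$ for causal markers under the run's
trait — emulating published-estimate error — and pure-noise weights for
null markers under the other traits, so the R set is the causal set and the
A set adds the nulls. The default 18 causal / 42 null split mirrors a lipid
GWAS catalog in which roughly 30% of all catalogued markers are reported
for any one trait. A `TruthRecord` (effects, subject intercepts, complete
dosages, variance components) is returned for recovery tests.

What the generator does **not** emulate: linkage disequilibrium between
markers (dosages are independent), gene–gene and gene–environment
interaction, cross-trait correlation (one trait per run), ancestry
structure, and measurement-protocol drift over calendar time. Passing tests
therefore demonstrate correctness of the machinery and the qualitative
behaviour of the estimators under the assumed generative model — not
performance on real cohort data.

The bundled `inst/extdata/synthetic_marker_catalog.tsv` is likewise a
**synthetic** stand-in for a curated lipid GWAS-catalog extract: 207
markers with per-trait unique-marker counts 77 (HDL), 62 (LDL), 65 (TC),
40 (TG), including a few multi-study duplicates for the deduplication
logic. Its weights are draws from trait-scaled normals, not real published
estimates.

## Numerical choices and edge cases

* Variance-ratio optimization: `optimize()` on $\log\gamma \in [-12, 12]$;
  the boundary $\gamma = 0$ is checked explicitly and flagged.
* Markers monomorphic in a training split contribute effect 0 to scores
  (no information, avoids division by ~0), with a warning.
* Largest-study ties in the catalog break to the first occurrence, with a
  warning.
* In the lasso hierarchy $\beta_j^2$ is floored at 1e-12 before the
  inverse-Gaussian draw of $1/\tau_j^2$.
* All-zero genotype columns draw their effect from the prior and never
  touch the residual.
* Degenerate $R^2$ inputs (constant observed or predicted vectors) are
  errors, and degenerate bootstrap resamples are redrawn a bounded number
  of times.
* MCMC defaults are 20,000 iterations, 5,000 burn-in, thinning 5;
  convergence is monitored with an initial-positive-sequence effective
  sample size and a Geweke-style first/last segment z-statistic.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen as the package's own study conditions: variance-component recovery
on 500 subjects; ridge-sampler recovery on 300 subjects × 30 causal
markers with 10,000 iterations; and the directional model-roster
comparison on cohorts of 150 subjects × 60 markers (18 causal / 42 null,
preserving the ~0.4 markers-per-subject ratio and ~30% causal share of the
emulated study) over 8 simulation replicates with 1,000-iteration samplers
inside each CV fold. The acceptance script reports, among other things, the
full-roster cross-validated $R^2$ and $\Delta R^2$ on one such cohort.

## Known limitations

* Only a single random intercept is supported — no random slopes, crossed
  designs, or non-Gaussian responses.
* The whole-genome samplers assume complete dosages; imputation is the
  caller's (or the CV builder's) responsibility.
* The package evaluates *predictive* accuracy of lipid levels; it does not
  model clinical endpoints, and its synthetic cohorts cannot stand in for
  real-data performance claims.
* The sequential "continually updated clinic database" setting that
  leave-one-subject-out CV emulates — refitting as each new patient
  arrives, possibly using the patient's own earlier visits — is out of
  scope; predictions here never use any observation of the predicted
  subject.
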