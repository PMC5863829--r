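---
title: "Methods: mediation of placental methylation effects on full-term low birth weight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mediation of placental methylation effects on full-term low birth weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placmed)
```

## The scientific question

Full-term low birth weight (FT-LBW; birth weight below 2500 g at
37–42 weeks of gestation) isolates intrauterine growth restriction from
prematurity.  One candidate mechanism runs through the placenta: DNA
methylation at placental CpG sites may impair trophoblast invasion and
interface development, which manifests as a smaller placental surface
area, which in turn restricts maternal–fetal transfer and raises the
odds of FT-LBW.  placmed implements the full analysis chain for this
hypothesis — EpiTYPER-style quality control of beta-value methylation
data, standardized-covariate association models, correlation-block
multiple-testing correction, and an imputation-based natural-effects
mediation engine — together with a synthetic-data generator whose known
causal structure makes every stage testable without access to any
study's individual-level data.

## The causal model

Write $z_x$ for standardized methylation at the exposure CpG (z-score
of the beta value), $z_m$ for standardized placental surface area, $Y$
for the FT-LBW indicator, and $C$ for the covariate vector (maternal
age, education, family income, environmental-tobacco-smoke exposure,
gestational age, newborn sex).  The working structural model is

$$z_m = \beta_1 z_x + \gamma_m' C + \varepsilon, \qquad
\operatorname{logit} P(Y = 1) = \theta_0 + \theta_1' z_x + \theta_2 z_m
+ \gamma_y' C .$$

Four fitted quantities drive the mediation logic:

* $\beta_1$ — the mediator path (SD of area per SD of methylation),
  from the adjusted linear model;
* $\theta_1$ — the total exposure log-OR, from the adjusted logistic
  model *without* the mediator;
* $\theta_1'$ — the direct-path log-OR, from the logistic model *with*
  the mediator;
* $\theta_2$ — the mediator log-OR from the same model.

Mediation is declared present when (a) $\beta_1$ is significant, (b)
$\theta_1$ is significant, (c) $\theta_2$ is significant, and (d)
$|\theta_1'| < |\theta_1|$ — a strict attenuation; losing significance
alone does not satisfy (d).  The indirect path is additionally tested
with the Sobel statistic
$z = \beta_1\theta_2 / \sqrt{\beta_1^2\,\mathrm{se}_{\theta_2}^2 +
\theta_2^2\,\mathrm{se}_{\beta_1}^2}$.

### The natural-effects estimator

`fit_natural_effects()` decomposes the total odds ratio into natural
direct (NDE) and natural indirect (NIE) components by working-model
imputation:

1. fit the working logistic model
   $Y \sim z_x + z_m + C$;
2. replicate every subject once per offset in the counterfactual grid
   (default $\{0, -1\}$ SD), carrying `x_direct` $= z_x + \delta$ and
   `x_indirect` $= z_x$ while leaving the observed mediator untouched;
3. impute each replica's expected outcome from the working model
   evaluated at (`x_direct`, observed $z_m$, $C$);
4. fit the natural-effect logistic model of the imputed probabilities
   on `x_direct + x_indirect + C` (quasibinomial; every replica
   weighted equally);
5. report $\mathrm{NDE} = e^{\hat b_{\mathrm{direct}}}$,
   $\mathrm{NIE} = e^{\hat b_{\mathrm{indirect}}}$, and
   $\mathrm{TE} = \mathrm{NDE}\times\mathrm{NIE}$ — exact by
   construction, since coefficients add on the log scale.

The grid $\{0, -1\}$ makes both effects per-one-SD contrasts, matching
the "per SD increment" scale of the association models.  Imputation
uses expected outcome *probabilities* rather than resampled binary
outcomes so that point estimates are deterministic.  The proportion
mediated is computed on the log-OR scale,
$100\,\ln(\mathrm{NIE})/\ln(\mathrm{TE})$; with NDE $= 1.41$ and NIE
$= 1.38$ this evaluates to $48.38\%$, and `proportion_mediated(a, b) +
proportion_mediated(b, a) = 100` for every valid pair.

Confidence intervals come from a nonparametric bootstrap
(`bootstrap_mediation()`): subjects — never expanded replicas — are
resampled, the whole estimator is refit, and percentile intervals are
taken (default 1000 replicates; replicate failures are counted and
more than 10% aborts).  A sandwich-variance alternative would be a
reasonable future addition; the percentile bootstrap was chosen because
it is assumption-light and respects the OR scale.

Under a rare outcome the logistic model is approximately log-linear, so
the estimands have closed forms:
$\mathrm{NDE} \approx e^{\theta_1'}$,
$\mathrm{NIE} \approx e^{\beta_1\theta_2}$.  `true_effects()` exposes
these as the independent oracle that the simulation tests compare
against.  On a case-control sample the fitted ORs are interpretable as
population effects only under the same rare-outcome assumption; the
simulation-based validation therefore uses cohort sampling.

### Multiple testing across correlated CpGs

Nearby CpGs are correlated, so site-wise Bonferroni over five tests
would be conservative.  `correlation_blocks()` computes Pearson
correlations over pairwise-complete observations and groups CpGs by
single linkage at $|r| \ge 0.30$: correlation blocks are connected
components of the threshold graph, which reproduces transitive "block"
reasoning.  With the five valid CpGs falling into two blocks (CpG 2
with CpG 3.4 at $r = 0.66$; CpG 5, 7 and 11 at $r = 0.36$–$0.52$;
cross-block $|r| < 0.30$), `bonferroni_threshold(0.05, partition)`
yields the discovery threshold $0.05/2 = 0.025$.  Pearson (rather than
Spearman) correlation and single linkage are package choices; the
underlying block logic is not sensitive to them at these correlation
levels.  Inside the mediation condition checks the conventional
$\alpha = 0.05$ applies — the 0.025 threshold governs which CpG–stratum
combinations are carried into mediation at all, mirroring the two-tier
usage of the original analysis.

## Quality control of EpiTYPER-style beta values

The assay reports, per sample and CpG unit, a methylation fraction
$\beta \in [0, 1]$.  QC proceeds per CpG, in the order the rules are
stated:

* **Fragment aggregation.**  Mass-overlapping fragments cannot be
  resolved; their composite unit (here "CpG 3.4" from the CpG 3 and
  CpG 4 fragments) is the unweighted mean of the member readouts and is
  missing whenever any member is missing.  Which CpGs are measurable at
  all (e.g. the exclusion of CpG 13 for excessive fragment mass) is
  taken as given through the fragment map, not re-derived.
* **Poor readouts.**  A missing beta is flagged `removed_missing`.  No
  spectrum-level information exists in this artifact, so "poor
  readout" is operationalized as missingness.
* **Detection-limit censoring.**  Readouts *strictly* below 0.05 or
  strictly above 0.95 are flagged `removed_censored`; the boundary
  values themselves are retained, reading the rule's "lower than /
  higher than" literally.
* **CpG retention.**  A CpG is kept when its valid fraction is at
  least 0.75.  The denominator is the number of samples assayed for
  that CpG (per-CpG coverage differs in practice); it is configurable.
* **Plate controls.**  Each plate carries one re-assayed sample and one
  bisulfite conversion control.  A repeat pair differing by $\ge 0.05$
  or a conversion efficiency $\le 0.98$ flags the plate.  Failing
  plates are reported but not dropped by default (a concordance failure
  warrants inspection, not silent deletion); `strict = TRUE` drops
  them before counting.

The per-CpG report satisfies the conservation identity
`input = removed_missing + removed_censored + valid` exactly, readout
filtering is idempotent, and whether poor-readout removal precedes or
follows censoring cannot change the final valid set under these
semantics (a missing value can never be censored and vice versa).

## The synthetic cohort generator

`generate_cohort()` draws mother–baby pairs with a fully known causal
structure, and `generate_epityper_plates()` overlays the measurement
process.  Defaults encode the study conditions the package is
validated against:

* **Design.**  86 cases / 79 controls can be imitated through
  `design = "case_control"`; validation simulations use cohort
  sampling (`n_subjects` up to $10^5$) because the OR-scale mediation
  formulas are derived for rare outcomes.  Girls make up 58.8% of
  subjects, matching the observed sex split.
* **Methylation.**  Five CpG units in two correlation blocks
  (within-block $r$ of 0.66 and 0.44, between 0.15), with beta-scale
  means 0.36, 0.365, 0.48, 0.185, 0.37 and SDs 0.21, 0.08, 0.13, 0.12,
  0.10 — the pooled case/control values of the observed cohort.  The
  cohort table stores *latent* (unclipped) beta values so that these
  marginal moments are exactly calibrated; clipping to $[0,1]$ happens
  at the assay stage, where the detection-limit filter removes the
  censored tail anyway.
* **Paths.**  `theta1_prime = 0.3436`, `theta2 = -0.8440`,
  `beta1 = -0.3816` — the calibration at which the closed forms give
  $\mathrm{NDE} = e^{0.3436} = 1.41$ and
  $\mathrm{NIE} = e^{0.3221} = 1.38$, the girls-stratum decomposition
  the package reproduces.  `girls_only_effect = TRUE` restricts both
  exposure paths to girls, emulating the sex-specific finding.
* **Prevalence.**  The outcome intercept $-3.4$ was chosen by the
  probit-style approximation
  $E[\operatorname{expit}(b_0 + \eta)] \approx
  \operatorname{expit}(b_0 / \sqrt{1 + 0.346\,\sigma_\eta^2})$ with
  $\sigma_\eta^2 \approx 1.1$, targeting the ~5% cohort prevalence at
  which rare-outcome reasoning holds; the realized prevalence at
  $n = 10^5$ is 4.95%.
* **Mediator scale.**  The mediator residual SD defaults to
  $\sqrt{1 - \beta_1^2 - \mathrm{var}(\text{covariate terms})}$ so the
  latent standardized area has variance $\approx 1$; re-standardizing
  the observed area in analysis is then effect-preserving.  The area
  is assumed Normal on the standardized scale (its true distribution
  is not identified by the published summaries), mapped to cm² with
  mean 275 and SD 55 (between the case and control group means), and
  decomposed into axes by drawing an aspect ratio around 1.08 (the
  observed major/minor ratio) and inverting the ellipse formula
  $A = \text{major} \times \text{minor} \times \pi/4$.  Axes are
  rounded to 0.1 cm and the recorded area recomputed from the rounded
  axes, so the ellipse identity holds exactly in the output.
* **Covariates.**  Education (college or above, 41%), low family
  income (55%), ETS exposure (30%), alcohol use (4.2%), primiparity
  (73%) as Bernoulli draws matching the observed dichotomies; maternal
  age truncated-Normal(28, 5) on [18, 45]; gestational age
  truncated-Normal(38.03, 0.97) on [37, 42].  Covariates act on
  mediator and outcome but not on methylation, so they are precision
  variables rather than exposure confounders; the adjusted models
  handle either case.
* **Draw order.**  Randomness is consumed in a fixed documented order
  (covariates column by column, methylation matrix, mediator residual,
  outcome uniforms, aspect ratio, weight noise), one draw per subject
  per step, so a seed fully determines the table and remains portable
  across parameter settings.
* **Matching.**  The original pairs were individually matched on
  gestational age, BMI, parity and sex, but the published models are
  unconditional logistic regressions with covariate adjustment; the
  generator therefore does not construct matched pairs.  Whether
  matching induced residual correlation that unconditional models
  ignore cannot be determined from published information and is out of
  scope.

The assay layer adds per-readout Normal noise (default SD 0.01 beta
units), missingness (5%), and explicit detection-limit censoring
injections (2% low, 0.5% high) recorded in an event ledger, so QC
tests can verify exact recovery of every injected event.  Plates
alternate case and control samples (half/half as far as the group sizes
allow), carry one repeated sample and one conversion-control entry
each, and conversion efficiencies are drawn from [0.985, 0.999].

**What the generator does not emulate:** Sequenom mass spectra and
peak calling, bisulfite chemistry, genotype-driven methylation (mQTL)
effects, placental cell-type composition, and matched-pair sampling.
Passing tests therefore demonstrate that the statistical machinery is
correct under the stated generative model — not that the substantive
findings would replicate in new placental cohorts.

## Numerical choices

* Standardization uses the sample mean and SD over all QC-valid values
  of a variable (within stratum, when stratified) *before*
  model-specific complete-case restriction; per-model standardization
  is available through explicit `center`/`scale` arguments.
  Complete cases are taken per model with no imputation, so per-CpG
  sample sizes differ, as they should.
* Logistic fits are maximum likelihood via IRLS with relative deviance
  tolerance $10^{-8}$ and at most 100 iterations; inference is Wald
  (observed information), giving symmetric CIs on the log-OR scale.
  (Whether the original p-values were Wald or likelihood-ratio is not
  stated; Wald matches the symmetric printed intervals.)
* Separation is detected by an implausible coefficient magnitude
  ($|\log \mathrm{OR}| > 15$ for standardized/binary predictors) or
  the fitter's numerical 0/1 warning, and raises a diagnostic error
  naming the term; constant predictors and rank-deficient designs
  error before fitting.
* Degenerate inputs: a constant series cannot be standardized; an
  empty counterfactual grid, an empty block partition, and a total
  effect OR of exactly 1 (undefined proportion mediated) are errors,
  not silent `NA`s.  `n_subjects = 0` yields an empty, well-typed
  table.
* `fit_natural_effects()` checks (loosely) that exposure and mediator
  look standardized and refuses otherwise; bootstrap refits skip the
  check because resampled z-scores drift slightly by construction.

## Validation problem sizes

The test suite validates parameter recovery at the scales where
Monte-Carlo error is informative rather than dominant: natural-effects
recovery on 20 cohorts of $n = 100{,}000$ (median NDE/NIE against the
closed forms), mediator-path recovery ($\beta_1 = -0.18$) on 20 cohorts
of $n = 20{,}000$ judged within 3 standard errors, marginal calibration
at $n = 50{,}000$ within 3 Monte-Carlo SEs, null calibration of the
association scan (~5% of p-values below 0.05 across 30 null cohorts),
and bootstrap-interval coverage of the null NIE across repeated
simulations.  Determinism is asserted byte-for-byte: identical
parameters and seeds reproduce identical cohorts, bootstrap intervals,
and pipeline artifacts.

## Known limitations

* The OR-scale decomposition and its closed-form oracle rely on the
  rare-outcome approximation; at prevalences well above ~10% the NIE
  and NDE drift from $e^{\beta_1\theta_2}$ and $e^{\theta_1'}$ by
  non-collapsibility, and `true_effects()` warns.
* Exposure–mediator interactions, multiple mediators, and
  weighting-based natural-effect estimators are out of scope; the
  estimator assumes the working model is correctly specified.
* Latent methylation columns in the cohort table may fall slightly
  outside $[0,1]$ for low-mean CpGs; they model propensities, and only
  the assay layer produces bounded observable betas.
* Conditional logistic regression for the matched design is
  deliberately not provided, matching the published unconditional
  analysis.
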