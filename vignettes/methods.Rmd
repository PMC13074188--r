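---
title: "Models and methods behind dtathresh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dtathresh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtathresh)
```

# The problem

Quantitative biomarkers read against a positivity cutoff — the motivating case
is cerebrospinal-fluid heparin-binding protein (HBP, in ng/mL) for
healthcare-associated ventriculitis and meningitis (HAVM) — are evaluated in
small single-center studies that each report one 2x2 table (TP/FP/FN/TN) at
their own cutoff. Meta-analysis of such studies has to deal with two coupled
problems: accuracy pairs are correlated across studies (a *threshold effect*:
a study using a higher cutoff trades sensitivity for specificity), and the
clinically useful output is not a pooled accuracy pair but *decision
thresholds* — concentrations at which the test result should change
management. `dtathresh` implements the full chain: bivariate random-effects
pooling, heterogeneity and threshold-effect diagnostics, summary ROC geometry,
subgroup and metaregression analysis, Fagan post-test updating, Deeks'
small-study test, and a multiple-cutoff model yielding Youden-optimal and
likelihood-ratio-based rule-in/rule-out thresholds.

# The bivariate logit-normal model

For study $i$ let $y_{1i} = \mathrm{logit}(\widehat{\mathrm{sens}}_i)$ and
$y_{2i} = \mathrm{logit}(\widehat{\mathrm{FPR}}_i)$ with delta-method
within-study variances $v_{1i} = 1/\mathrm{TP}_i + 1/\mathrm{FN}_i$ and
$v_{2i} = 1/\mathrm{FP}_i + 1/\mathrm{TN}_i$. The model is

$$\begin{pmatrix} y_{1i} \\ y_{2i} \end{pmatrix}
\sim N\!\left( \mu,\; \Sigma + C_i \right), \qquad
\Sigma = \begin{pmatrix} \tau_1^2 & \rho\tau_1\tau_2 \\
\rho\tau_1\tau_2 & \tau_2^2 \end{pmatrix},\quad
C_i = \mathrm{diag}(v_{1i}, v_{2i}).$$

The two arms of a study are independent, so $C_i$ is diagonal — the standard
assumption. $\Sigma$ is estimated by restricted maximum likelihood; at any
candidate $\Sigma$ the fixed effects are profiled out by generalized least
squares, so the optimization runs over three parameters only. Pooled
sensitivity is $\mathrm{expit}(\mu_1)$, pooled specificity
$1 - \mathrm{expit}(\mu_2)$, and the between-study correlation $\rho$ is the
threshold-effect diagnostic (a magnitude near 1 indicates that cutoff
variation drives the heterogeneity). Because the literature states this
correlation in both conventions, `threshold_correlation()` reports the
sens-vs-FPR value with the sens-vs-specificity value (its negative) attached;
tests and reports compare magnitudes.

## Numerical choices

* **Parameterization.** The optimizer works on
  $(\log\tau_1, \log\tau_2, \operatorname{atanh}\rho)$, which enforces
  $\tau_j > 0$ and $|\rho| < 1$ smoothly. REML surfaces for a dozen studies
  are frequently multimodal near the boundary, so the fit uses five
  deterministic starting points plus five seeded random ones (Nelder-Mead,
  relative tolerance $10^{-12}$, best optimum polished once). The random-start
  seed is kept separate from the user's RNG stream. An exhaustive grid search
  at resolution 0.01 in $(\tau_1, \tau_2, \rho)$ confirms the optimizer in the
  test suite, and the profiled restricted log-likelihood is checked against an
  independent mixed-model implementation (`metafor::rma.mv`) at fixed variance
  components.
* **Boundary behavior.** $\tau_j < 10^{-4}$ is reported as a boundary fit;
  the between-study correlation is then undefined and returned as `NA` with a
  warning rather than a number.
* **Continuity correction.** Any study containing a zero cell has 0.5 added to
  all four cells (the mainstream convention; configurable to
  `only-zero-cells`, `always` or `none`). Raw integer counts are never
  mutated; corrected counts live in separate columns. One rationale: datasets
  in this literature contain studies with specificity 1.000, whose logit is
  infinite without correction.
* **Confidence intervals.** Intervals for pooled sensitivity and specificity
  are Wald intervals on the logit scale. The quantile uses a $t$ distribution
  with $k-2$ degrees of freedom by default: normal-quantile Wald intervals
  are known to undercover in the few-studies regime because they ignore the
  uncertainty of the variance components, and the $t(k-2)$ choice is the
  Knapp-Hartung-style small-sample practice. The shipped calibration check
  (200 replicate 12-study datasets) verifies that coverage of the default
  intervals lands inside [90%, 99%]. `df = Inf` restores the normal-quantile
  convention used by most published analyses; point estimates are identical
  either way. LR+, LR- and DOR intervals are percentile intervals
  from 100{,}000 Monte-Carlo draws of the fixed effects
  $N(\hat\mu, \widehat{\mathrm{cov}})$, with the seed recorded in every
  output; point estimates are derived from the pooled accuracy pair, so
  $\mathrm{DOR} = \mathrm{LR}^+/\mathrm{LR}^-$ holds as an identity.
* **Heterogeneity.** Cochran's $Q$ and $I^2$ are computed per component on the
  logit scale with inverse-variance weights and are labelled *descriptive*:
  the hierarchical model, not $I^2$, is the primary account of between-study
  variability.

# Summary ROC geometry

The SROC curve is the conditional-expectation line on the logit scale,
$\mathrm{logit\,TPR}(f) = \mu_1 + (\sigma_{12}/\sigma_{22})(f - \mu_2)$,
mapped through the inverse logit and truncated by default to the observed FPR
range (an extrapolation flag widens it). This is the common default for this
model family; the source analyses do not state a curve variant, and other
parameterizations (e.g. HSROC) are out of scope. Confidence and prediction
regions are chi-square(2) ellipses on the logit scale around $\hat\mu$ with
shape matrices $\widehat{\mathrm{cov}}(\hat\mu)$ and
$\widehat{\mathrm{cov}}(\hat\mu) + \hat\Sigma$ respectively, discretized at
360 vertices; the inverse logit is monotone per coordinate, so containment of
the confidence region in the prediction region survives the mapping.

# Subgroups and metaregression

Subgroup analysis fits an independent bivariate model per level of a
categorical study-level variable; levels with fewer than three studies are
skipped with a reason instead of being force-fitted. Metaregression adds the
covariate to *both* mean components (a binary covariate costs 2 degrees of
freedom) and compares against the intercept-only model by a likelihood-ratio
test. Both models in the comparison are refitted by ordinary maximum
likelihood, not REML — REML log-likelihoods are not comparable across
fixed-effect structures. This is the statistically defensible choice and may
produce small p-value differences against software that tests on the REML
scale. Missing covariate values become their own level (`"unreported"`)
rather than dropping studies.

# Clinical utility

`post_test_probability()` is the Fagan-nomogram update
$\mathrm{odds}_{post} = \mathrm{odds}_{pre}\cdot LR$. Display percentages
round *half-up* to the whole percent (R's default half-to-even rounding would
disagree with printed clinical tables). Deeks' test regresses
$\ln \mathrm{DOR}_i$ on $1/\sqrt{\mathrm{ESS}_i}$ with weights
$\mathrm{ESS}_i = 4 n_{1i} n_{2i}/(n_{1i}+n_{2i})$ and tests the slope with a
two-sided $t$ on $k-2$ df (the conventional small-sample choice), flagging
asymmetry at $p < 0.10$, the customary level for this test.

# The multiple-cutoff model

Across studies with explicit cutoffs $c_i$, the two group-specific CDFs at the
cutoff are modelled on the logit scale as linear in a transform $f$:

$$\mathrm{logit}(1-\mathrm{sens}_i) = a_d + b_d f(c_i), \qquad
\mathrm{logit}(\mathrm{spec}_i) = a_{nd} + b_{nd} f(c_i),$$

fitted by weighted least squares with the respective group sample sizes as
weights (inverse-variance and equal weighting are options; sample-size
weighting follows the cited method family). $f$ is chosen among identity, log
and square root by the combined AIC of the joint two-line weighted Gaussian
likelihood (six parameters); ties break toward log, because concentrations
live on a positive multiplicative scale. With one cutoff per study — all this
corpus supports — study-level random effects are not identifiable, so the
model is fixed-effects WLS; multi-cutoff extensions would require a
random-intercept variant that is deliberately not offered on such data.

From the fitted lines, accuracy, Youden index
$J(c) = \mathrm{sens}(c) + \mathrm{spec}(c) - 1$ and LR curves are continuous
in $c$. The Youden optimum is located on a 2001-point grid over the evaluation
range with golden-section refinement; its uncertainty comes from a cluster
bootstrap (resample studies with replacement, refit the selected transform,
B = 1000, seeded; failed refits are dropped and counted, with an instability
warning beyond 20%). Rule-in and rule-out thresholds are the crossings of
$LR^+(c)$ with 10 and $LR^-(c)$ with 0.1, found by bracketing plus root
refinement; multiple crossings resolve to the one nearest the Youden optimum
(with the multiplicity reported), and a target not met anywhere on the grid is
reported as *not achieved* — never extrapolated into a number. The evaluation
range is $[0.5\,c_{\min},\, 1.2\,c_{\max}]$ of the observed cutoffs:
published analyses of this kind report boundary LR extrema outside the
observed cutoff range, so a modest extension is the default, with points
outside the observed range flagged as extrapolated.

# The synthetic-data generator

No per-study data can be redistributed with the package, so validation runs on
a generator that emulates the structure of the HAVM/HBP evidence base: $k=12$
single-center studies, total sizes uniform on 58-390, common prevalence
$841/1761 \approx 0.478$, per-study cutoffs log-uniform on 14.96-92.5 ng/mL
with two studies masking their cutoff. Within each study the biomarker is
log-normal: $\log X \sim N(\mu_d + \delta_{di}, \sigma_d^2)$ in diseased and
$N(\mu_{nd} + \delta_{ndi}, \sigma_{nd}^2)$ in non-diseased subjects, with
study shifts $(\delta_{di}, \delta_{ndi})$ bivariate normal. True accuracy at
any cutoff is a pair of normal CDFs, giving closed-form oracles for every
downstream stage, and the same mechanism exercises both the bivariate model
(through the shifts) and the cutoff model (through the cutoff spread).

Calibration, fixed once:

* $\sigma_d = \sigma_{nd} = 1.3$ log-units — an order-of-magnitude
  within-group spread, typical for infection biomarkers;
* $\mu_d, \mu_{nd}$ anchored so that at 30 ng/mL population sensitivity is
  0.861 and specificity 0.848, the published pooled values. With
  $\sigma = 1.3$ this implies group medians of about 122 and 7.8 ng/mL,
  consistent with reported HBP levels in infected and non-infected
  postneurosurgical patients;
* $\tau_d = \tau_{nd} = 0.5$ with shift correlation 0.8. A delta-method
  calculation (cutoff-induced slopes of both logit outcomes in $\ln c$, plus
  correlated shifts) puts the induced between-study logit correlation
  magnitude near 0.9, matching the strong threshold effect the evidence base
  shows ($|\rho| \approx 0.92$), and the induced $I^2$ values in the 85-95%
  range.

What the generator does **not** emulate: per-study prevalence variation (a
common prevalence is used), assay-platform shifts, two-gate spectrum bias, and
outlier studies with specificity exactly 1. Passing tests therefore show that
the estimators recover the truth of *this* mechanism, not that any particular
published number is correct.

One structural point is worth stating plainly: the published bivariate pooled
pair (0.861, 0.848; $J = 0.709$) and the published cutoff-model accuracy at
the Youden optimum (0.905, 0.929; $J = 0.834$) cannot both arise from a single
coherent log-normal truth — they come from two different models fitted to the
same studies. The generator is anchored to the pooled pair, so its population
LR curves are shallower than the published cutoff-model curves: solving the
closed-form curves from `true_accuracy()` at the default calibration puts the
population Youden optimum at 31.1 ng/mL and the rule-out and rule-in
crossings near 18.9 and 51.3 ng/mL, rather than 28.4 / 30.1 / 41.3, and
replicate-averaged pipeline outputs inherit that gap. This is a property of
the anchoring choice, not an estimation failure; the cutoff-model recovery
tests use data generated from the two-line model itself, where the transform,
optimum and threshold ordering are recovered cleanly.

# Problem sizes used in validation

The shipped checks use: an exhaustive $(\tau_1, \tau_2, \rho)$ grid at 0.01
resolution on a fixed 6-study dataset; 200 replicate 12-study datasets for
parameter-recovery and CI-coverage calibration (direct draws from the
bivariate model at $\mu = (\mathrm{logit}\,0.861, \mathrm{logit}\,0.152)$,
$\tau = (0.7, 1.2)$, $\rho = -0.92$); 200 replicates of a well-powered
two-line design (12 studies, 500 per arm, cutoffs log-uniform on 10-100
ng/mL, slopes 1.4 per log-unit) for transform selection and threshold
ordering — the wide, well-powered design is what makes log-vs-sqrt
discrimination a fair test over a ~6-fold cutoff range; and 2000 replicates
for the type-I error of Deeks' test. The acceptance script averages the
pipeline over 40 replicate 12-study datasets so that reported values reflect
the method under the study conditions rather than a single draw.

# Known limitations

* With ~12 studies the bivariate model sits near the lower edge of stability;
  $\rho$ estimates frequently reach the boundary and should be read as
  qualitative evidence of a threshold effect.
* The metaregression LRT relies on the chi-square reference; with k this
  small its size is approximate (the shipped calibration keeps it near
  nominal but it is anticonservative in the tails).
* The cutoff model treats the reported study cutoff as exact and ignores
  assay-platform differences in concentration scale.
* Bootstrap intervals for the Youden optimum are percentile intervals; with
  10 cutoff-bearing studies they are wide and occasionally unstable, which the
  report flags rather than hides.
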