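---
title: "Methods: brain-age modelling and random-effects meta-analysis with brainpad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-age modelling and random-effects meta-analysis with brainpad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`brainpad` implements the complete analytic workflow of a multi-cohort,
consortium-style case-control brain-ageing study:

1. **Brain-age prediction.** Sex-stratified ridge-regression models map 77
   regional structural MRI features (hemisphere-averaged cortical thickness,
   surface area, subcortical volumes, lateral ventricle volume and ICV) to
   chronological age, trained on healthy adults only.
2. **Brain-PAD.** The brain-predicted age difference, predicted minus
   chronological age in years, is the per-subject outcome; positive values
   mean an "older-looking" brain.
3. **Per-cohort inference.** Within each cohort, ordinary least squares
   relates brain-PAD to diagnosis (with sex, age, age$^2$ and scanner-site
   covariates), and - within patients - to clinical characteristics (with
   age and age$^2$).
4. **Evidence synthesis.** Per-cohort coefficients are pooled by a
   restricted-maximum-likelihood (REML) random-effects meta-analysis with
   inverse-variance weights, heterogeneity statistics (Cochran's $Q$,
   $I^2$), single-moderator meta-regressions, and Benjamini-Hochberg FDR
   control over the family of clinical tests.
5. **Feature importance.** Structure coefficients - Pearson correlations
   between predicted age and each input feature, sample-size-weighted
   across cohorts - summarise which feature classes drive the prediction.

Because consortium MRI data cannot be redistributed, the package ships a
synthetic consortium generator whose defaults emulate the demographic and
clinical structure of a large schizophrenia case-control consortium
(26 cohorts, one patients-only; cohort sizes in the tens to low hundreds;
case cohorts about two-thirds male; onset mid-20s; mostly atypical
antipsychotic use). Every stage of the pipeline is exercised and tested
against this generator.

# The synthetic consortium generator

## Feature model

Each of the 77 averaged features $j$ of subject $i$ is generated as

$$x_{ij} = b_j + s_j\,(a_i - 45) + q_j\,(a_i - 45)^2 +
  \gamma_j\,\mathrm{male}_i + u_{s(i),j} + \varepsilon_{ij},$$

where $b_j$, $s_j$ are class-level baselines and ageing slopes scaled by
fixed per-feature multipliers, $q_j$ is a mild quadratic term (lateral
ventricles only), $\gamma_j$ a male offset, $u_{s(i),j} \sim N(0,
\sigma^2_{\mathrm{site}})$ a site effect drawn once per site, and
$\varepsilon_{ij} \sim N(0, \sigma^2_{\mathrm{resid}})$ independent
residual noise. Cortical thickness, surface area and subcortical volumes
shrink with age; ventricles expand; ICV is age-flat and carries only a sex
offset. Class defaults (thickness 2.5 mm baseline, $-0.005$ mm/yr, residual
SD 0.12 mm; area 2500 mm$^2$, $-2.5$ mm$^2$/yr, SD 145; subcortical
3800 mm$^3$, $-8$ mm$^3$/yr, SD 300; ventricle 7000 mm$^3$, $+60$
mm$^3$/yr plus quadratic, SD 2500; ICV sex offset $+10\%$) were chosen so
that the standardized age signal is ordered thickness > subcortical >
area - the class ordering structural brain-age models typically show -
and are generator calibration choices, not empirical facts.

Hemisphere pairs are emitted as $b_{ij} \pm d_{ij}$ around the averaged
value, so `average_hemispheres()` recovers the modelled 77-feature signal
exactly while left and right still differ realistically.

## The ageing offset and why subject jitter is large

The key generative quantity is an *effective brain age*
$a_i = \mathrm{age}_i + \delta_i$. Healthy subjects draw
$\delta_i \sim N(0, \sigma_\delta^2)$; cases add a cohort-level offset
$\Delta_c \sim N(\Delta, \tau^2)$ (defaults $\Delta = 3.55$,
$\tau = 1.5$ years), i.e. case brains are shifted $\Delta_c$ years along
every feature's ageing trajectory. This makes "the injected effect" a
well-defined recovery target: the expected brain-PAD difference is
$g \cdot \Delta$, where the calibration gain $g$ is the slope of predicted
on true age in controls (measurable within the pipeline, typically around
0.75 under the defaults).

The default subject jitter is $\sigma_\delta = 8$ years. This is a
deliberate calibration: with many informative features, a ridge model
averages away *independent* feature noise almost entirely, so tiny jitter
would yield implausibly accurate prediction (control $r$ near 0.97, MAE
near 3 years). Variation shared across features *along the ageing
gradient* is the one noise source the multivariable model cannot remove -
and it is exactly what "biological brain age differs from chronological
age" means. At $\sigma_\delta = 8$ the default consortium lands in the
regime large ROI-based brain-age studies report: control MAE around 6-8
years, control $r$ around 0.55-0.65, within-group brain-PAD SD around 8
years, and a case-control difference of $d \approx 0.4$ with moderate
between-cohort heterogeneity ($I^2$ around 50-70%).

Clinical variables (onset, duration = age $-$ onset, PANSS/SANS/SAPS,
antipsychotic class, CPZ-equivalent dose, handedness) are drawn from
plausible marginal distributions *independently of the brain* by default,
so the default consortium is a faithful null for the clinical analyses; an
optional `clinical_effect` injects a true slope for recovery studies. Ages
are uniform within each cohort's window (only means and ranges of real
consortia are typically published). One cohort defaults to patients-only
and one to 100% male, to exercise the eligibility logic.

## What the generator does not emulate

Real multi-site data have scanner-specific covariance structure, non-Gaussian
and heavy-tailed features, segmentation failures, age-dependent recruitment,
and diagnosis effects that are regionally specific rather than a uniform
shift along the ageing gradient. Passing tests therefore demonstrate the
*statistical machinery* - estimator correctness, calibration, recovery of
injected truth - not that any particular clinical effect size would
replicate in real data.

# Brain-age models

Features are standardized by training means/SDs; coefficients minimise
$\lVert y - X\beta \rVert^2 + \alpha \lVert \beta \rVert^2$, computed in
closed form from the SVD of the standardized design (no iterative fitting;
predictions are invariant to affine rescaling of any input feature). The
penalty $\alpha$ is selected by internal 10-fold cross-validation over a
log-spaced grid $10^{-3}$-$10^5$ (minimum MSE, ties to the smaller
$\alpha$, fold assignment seeded and recorded). Models are trained per sex
on healthy subjects only - by default 952 males and 1236 females aged
18-75 - and applied per sex to each test cohort, after which predictions
are pooled within cohort for the brain-PAD analyses.

Performance is summarised as MAE (years), Pearson $r$ between predicted
and chronological age, and $R^2$ defined as $r^2$. The squared-correlation
definition is used deliberately: out-of-sample $1 - \mathrm{SSE}/\mathrm{SST}$
can go negative and does not match how generalization $R^2$ is reported in
this literature. Cohort-level metrics are aggregated by sample-size-weighted
means; the standard error of a weighted mean is taken as the weighted
(population) SD across cohorts divided by $\sqrt{k}$, a pragmatic choice
since no standard formula exists for this quantity.

# Per-cohort linear models

The diagnosis model regresses pooled brain-PAD on a diagnosis indicator
(healthy controls as reference), sex (female reference), age, age$^2$ and,
in multi-site cohorts, $n_{\mathrm{sites}} - 1$ site dummies (first site
lexicographically as reference). Age and age$^2$ covariates absorb the
systematic age bias of brain-age prediction (regression to the mean makes
raw brain-PAD negatively age-dependent). Age is centred within cohort
before squaring to limit collinearity; the diagnosis coefficient is
invariant to this reparameterization. Two-sided p-values use the t
distribution with residual degrees of freedom. Cohen's $d$ for the
diagnosis term uses the covariate-adjusted conversion
$d = t\,(n_1 + n_2) / (\sqrt{n_1 n_2}\,\sqrt{\mathrm{df}})$ with sampling
variance $(n_1 + n_2)/(n_1 n_2) + d^2 / (2(n_1 + n_2))$.

Clinical models within patients regress brain-PAD on one characteristic
plus age and age$^2$, complete cases per characteristic (real consortium
tables show varying Ns per variable, implying the same). Site dummies are
included for multi-site cohorts by default (`use_site_in_clinical`), a
package choice since published descriptions leave this open. Antipsychotic
class is analysed as three pairwise contrasts - atypical, typical and both
versus unmedicated - each fitted on the subset of patients in the two
classes involved, so a thin subgroup drops only its own contrast.

**Eligibility.** A cohort enters the case-control analysis only with at
least 10 healthy controls. Any *non-empty* predictor or covariate subgroup
with fewer than 5 members excludes the cohort from that analysis; an
*empty* subgroup (e.g. a single-sex cohort) instead drops the term, since
a constant column identifies nothing and the model remains estimable.
Sensitivity mode additionally drops cohorts whose control-group
generalization is poor (MAE > 10 years or $R^2 < 0.1$) and re-pools the
diagnosis effect, reporting both estimates side by side.

# The meta-analysis engine

Per-cohort effects $y_i$ with sampling variances $v_i$ follow
$y_i = \mathbf{x}_i'\boldsymbol\beta + u_i + e_i$ with
$u_i \sim N(0, \tau^2)$, $e_i \sim N(0, v_i)$. $\tau^2$ maximises the
restricted log-likelihood

$$\ell_R(\tau^2) = -\tfrac12\Big[\textstyle\sum_i \log(v_i + \tau^2) +
  \log\lvert X'WX\rvert + y'Py\Big],$$

via Fisher scoring (score $\tfrac12(y'PPy - \mathrm{tr}\,P)$, expected
information $\tfrac12\mathrm{tr}\,P^2$), with iterates truncated at zero,
step-halving to keep $\ell_R$ monotone, convergence at $|\Delta\tau^2| <
10^{-8}$ (or likelihood stagnation), and a bisection fallback on the score
for pathologically flat likelihoods. The implementation is validated in the
test suite against a brute-force grid/golden-section maximiser of
$\ell_R$, against the exact two-study closed form
$\hat\tau^2 = \max(0, ((y_1 - y_2)^2 - v_1 - v_2)/2)$, and against an
independent reference implementation.

Pooling uses $w_i = 1/(v_i + \hat\tau^2)$: $\hat b = \sum w_i y_i / \sum
w_i$, $\mathrm{se} = (\sum w_i)^{-1/2}$, Wald $z$ tests and Normal 95%
CIs (the reference default in this literature; Knapp-Hartung adjustment is
out of scope). Cochran's $Q$ is computed at fixed-effect weights against
the (moderator-adjusted, when present) weighted fit. $I^2$ uses the
$\tau^2$-based definition $100\,\tau^2/(\tau^2 + s^2)$ with Higgins'
typical sampling variance $s^2 = (k-1)\sum w_i^{(0)} /
\big[(\sum w_i^{(0)})^2 - \sum (w_i^{(0)})^2\big]$, $w_i^{(0)} = 1/v_i$ -
not the $(Q - \mathrm{df})/Q$ form, which is inconsistent with the
$\tau^2$ actually estimated by REML.

Meta-regressions take one moderator at a time (single- vs multi-site
status, field strength 1.5 T vs 3 T, cohort mean age, percent female),
matching the post-hoc one-at-a-time design such analyses use; the omnibus
moderator test is the 1-df Wald chi-square $Q_M$, and heterogeneity
accounted for is $R^2 = 100 \cdot \max(0, (\tau^2_{\mathrm{null}} -
\tau^2_{\mathrm{mod}})/\tau^2_{\mathrm{null}})$. Moderators act on the
year-scale effects; the year-scale and $d$-scale diagnosis meta-analyses
are run in parallel from the same cohort fits.

The nine clinical tests (onset, duration, PANSS total, SANS global, SAPS
global, three antipsychotic contrasts, CPZ dose) form one FDR family,
adjusted by a self-implemented Benjamini-Hochberg step-up (validated
against the brute-force definition $\min_{i \ge j} n\,p_{(i)}/i$ and
against `p.adjust`).

# Structure coefficients

Within each cohort and diagnosis group (at least 3 subjects, non-zero
variance), Pearson correlations between *predicted age* (not brain-PAD)
and each of the 77 features are computed, then averaged across cohorts
weighted by group-specific sample size - plain averaging of coefficients,
with Fisher-$z$ averaging available behind a flag for comparison. Class
summaries report the mean and SD of the weighted feature correlations
within thickness, area and subcortical classes; ventricle and ICV are
reported individually. Under the defaults the expected pattern is a
positive ventricle correlation, negative correlations everywhere else, and
class magnitudes ordered thickness > subcortical > area.

# Numerical and design choices

- Ridge via SVD; penalty grid $10^{-3}$-$10^5$ (9 points); CV ties broken
  toward the smaller penalty; constant training features are an error.
- Rank-deficient cohort designs (e.g. site confounded with diagnosis) are a
  hard error naming the collinear columns; degenerate subgroups drop terms
  or cohorts as described above.
- Zero-variance features in outlier flagging and structure coefficients
  are skipped with a warning, never silently imputed.
- $\tau^2$ truncated at zero; $R^2$ of meta-regression truncated at zero;
  $I^2$ bounded in $[0, 100]$ by construction.
- All randomness flows from explicit integer seeds: identical
  configuration and seed reproduce every table byte-identically.
- Reference levels: diagnosis HC, sex female, site first-lexicographic,
  antipsychotic "none"; these are arbitrary and recorded here.

**Problem sizes in the shipped tests.** The statistical checks run at
sizes chosen to make Monte-Carlo error small relative to the asserted
tolerances while keeping the default suite quick: oracle equivalence on 20
random meta instances ($k \le 8$); null calibration of the per-cohort
diagnosis test, pooled $z$, $Q$ and $Q_M$ at 2000 replicates each
(rejection within $5\% \pm 1.5\%$); parameter recovery on 100 consortia of
25 cohorts with $\Delta = 3.55$, $\tau = 1.5$ (CI coverage of $g\Delta$ at
$\ge 90\%$, median-unbiased $\hat\tau^2$); and the full default consortium
(26 cohorts, about 6000 subjects) for the qualitative structure-coefficient
pattern and end-to-end determinism.

# Limitations

- The generator's diagnosis effect is a uniform shift along the ageing
  gradient; regionally heterogeneous disease effects, scanner covariance
  and non-Gaussian tails are not modelled.
- $d$-scale pooling converts per-cohort t statistics; if a real analysis
  derived $d$ from the pooled year-scale estimate instead, small
  differences are expected.
- Wald-type meta CIs are slightly liberal at very small $k$; with the
  default 25 cohorts this is negligible (verified by the calibration
  tests).
- The eligibility reading of "fewer than 5 in a subgroup" distinguishes
  empty subgroups (term dropped) from thin ones (cohort excluded); other
  readings are possible where a published rule is not fully specified.
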