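---
title: "Assessing repeatability and reproducibility: models, simulations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing repeatability and reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhinorep)
```

## The model behind the ICC

All repeatability computation in this package rests on the two-level
random-effect model for a balanced table of $n$ subjects with $k$
replicate measurements,

$$X_{ij} = \mu + b_i + e_{ij}, \qquad b_i \sim N(0, \sigma_B^2), \quad
e_{ij} \sim N(0, \sigma_W^2),$$

under which the one-way random-effects, single-measurement intraclass
correlation is $ICC = \sigma_B^2 / (\sigma_B^2 + \sigma_W^2)$: the
fraction of total variance attributable to real differences between
subjects rather than measurement error. `anova_oneway()` estimates the
mean squares ($MSB = k \cdot \mathrm{var}(\text{row means})$, $MSW$ the
mean of per-subject sample variances), and `icc_oneway()` forms the
classical ANOVA estimator

$$\widehat{ICC} = \frac{MSB - MSW}{MSB + (k-1)\,MSW}.$$

We implement the one-way, single-rater form deliberately: repeated
measurements taken by one operator with one instrument within a visit
have no rater or occasion structure to model, and this is the form that
matches the variance-ratio definition above. Two-way and consistency
variants are out of scope.

Three numerical choices worth knowing:

* **Negative estimates are reported unclamped.** The method-of-moments
  component $\hat\sigma_B^2 = (MSB - MSW)/k$ can be negative in small
  samples; truncating at zero would bias every Monte-Carlo summary that
  averages estimates. The benchmark mapping sends any estimate at or
  below 0.20 to "poor", so interpretation is unaffected.
* **The null is not zero.** The test is $H_0: ICC \le \rho_0$ with
  default $\rho_0 = 0.20$, via
  $F = (MSB/MSW)(1-\rho_0)/(1+(k-1)\rho_0)$ on $(n-1, n(k-1))$ degrees of
  freedom; rejecting means at least "fair" agreement, not merely
  "non-zero correlation". With $\rho_0 = 0$ this reduces exactly to the
  one-way ANOVA F-test.
* **Benchmark edges are half-open.** The conventional verbal scale has a
  printed gap between "< 0.20" and "0.21–0.40"; we close it as
  $(0.20, 0.40]$, $(0.40, 0.60]$, $(0.60, 0.80]$, $(0.80, 1]$, so every
  value receives exactly one label and 0.20 itself is "poor".

## The CV and why it conflicts with the ICC

The per-subject coefficient of variation $CV_i = s_i / \bar x_i$ (sample
SD over sample mean, denominator $k - 1$) is meaningful only on a ratio
scale, so nonpositive means raise an error rather than silently flipping
sign. `cv_mean()` averages $CV_i$ over subjects and applies the
customary strict 15% rule (exactly 0.15 is *not* acceptable).
`cv_pooled()` instead divides the SD of all $n \cdot k$ values by the
grand mean; unlike the per-subject form it absorbs between-subject
spread.

The two simulation engines make the conflict concrete:

* `simulate_batch1()` generates data with a *known true CV* — subject
  means fixed at 10 equally spaced values from 5 to 8, replicates
  $N(\mu_i, \mu_i \cdot CV)$ — and estimates the ICC. The subject means
  are deterministic by design, so the "true" between-subject spread is
  the spread of that grid, and the design-level ICC has the closed form
  $V_\mu / (V_\mu + CV^2 M_\mu)$ with $V_\mu$ the variance and $M_\mu$
  the mean square of the grid. Across the default grid (50 CV values,
  1000 replicates each) the mean estimated ICC stays above 0.5 for all
  true CVs below 15% and decreases as CV grows: a measurement can be
  "unacceptable" by the CV rule while the ICC is still moderate.
* `simulate_batch2()` generates from the mixed model with a *known true
  ICC* — $\sigma_W = \sigma_B \sqrt{(1-ICC)/ICC}$ via
  `derive_sigma_w()` — and estimates the CV. For a fixed ICC the mean
  estimated CV sweeps over an order of magnitude as the overall mean
  $\gamma$ moves from 1 to 10, because the CV divides by the mean: the
  CV cannot measure reliability.

The batch-2 CV is the **pooled** variant. The per-subject average (mean
of $s_i/\bar x_i$, expectation $\approx \sqrt{(1-ICC)}\,\sigma_{tot}/\gamma$)
is systematically smaller because it excludes between-subject spread;
the pooled expectation at large mean is
$\sqrt{\sigma_B^2+\sigma_W^2}/\gamma$ by the delta method, which is what
the published grid of this design reproduces (e.g. $\sqrt2/10 = 0.141$
at $\sigma_B = \sigma_W = 1$, $\gamma = 10$). A `per_subject` estimator
mode is exposed for sensitivity analysis.

Two caveats we quantified and accept:

* The ANOVA ICC estimator at $n = 10, k = 5$ carries a small negative
  bias — up to about 0.013 for true CVs between 0.2 and 0.5 — so batch-1
  cell means sit slightly below the closed-form design ICC; tests allow
  a 0.015 absolute floor around the analytic curve.
* The first-order delta approximation for the pooled CV degrades when
  the total CV itself is large. At $\gamma = 10$ it describes 26 of the
  27 $(\sigma_B, ICC)$ cells within 0.02; the most dispersed cell
  ($\sigma_B = 3$, $ICC = 0.1$, so $\sigma_W = 9$ and total CV
  $\approx 0.95$) exceeds it by the second-order term
  $\mathrm{var}(\bar X)/\gamma^2 \approx 2.5\%$ of the value — a bias of
  the ratio estimator itself, not a simulation artefact. At small
  $\gamma$ the ratio estimator is outright heavy-tailed (means can reach
  10 and beyond); those cells are reproducible only qualitatively and
  are excluded from quantitative checks.

Reproducibility of the grids: one root seed; cell $i$ draws from the
substream seed $(\mathrm{root} + 7919\,i) \bmod (2^{31}-1)$, so any
subset of cells — including parallel or partial runs — reproduces the
full run bit for bit.

## Bland-Altman agreement

`bland_altman()` takes differences as *first minus second* (in the
pipeline: day 1 minus the later day) and defaults to nonparametric
limits of agreement, the 5th and 95th percentiles of the differences,
preferred when differences are visibly non-normal. One percentile
convention is used package-wide: rank $1 + p(m-1)$ with linear
interpolation (`quantile` type 7), declared once so the limits are
exactly reproducible. The classical $\bar d \pm 1.96\,s_d$ limits remain
available as `mode = "parametric"`.

Heteroscedasticity — differences growing with the size of the
measurement — is traditionally judged by eye; as a numeric companion we
report the Spearman rank correlation between $|d_i|$ and the pairwise
means (two-sided test). The pipeline re-runs the analysis on the log
scale whenever this companion is significant at 0.05 and the values are
positive, and reports both scales.

## Sample sizes

`icc_sample_size()` implements the asymptotic method based on the
log-transformed F ratio:

$$n = 1 + \frac{2k\,(z_{1-\alpha/\text{tails}} + z_{\text{power}})^2}
{(k-1)\,[\ln(C_1/C_0)]^2}, \qquad C(\rho) = \frac{1+(k-1)\rho}{1-\rho},$$

always ceiled. The tail convention is exposed explicitly because the two
published design sizes this reproduces are mutually consistent only
under different conventions: 10 subjects per group at $k = 5$ (two-sided)
and 21 at $k = 2$ (one-sided), both for $\rho_0 = 0.20$, expected ICC
0.70, 90% power, $\alpha = 0.05$. We default to two-sided.

`ba_sample_size()` answers: how many paired differences are needed so
that, with the requested power, both estimated 95% limits of agreement
*and* their one-sided $1-\alpha$ confidence bounds (standard error
$s\sqrt{1/n + 1.96^2/(2(n-1))}$) fall inside the clinically acceptable
band $\pm\Delta$? Rather than a closed-form approximation, the power at
each $n$ is computed exactly by integrating over the joint sampling
distribution of the mean (normal) and SD (scaled chi) of the
differences, and the smallest adequate integer is returned — so a
simulation of the same acceptance rule reproduces the nominal power
directly, which is how the operation is tested. Defaults
$\alpha = 0.05$, power 0.80, symmetric band.

## The synthetic study generator

The real paediatric cohort behind this methodology is not publicly
deposited, so `generate_study()` emulates its design: five diagnosis
groups (healthy controls; non-allergic rhinitis; perennial allergic
rhinitis; seasonal allergic rhinitis outside and during the pollen
season) of 10 children each; four resistance parameters (R2, R75, R100,
R150) × two phases × two nostrils; five replicates per nostril at
baseline and one at each follow-up (days 14 and 28); a binary
current-symptoms outcome and a 0–15 total symptom score.

Calibration anchors and their rationale:

* **Group means and SDs** of the total (R + L) resistance come from the
  published group summary table; per-side values are half the total
  (sides generated independently and symmetrically; `TOT` rows are the
  exact record-wise sum R + L, and "combined total" is total inspiratory
  plus total expiratory — the published summaries are numerically
  additive).
* **Lognormal noise by default.** Resistances are positive and the
  group SDs are of the order of the means (e.g. 8.85 ± 11.77), which no
  normal model can honour without negative resistances; log-scale
  parameters are moment-matched to the calibrated mean and SD. The
  normal family exists to match the simulation batches' assumptions for
  estimator-recovery work, and *can* emit nonpositive values in the
  extreme groups — which the CV operations then reject by design.
* **True ICC per group** splits the calibrated variance into between-
  and within-subject parts (on the log scale in lognormal mode);
  defaults (0.50–0.85) sit in the observed within-day range. They are
  conveniences, not claims: the published cohort provides no
  within/between split, so calibrating total SD plus ICC is the only
  available anchoring and is approximate by construction.
* **Follow-up visits** add an independent day-level random effect (SD
  half the within-subject SD by default) so between-day reproducibility
  is genuinely worse than within-day repeatability, and a multiplicative
  per-day drift; the during-season allergic profile defaults to a
  decreasing drift (0.85 at day 14, 0.70 at day 28), reproducing the
  trending Bland-Altman pattern seen for that group.
* **Symptoms** are drawn with the group's prevalence (0.60 for healthy
  controls up to 1.00 for seasonal allergic rhinitis) tilted by a
  logistic link on the subject's standardised log latent R2 level
  (default slope 1), so resistance genuinely predicts symptoms and ROC
  performance lands near the published range (AUCs ≈ 0.7–0.85) while
  remaining tunable.

What passing tests on these data do **not** show: the generator has
symmetric nostrils, no therapy effects, no item-level symptom dynamics,
and exchangeable replicates — real rhinomanometry data may violate any
of these, so pipeline results on synthetic data validate the *software
and the statistics*, not clinical conclusions.

## The analysis pipeline

`within_day_repeatability()` and `between_day_reproducibility()` are
deliberately thin: every ICC, CV and agreement number they emit is the
unmodified output of the corresponding core function applied to the
extracted sub-table (tests assert bit-identity). Design choices the
published analysis leaves open, and what we chose:

* **Day-1 value for between-day comparisons**: the mean of the five
  baseline replicates (configurable to the first replicate); the choice
  is recorded in the output metadata. Note an interaction we document
  rather than hide: averaging five replicates shrinks the baseline error
  variance fivefold, so with mild day-level noise the two-occasion ICC
  computed against the day-1 *mean* can exceed the within-day
  single-measurement ICC; on the single-replicate basis between-day
  reliability is strictly lower, which is the basis our property tests
  use.
* **ROC predictor**: the per-subject mean of the baseline combined-total
  (or per-phase total) resistance; no classifier is fitted — a single
  variable already defines a ranking, and the cross-validated AUC simply
  re-evaluates the Mann-Whitney statistic on held-out stratified folds
  (5 by default, fixed seed).
* **No multiple-testing correction** is applied anywhere, matching the
  analysis style this package accompanies; p < 0.05 is the significance
  convention. This is stated rather than silently assumed.
* **Descriptive comparisons** use Kruskal-Wallis for quantitative and
  chi-square (without continuity correction, so the statistic is the
  textbook $\sum (O-E)^2/E$) for categorical covariates.

DeLong confidence intervals are computed from placement values
($\mathrm{var} = \mathrm{var}(V_{10})/m + \mathrm{var}(V_{01})/n$), are
rank-invariant, collapse (and say so) under perfect separation, and
their null coverage calibrates at the nominal 95% in simulation.

## Problem sizes used in the test suite

The shipped tests run the two simulation engines at their full default
grids (50 CV cells and 270 mixed-model cells, 1000 replicates each — a
few seconds), the estimator-recovery study at 200 subjects per group,
DeLong null-coverage at 1000 simulated studies of 100 subjects, and the
Monte-Carlo power oracle for `ba_sample_size()` at 2000 replicates.
These sizes were chosen so that Monte-Carlo error is comfortably below
every tolerance asserted while the whole suite stays interactive.
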