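---
title: "Modeling repeated maternal hemoglobin measurements against binary birth outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling repeated maternal hemoglobin measurements against binary birth outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbtraj)
```

## The problem

Maternal hemoglobin (Hb, g/L) is measured repeatedly during antenatal care —
typically two or three times, once per trimester — and both low and high
concentrations have been linked to adverse birth outcomes: low birth weight
(LBW, birthweight < 2500 g), preterm birth (PTB, delivery before 37
completed weeks) and small-for-gestational-age (SGA, birthweight below the
10th percentile). The statistical difficulty is that the exposure is a short,
irregular longitudinal series per woman while each outcome is a single binary
endpoint. Summarising the series to one number discards the trajectory;
entering all measurements as separate covariates invites collinearity.

`hbtraj` implements five complementary strategies for this
repeated-exposure / binary-outcome design, together with a synthetic cohort
generator whose ground truth (random effects, latent classes, window
exposures, linear predictors) is returned next to the data, so every claim
the package makes can be checked by simulation.

Throughout, subject $i$ has outcome $Y_i \in \{0,1\}$, Hb measurements
$X_{ij}$ at gestational ages $t_{ij}$ (weeks) in trimesters $T_{ij}$, with
$n_i \in \{2,3\}$ after preprocessing. Trimesters are the half-open intervals
$[0,13)$, $[13,29)$, $[29,41]$ weeks: the conventional verbal ranges share
their endpoints, and a deterministic mapping needs the boundary weeks
assigned somewhere, so week 13 is second trimester and week 29 third.
Repeated measurements inside one trimester are averaged (both Hb and the
visit time) before modelling; methods that need one measurement per
trimester run on the subjects with exactly three visits after averaging,
while the additive model uses everyone.

## Method 1 — sequential-residual logistic regression

Later visits are residualized on earlier ones across subjects,

$$X_{i2} = a_0 + a_1 X_{i1} + \epsilon_{i1}, \qquad
  X_{i3} = a_0' + a_1' X_{i1} + a_2' X_{i2} + \epsilon_{i2},$$

and the standardized residuals enter the outcome model

$$\operatorname{logit} P(Y_i = 1) =
  \beta_0 + \beta_1 X_{i1} + \beta_2 \hat\epsilon_{i1} + \beta_3 \hat\epsilon_{i2}.$$

The residuals are the parts of the later measurements not predicted by the
earlier ones — window-specific changes — and are mutually far less collinear
than the raw measurements. The two auxiliary regressions carry independent
coefficient sets, and each residual vector is standardized on its own
(mean 0, sample $n-1$ SD 1), so $\beta_2, \beta_3$ read per 1 SD of
innovation; first-visit Hb is reported per 5 g/L for comparability with the
other methods. Exact collinearity (a residual vector that is constant)
surfaces as an explicit degenerate-fit error rather than a silent zero
column.

## Method 2 — two-stage mixed-effects model

Stage 1 is a linear mixed model of Hb on trimester indicators (second and
third versus first) with a subject random intercept and random trimester
slopes under an unstructured $3\times3$ covariance, fitted by REML
(`lme4`). Stage 2 regresses each outcome on the subject's estimated random
effects (BLUPs), divided by 5 so odds ratios correspond to a 5 g/L
difference in the subject's own level or trimester change.

Two honest caveats are built into the reporting. First, with exactly three
observations per subject the marginal within-subject covariance
$G + \sigma^2 I_3$ has six free entries but the model carries seven variance
parameters, so $G$ and $\sigma^2$ are only jointly identified; the REML
criterion is maximized along a ridge. Fixed effects and the marginal
covariance are unaffected; `fit_lmm` therefore disables the count and
curvature checks that would reject the printed model, keys convergence on
the optimizer's own status, and flags boundary fits. Second, Stage 2 treats
the BLUPs as observed data. Because BLUPs are shrunken toward zero, Stage-2
coefficients are attenuated relative to a regression on the true random
effects; the test suite demonstrates the attenuation directly against the
generator's ground truth rather than pretending it away.

## Method 3 — distributed lag non-linear model (DLNM)

Each subject's sparse measurements are expanded to a weekly exposure history
on gestational weeks 1–39 by linear interpolation between visits and
constant extrapolation outside them, with a provenance flag
(observed / interpolated / extrapolated) kept per week. A cross-basis then
parameterizes a week-varying, possibly non-linear effect: with exposure
basis functions $B^e_k$ (linear, or natural cubic splines with knots at
exposure quantiles, centred at the 110 g/L reference) and lag basis
functions $B^l_l$ (constant, linear, or natural splines over the lag range,
lag $= 39 - \text{week}$), subject $i$'s covariate row is

$$q_{i,(k,l)} = \sum_{w=1}^{39} B^e_k\big(H_i(w)\big)\, B^l_l\big(39 - w\big),$$

entered into a logistic regression. The basis pair is chosen by AIC over a
candidate grid (exposure: linear, spline with 2 or 3 interior knots; lag:
constant, linear, spline with 2 interior knots), ties broken by smaller
dimension then label order. The headline output is the odds-ratio curve for
a +5 g/L increase at week $w$ against the reference profile, with
delta-method bands on the log scale. Centring the exposure basis at the
reference makes this contrast exact: at zero increment the OR is exactly 1
at every week, a property the tests assert literally.

Because no distributed-lag machinery is available as a dependency, the
cross-basis construction, AIC selection and contrast prediction are
implemented in the package itself; the one-column special case is verified
in the tests against an ordinary logistic regression on the hand-collapsed
cumulative covariate.

## Method 4 — outcome-stratified additive mixed model

The modelling direction is reversed: Hb is the response,

$$X_{ij} = \beta_0 + b_{0i} + f_1(t_{ij})(1 - Y_i) + f_2(t_{ij})\,Y_i + \epsilon_{ij},$$

fitted in the equivalent shared-plus-difference form
$\beta_0 + \beta Y_i + f(t_{ij}) + Y_i\,g(t_{ij}) + b_{0i} + \epsilon_{ij}$.
That parameterization exists because "the EDF of the difference between
outcome groups" is otherwise ill-defined; here it is simply the effective
degrees of freedom of $g$. Smooths are penalized thin-plate regression
splines with basis dimension capped at `k = 5` by default — a deliberate
limit that keeps the fitted trajectories at the gentle, U-shaped level of
wiggliness seen in pregnancy Hb, at the cost that an exactly quadratic truth
is only approximated (to a few tenths of a g/L over a ~25 g/L swing), not
reproduced to machine precision. Smoothing parameters are chosen by REML.
EDF values near 1 mean the groups differ by at most a linear trend; the EDF
is bounded by the difference-basis dimension ($k-1$ after centring).
Single-replicate EDFs are noticeably variable even under a linear-difference
truth — REML smoothing-parameter noise, visible in the test suite — so
EDF-based conclusions should be drawn from the curve plots and bands, not
the EDF alone.

Fitting uses two engines. Up to a few hundred subjects, `mgcv::gam` fits the
full model with the subject intercept as a random-effect smooth by exact
REML; its dense algebra scales cubically in the number of subjects (minutes
at a few thousand). Beyond 300 subjects the package switches to a GLS
engine: the intercept and residual variances are estimated by sparse
`lme4::lmer` on a parametric trimester-by-group model, the implied
compound-symmetric covariance is removed exactly with the closed-form
transform $y^*_{ij} = y_{ij} - \lambda_i \bar y_i$,
$\lambda_i = 1 - \sigma_e / \sqrt{\sigma_e^2 + n_i \sigma_u^2}$, and the
penalized smooths are refitted to the whitened data by REML through `mgcv`'s
`paraPen` interface. At n = 400 the two engines agree to about 0.005 g/L in
predictions and 0.002 in EDF (asserted in the tests); the GLS engine handles
the full default cohort in under two seconds. Predictions are population
level (random intercept at 0) with pointwise, not simultaneous, bands;
extrapolation beyond the observed gestational-age range is refused.

This method describes trajectories by outcome status; it deliberately
produces no outcome effect estimate, and its outputs are labelled
accordingly.

## Method 5 — group-based trajectory modeling (GBTM)

A finite mixture of polynomial mean curves: class $k$ has mean
$\mu_k(t) = \gamma_{0k} + \gamma_{1k} t\ (+\ \gamma_{2k} t^2)$, a shared
residual SD, and mixing proportions $\pi$. Classic GBTM (no within-class
random effects) is implemented even though richer latent-class mixed models
exist: with at most three observations per subject, class-specific random
effects are weakly identified, and the posterior machinery downstream is
agnostic to the choice. The EM algorithm alternates subject-level
responsibilities and responsibility-weighted polynomial regressions, with 20
seeded restarts from k-means initializations on per-subject level/slope
features, convergence at a relative log-likelihood change of $10^{-8}$, and
empty-class restarts counted. The observed-data log-likelihood is asserted
non-decreasing on every run. Labels are canonicalized by fitted mean Hb at
week 24, descending, making the fit invariant to subject order and restart
order.

Model choice follows a two-step rule: degree (linear vs quadratic) on the
one-class model by BIC, then the number of classes $K \in 1..7$ as the
smallest-BIC model whose every modal class holds at least 5% of subjects,
falling back to $K = 1$ with a warning when nothing satisfies the floor.
BIC is the criterion (AIC is reported alongside in the selection table).
One behaviour worth knowing: when the data contain within-subject
correlation beyond the class structure (as the default generator's random
intercepts create), BIC tends to add classes to absorb it — a known property
of mixture selection under residual dependence, visible in the selection
tests, which therefore validate selection consistency on truths that match
the GBTM assumption of independent within-class residuals. Downstream,
outcomes are regressed on modal class indicators (largest class as
reference) or on the $K-1$ posterior-probability columns; with hard 0/1
posteriors the two modes coincide exactly.

## The synthetic cohort generator

`simulate_cohort()` emulates the data structure all five methods assume:

* about 10.5% of subjects with three visits centred at weeks 10 / 24 / 32
  (triangular jitter of half-width 2 weeks, truncated to keep each visit in
  its intended trimester — observed visit-time spreads are interquartile
  ranges of roughly 9–11, 21–26 and 30–33 weeks); the remainder with two
  visits, enrolment in the first or second trimester (split evenly, a
  choice, since enrolment timing is rarely reported) plus an
  end-of-gestation visit;
* trimester-level mean Hb of 119.7 g/L with contrasts −8.7 (second) and
  −6.25 g/L (third) — a shallow U over gestation; an optional smooth
  quadratic U-shape with configurable nadir near week 24;
* independent subject random effects (SDs 10 g/L intercept, 6 g/L per
  trimester slope) and 7 g/L measurement noise, values in the range reported
  for antenatal Hb series;
* marginal outcome prevalences 19% (LBW), 6% (PTB), 31% (SGA), with
  optional links from the true random effects (`random_effect_link`), latent
  classes (`class_link`), or a reverse `group_shift` that lowers the
  affected group's Hb before a given week;
* `simulate_window_effect_cohort()` for the DLNM: smooth weekly latent
  curves, outcome log-odds driven only by mean centred Hb inside a stated
  week window, observed visits as noisy samples of the curve.

Birthweight, delivery week and a birthweight percentile are drawn
consistently with the binary outcomes so the derivation rules are
exercised; the percentile is a uniform stand-in, not an external growth
standard. One seeded RNG stream drives each cohort, and the ground truth is
returned with the data.

What the generator does *not* emulate: between-site heterogeneity (the kind
of multi-country differences in assay, blood source and altitude adjustment
real pooled cohorts carry), measurement-device effects, informative visit
timing, or missingness mechanisms. Passing tests therefore demonstrate that
the estimators recover the structures they model when those structures are
present — not that real cohorts satisfy the models.

## Numerical choices and degenerate inputs

* Wald intervals everywhere (symmetric on the log-odds scale); no
  profiling.
* Separation is declared when a standardized coefficient passes ±15 with
  fitted probabilities pinned at 0/1, and aborts with the column named —
  sparse outcomes in small subsets make this failure mode likely, and a
  silent huge OR would be worse than an error.
* REML, not ML, for all variance components (low bias at these subject
  counts).
* Sample ($n-1$) SDs for standardization.
* Out-of-range gestational ages, non-positive Hb, g/dL-looking magnitudes,
  one-class outcomes, constant residuals, duplicate spline knots,
  over-parameterized cross-bases and empty visit-count subsets all fail
  loudly with the offending value named.

## Problem sizes used in the test suite

The suite exercises every method at the scale its statistics need rather
than at the full study scale: estimator oracles at tens of observations,
recovery runs at 500–2000 subjects with tens of replicates, calibration at
500 replicates of the three-visit subset size (676), and the acceptance
script at the full cohort scale (6,452 subjects, ~10.5% three-visit). All
replicate counts are fixed in the code with their seeds.

## Known limitations

* The DLNM's weekly profiles are interpolations of 2–3 points; weeks far
  from any visit are extrapolations, flagged but still used. Effects
  localized between visits are attributed to the interpolation path.
* Stage-2 uncertainty from Stage 1 is ignored by construction (that is the
  method); the attenuation is demonstrated, not corrected.
* GBTM assumes independent within-class residuals; correlated residuals
  inflate the selected number of classes.
* EDF of the trajectory difference is a REML point estimate with
  substantial replicate noise.
* Confidence bands on trajectories and OR curves are pointwise.
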