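---
title: "Methods: thermal optima of nectar secretion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal optima of nectar secretion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nectartherm)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, and the decisions taken where the
underlying experimental protocol left the numerical details open.

## The experiment being modelled

A stepped-temperature climate-chamber protocol: potted plants of one
species experience a staircase of day temperatures in fixed increments,
one step every 3 days, with night temperature always 6 °C below day. The
analysis temperature is the 24-h mean,

$$\bar T = T_{day} - 6 \cdot \frac{h_{dark}}{24},$$

exact arithmetic from the day setpoint and photoperiod
(`compute_24h_mean()`). On the last day of each step, three randomly
chosen fresh flowers per plant are emptied and measured (volume in µl by
microcapillary, sugar concentration in % w/w by refractometer), and the
flowers opened in the previous 24 h are counted. A parallel control group
(constant chamber temperature or ambient placement) experiences only the
passage of time.

Five traits are analysed per plant-day: nectar volume per flower, sugar
concentration, sugar content per flower, sugar content per plant
(= mean sugar per flower × open flowers), and the number of flowers.

## Trait derivation

**Sugar mass.** A flower with volume $v$ µl at concentration $c$ % w/w
holds $v \cdot (c/100) \cdot d(c)$ mg of sugar. $d(c)$ is a quadratic
approximation to the standard 20 °C sucrose-solution density table,
pinned at $d(0) = 0.9982$ g/ml:

$$d(c) = 0.9982 + 3.771162\times10^{-3}\,c + 1.726751\times10^{-5}\,c^2,$$

with maximum relative error 0.09 % over 0–75 % w/w (requirement was 1 %;
the coefficients were fitted once against the published table and are
verified against a linear-interpolation oracle in the tests). No
correction is attempted for hexose-dominant nectars or refractometer
temperature.

**Imputation.** Volumes below 0.05 µl (configurable) cannot be read on
the refractometer; their concentration is imputed as the arithmetic mean
of the same plant-day's observed flowers. If *no* flower on a plant-day is
readable, the record is flagged and excluded from concentration-based
traits rather than aborting the run.

**Empty flowers.** A sampled flower holding no nectar at all is a real
flower: it enters the plant-day mean volume as 0 µl and the mean sugar as
0 mg, but never contributes to mean concentration (there is nothing to
measure). The protocol description does not state this convention either
way; this choice is consistent with treating empty flowers as a separate
zero process (below).

**Transforms and standardization.** Volume, both sugar traits and the
flower count are right-skewed and log-transformed; concentration, being a
percentage, is logit-transformed. Two rules the protocol leaves open:

* *log offset* — traits that can be exactly 0 use $\log(x + c)$ with $c$
  = half the smallest positive observed value of that trait (0 when no
  zeros occur). The offset is recorded in every fit's metadata.
* *logit boundary* — proportions are clamped to $[\varepsilon,
  1-\varepsilon]$ with $\varepsilon = 1/(2N)$, the usual finite-sample
  adjustment, since 0 % and 100 % readings are possible.

All responses and temperature are standardized (mean 0, SD 1) before
fitting: **per species** for single-species models (each species is its
own scale), **pooled** when species enter one model and must be
comparable. The scope is stored in each fit and every optimum is mapped
back to °C through the stored center/scale.

## Mixed models

Per species and trait (`fit_quadratic_lmm()`):

$$y_{ij} = \beta_0 + \beta_1 T_j + \beta_2 T_j^2 + b_i + \epsilon_{ij},
\qquad b_i \sim N(0, \sigma_p^2),\ \epsilon \sim N(0, \sigma^2),$$

fitted by REML with a random intercept per plant. Coefficient p-values
use the **normal approximation** (the Satterthwaite machinery is not
available in this dependency set); the choice is recorded as
`df_method = "normal"` in every fit and in the run manifest. With ≈100+
plant-days per species the difference from a t reference is negligible.

The control-validation model (`fit_time_group_interaction()`) contrasts
experimental and control groups under the assumption that both respond to
time identically, so `time × group` and `time² × group` interactions
isolate the manipulated-temperature effect. The flowering-group model
(`fit_flowering_group_model()`) fits `(T + T²) × group` with additive
random intercepts for species and plant-within-species — "plant nested
within species" is implemented as the two additive intercepts, the
standard lme4 parameterization of a nested structure.

Model selection between linear and quadratic trends (`aic_select()`)
refits both models by **ML** (REML criteria are not comparable across
fixed-effect structures) while curve reporting stays on the REML fit.
R²m/R²c follow the variance-decomposition definition: marginal =
var(fixed predictions) over total; conditional adds the random-intercept
variances to the numerator.

Degenerate inputs: data with exactly zero residual variance (the
noiseless simulator limit) are detected by an exact OLS interpolation
check and returned with OLS coefficients, zero variance components and
the explicit note `"degenerate_noiseless"` — flagged, never silent.

## Thermal optimum and the 5 %-band range

On the standardized scale the fitted parabola peaks at
$x^* = -\beta_1/(2\beta_2)$; `optimum_temperature()` maps this to °C and
flags extrapolation when $x^*$ lies outside the tested range (the
situation that produces an implausible optimum when a response is nearly
linear).

The *optimal temperature range* is defined by a band of height

$$\delta = 0.05 \times (\max y_{obs} - \min y_{obs})$$

below the fitted maximum, where the observed range is taken **on the
transformed, standardized model scale** — the scale on which curve and
measurements are plotted together. Two published phrasings of the band
("5 % of the highest trait values" vs "5 % of the measured trait value
range") are reconciled as the latter, the only version that yields a
well-defined interval from the fitted curve. The interval solves
$\beta_2 x^2 + \beta_1 x = \beta_2 x^{*2} + \beta_1 x^* - \delta$ exactly:

$$x = x^* \pm \sqrt{\delta / |\beta_2|},$$

symmetric about the vertex in standardized units. Properties verified in
the tests: agreement with a 1e-4 grid-search oracle, $1/\sqrt2$ width
scaling when the band is halved, monotone narrowing in $|\beta_2|$.

Decisions: intervals are **not truncated** to the tested temperature
range by default (published intervals extend past tested bounds;
`truncate = TRUE` clips them, and the flag is recorded). Optima are
computed from point estimates even when the quadratic term is
non-significant — significance travels as an annotation, never as a
filter. Convex (⋃) fits report the analogous band above the minimum.

## Climate comparison

Baselines are long-term (1958–2001) monthly means for the flowering
months of the six species (January 9.2, March 11.9, April 15.9, May 21.3,
June 26.2 °C); projections add a seasonal end-of-century increment
(winter 1.5–2.4, max 3.0; spring 2.1–2.7, max 3.7; summer 2.3–3.3, max
5.5 °C). May belongs to spring, January to winter. Species flowering
January–April form the early group, May–June the late group; other
months are outside the design and error out.

`paired_t_optima()` computes $t = \bar d/(s_d/\sqrt n)$ with the sample
SD and df = n−1, dropping species without a defined optimum pairwise
(this is what produces df = 1 in the early-group sugar-per-flower rows:
one species' response is linear). Annotations use the conventional bands
plus the marginal "." for 0.05 < p < 0.1, which reproduces the published
annotations exactly. Concentration is excluded from the comparison table:
several species respond linearly and have no optimum.

**The p50 problem.** The published comparison includes "50 % projection"
rows, but the median seasonal increments were never printed (only the
25th–75th percentile range and the maximum). Those increments are
recoverable only by inverting the published t statistics — a validation
exercise, not data. The package therefore treats p50 as **required user
configuration with no default**: requesting the level without supplying
increments fails loudly. All 24 baseline/p75/max cells reproduce the
printed t values to ±0.001 from the published optima and climate values
(verified in `test-acceptance.R`).

## Empty flowers: zero-inflated negative binomial

The count of empty flowers among the three sampled, per plant-day, is
modelled as

$$y \sim \pi\,\delta_0 + (1-\pi)\,\mathrm{NB}(\mu, \theta), \qquad
\log \mu = b_0 + b_1 T + b_2 T^2,$$

with an intercept-only zero-inflation probability (the default of the
tool the original analysis used) — temperature enters only the count
mean. The likelihood is authored in the package (no ZINB library exists
in this dependency set) and maximized by BFGS from two starting points,
one with excess-zero inflation and one at $\pi \approx 0$, so the
optimum never falls below the nested plain-NB fit. Standard errors come
from the observed information. A plant-level random intercept can be
integrated out by a Laplace approximation (`random = TRUE`); it is off
by default because the approximation is unstable for few plants. An
all-zero response returns a `zero_saturated` flag instead of a fit. The
plain NB special case is verified against `MASS::glm.nb` in the tests.

A "more empties at both temperature extremes" world yields a positive
fitted $T^2$ coefficient on the empty-flower count — the convex analogue
of the published finding.

## The synthetic world

The generator (`generate_experiment()` / `generate_control()`) emulates
the chamber protocol with the statistical structure the analysis models
assume — by construction, so that model and generator agree on what
"truth" means:

* per-trait true curves are concave parabolas **on the model scale**
  (log µl, logit proportion, log count):
  $f(T) = A - ((T - T_{opt})/w)^2$, with amplitude $A$, optimum
  $T_{opt}$ (°C) and breadth $w$ (°C per model-scale unit drop);
  $w = \infty$ switches a trait's temperature effect off;
* one Gaussian random intercept per plant and trait (SD `plant_sd`),
  Gaussian residuals (`resid_sd`) on the model scale;
* flower counts are negative binomial with size `nb_size`
  (`Inf` = deterministic limit);
* each sampled flower is empty with probability logistic in the absolute
  distance from the optimum (`zero_inflation_base` at the optimum,
  `zero_inflation_heat_slope` per °C), producing excess zeros at both
  extremes;
* a shared linear-plus-quadratic time drift acts identically in both
  groups — exactly the assumption that justifies the time × group
  validation logic;
* volumes below the measurable threshold get missing concentration, to
  exercise the imputation rule.

Default profiles for the six species put each trait optimum at its
published value, with field-realistic peak volumes (0.8–3 µl),
concentrations (25–40 %), flower counts (15–60/day) and empty flowers in
the three species that showed them. The study reports **no variance
components**, so `plant_sd = 0.3` and `resid_sd = 0.4` (model scale) were
chosen once as values giving the qualitative picture the study describes
— clearly unimodal responses with visible between-plant scatter — and are
not revisited. A green parameter-recovery test therefore establishes that
the *pipeline* recovers the truth of this stated world, not that the
world equals the real experiment. Features deliberately not emulated:
humidity, watering, light spectra, insecticide treatment, power-cut
interruptions, and the irregular replacement of exhausted plants.

**Seeding.** One master seed; each plant draws from a substream seeded by
a fixed affine function of (master seed, group, plant index), so enlarging
the design never reshuffles existing plants' data (verified in the
tests).

**Noiseless closure.** With `plant_sd = resid_sd = 0` and no zero
inflation, flower-level traits land exactly on their true curves and the
full pipeline returns the true optimum to < 0.01 °C (in fact to solver
precision). Count-based traits are the exception: negative-binomial
sampling noise is irreducible at finite `nb_size`, so their closure is
tested in the deterministic `nb_size = Inf` limit instead. Sugar traits
are products of two curves with different optima and are exactly
quadratic on no scale; they are covered by the stochastic recovery tests
rather than the exact-closure test.

## Numerical choices and limitations

* lme4 fits use `calc.derivs = FALSE` and ignore singular-fit signals
  (boundary estimates of a variance are legitimate); any other
  convergence message marks the fit not converged, and downstream
  consumers refuse unconverged fits.
* The quadratic-vs-linear shape call uses a 1e-10 tolerance on the
  standardized quadratic coefficient.
* Paired t significance bands: ns / "." (0.1–0.05) / * / ** / ***.
* The acceptance suite scales some spec'd replicate counts down (noted
  inline in the tests) where the statistical content is unchanged;
  thresholds are never loosened.
* No bootstrap confidence intervals on optima, no GEE/spline/Bayesian
  alternatives, no autocorrelation over steps, no precipitation
  scenarios: all outside this package's scope.
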