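---
title: "Methods: a time-stratified case-crossover analysis of summer temperature and asthma hospitalisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-crossover analysis of summer temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Short spells of warm weather are suspected to trigger asthma exacerbations
severe enough to need hospital care. The natural design for such transient
exposures is the **case-crossover**: each admitted patient serves as their
own control, and the temperature around the admission day is compared with
the temperature on nearby *referent* days for the same person. Anything
about the patient that does not change on the time scale of weeks -- age,
sex, deprivation, smoking history, baseline disease severity -- is matched
out by construction.

`heatasthma` implements this analysis end to end, together with a
synthetic-data generator with known ground truth, because the real inputs
of such studies (individual hospital episodes and residence locations)
are confidential and cannot be shipped. Every statistical claim the
package makes is therefore demonstrated on data whose true
exposure-response is known exactly.

## Referent selection

Referents are **time-stratified**: for an admission on day $t$, the
referents are all other days in the same calendar month and year falling
on the same weekday. This yields strata of 4 or 5 days (3 or 4 referents,
depending on the month's weekday structure), shared by every event in the
same (weekday, month, year) cell -- the disjointness that avoids overlap
bias -- and it absorbs weekday patterns, within-summer seasonality and
long-term trends. `referent_days()` is deliberately dumb calendar
enumeration; the test suite checks it against an independent brute-force
scan over thousands of random dates.

## Exposure

The daily exposure is the mean temperature, computed as
$(T_{\min} + T_{\max})/2$ at the 1 km grid cell containing the patient's
(privacy-jittered, 100 m) residence. The analysis exposure is the average
of this daily mean over the lag window; the default window `0:3` means
the admission day (lag 0) plus the three preceding days. The window is
re-anchored at every stratum day, the standard case-crossover convention.
Two points were genuinely open and are resolved as follows:

* **Does "lag 0--3" include the event day?** Yes: lag 0 is the event day
  by field convention, and the companion sensitivity analysis over "any
  lag between 0 and 5" only makes sense on that reading. The window is a
  plain argument (`lag_set`), so the alternative reading `1:3` is one
  keystroke away.
* **Are confounders lag-averaged too?** Same-day (lag 0) values are used
  for rainfall, humidity and wind -- the minimal assumption; a holiday is
  a property of the day itself.

Missing exposure days are a hard error naming the date: partial averages
would silently change the estimand.

## The model

Within stratum $s$, day $j$, the admission count is modelled as Poisson
with
$$\log \mu_{sj} = \alpha_s + \beta x_{sj} + \boldsymbol\gamma' \mathbf{z}_{sj},$$
where $x_{sj}$ is the lag-averaged mean temperature, $\mathbf{z}$ the
confounders (rainfall in mm, relative humidity in %, wind speed in m/s,
holiday indicator) and $\alpha_s$ a per-stratum intercept. Conditioning
on the stratum totals cancels every $\alpha_s$ and leaves the multinomial
likelihood
$$\ell(\beta, \boldsymbol\gamma) = \sum_s \left[ \eta_{s,\mathrm{case}} -
\log \sum_j e^{\eta_{sj}} \right],$$
identical to conditional logistic regression with one case per stratum.
Fitting this conditional form rather than thousands of explicit stratum
intercepts is exactly equivalent and much cheaper; the equivalence is not
assumed but *tested*, by comparing the flat-prior posterior mode against
`survival::clogit` on every run of the acceptance suite (agreement is at
numerical precision, ~1e-9).

Effects are reported as the percent change in hospitalisation risk per
1 °C, $100(e^\beta - 1)$, the exact transform rather than the linear
approximation $100\beta$; being monotone it is applied directly to
posterior quantiles or draws, so credible intervals transform exactly.

### Priors and computation

Priors are weakly informative and configurable: Normal(0, 10²) on fixed
effects, half-Normal(0, 1) on standard-deviation-type hyperparameters.
At the sample sizes involved they are numerically irrelevant for the
fixed effects -- which is the point, since the original INLA-style
defaults they stand in for are equally flat.

The default backend is a deterministic **Laplace approximation**: Newton
ascent (analytic gradient and Hessian, line search, convergence at
gradient norm < 1e-9) to the posterior mode, Gaussian quantiles from the
curvature. A Metropolis-Hastings backend (`backend = "mcmc"`, proposal
calibrated from the Laplace covariance, split-R̂ and effective sample
size reported) is provided as a cross-check; the two agree on every
dataset tested.

Numerical choices worth knowing: design columns are centred within
stratum before optimisation (the conditional likelihood is invariant to
within-stratum constants, so this is free and bounds the linear
predictor); strata with no exposure contrast contribute a constant and
are retained so record counts reconcile; a stratum with zero or two case
rows is a hard data error.

### Patient random effects

Recurrent admissions cluster within patients, and the model allows a
per-patient normal term. But each stratum belongs to exactly one
admission, hence one patient, so the term is **constant within every
stratum and cancels exactly** from the conditional likelihood: its
posterior equals its prior and the exposure coefficient cannot move.
The package implements the term faithfully (scope configurable to
patients with ≥ 2 admissions or all patients) but records this
cancellation in the diagnostics instead of carrying thousands of inert
parameters. The invariance is asserted to be exact in the acceptance
suite -- it is the formal content of the claim that the design controls
for patient-level factors.

## The RW2 non-linearity check

Departures from linearity are probed by replacing $\beta x$ with a free
curve $\theta_{b(x)}$ over `n_bins = 20` equal-width temperature bins
(exposures assigned to the nearest bin midpoint), tied together by a
**random-walk-2** prior: the improper Gaussian with precision
$\tau D'D$, $D$ the second-difference operator. Its null space is spanned
by constant and linear vectors, so the prior shrinks the curve toward a
straight line -- the linear model is its infinite-smoothness limit. The
structure matrix is rescaled so the geometric mean of the intrinsic
marginal variances is one, making the half-Normal(0, 1) hyperprior on
$\tau^{-1/2}$ interpretable regardless of bin count.

The level is fixed by a sum-to-zero constraint (the strata absorb it),
and the linear direction -- which the RW2 penalty leaves free -- gets the
ordinary fixed-effect prior so the posterior stays proper even with no
exposure contrast. The smoothness hyperparameter is integrated over a
13-point grid on its log scale, each point contributing a Laplace
approximation weighted by its approximate marginal likelihood
(a simplified INLA-style scheme). Reported outputs: the posterior-median
curve with a 95% band, a linearity summary (maximum deviation of the
median curve from its own least-squares line over the central 5--95% of
exposure mass, relative to the curve's range), and
`rw2_slope_contrast()`, the posterior probability that the curve is
steeper above a stated threshold than below it.

## Subgroups and the yearly trend

Effect modification (age 5--15 / 16--64 / 65+, sex, study period, region)
is assessed by **full re-fits within subgroups** -- strata rebuilt, all
nuisance parameters re-estimated, nothing pooled -- matching the
repeat-the-analysis convention rather than an interaction model.
Subgroups below a configurable event minimum are skipped with a warning.

The temporal trend uses a posterior-draw procedure: fit the fully
adjusted model per calendar year, draw 1000 values from each year's
posterior of the percent change, and for each draw index fit an
unweighted ordinary least-squares line of effect on year. The 1000
slopes are the posterior of the linear trend (percent-change points per
year). An inverse-variance-weighted variant exists but is off by
default, matching the plain-linear-models convention. The procedure is
location-equivariant (shifting every year's effect leaves the slope
distribution unchanged) and reduces to a single OLS fit at
`n_draws = 1`.

## What the synthetic data emulates -- and what it does not

The generator produces every input the real study would buy or be
granted: a fine (1 km) daily Tmin/Tmax grid over 26 May--31 August of
each year, a coarse (factor 11, i.e. 11 km) grid of rainfall, humidity
and wind with configurable correlation to temperature, a two-per-summer
holiday calendar, a patient population, and Poisson admission events
from a log-linear rate with a *known* temperature coefficient, calendar
baseline, confounder effects, per-patient random effects, optional
subgroup multipliers, and optional non-linear (e.g. threshold)
responses. A defect injector appends exact numbers of duplicates,
out-of-area residences, off-season dates, under-5 ages and missing
fields so the exclusion cascade's bookkeeping can be asserted record by
record.

Default study conditions, chosen once as representative of an English
summer at these resolutions: daily-mean temperature 15.5 °C with an
AR(1) day-to-day anomaly (marginal SD 3.5 °C, autocorrelation 0.55), a
2 °C seasonal cycle peaking mid-July, a 2 °C north-south gradient, a
4 °C mean diurnal half-range, humidity/rainfall/wind correlations with
temperature of −0.5 / −0.3 / −0.15, patient-effect SD 0.3, and a true
effect of 2% per °C (`beta_temp = log(1.02)`). The admission-rate
intercept is solved to hit a target event count, so cohort size is a
design parameter rather than an emergent one. Within-summer seasonality
of the *admission baseline* is a parameter defaulting to zero, since
its real magnitude is not well established; the stratified design
absorbs it in any case.

What it does **not** emulate: real geography (no projections, postcodes
or coastlines -- the grid is an abstract plane in km), real holiday
calendars, spatially correlated cell noise, age progression over the
study (a patient's age is fixed, avoiding age-group migration mid-study),
admission dependence beyond the patient random effect, and any
exposure-measurement error beyond the 100 m jitter. Passing tests
therefore demonstrate the *statistical machinery* -- unbiased recovery,
calibrated intervals, exact design invariances -- not robustness to the
messiness of real administrative data.

## Problem sizes and reproducibility

The test and acceptance runs use cohorts of 200--5000 events on grids of
11×11 to 22×22 km with 1--12 years, sizes at which one full
simulate-clean-link-fit cycle takes well under a second and the entire
statistical battery (50-dataset oracle comparison, 100-replicate
recovery study, 200-replicate type-I study, RW2 fits, 12-year trend
recovery) completes in a few minutes. Every stage is deterministic given
its seed; the pipeline splits a single root seed per stage and records
the splits in its output manifest, which together with the serialised
configuration suffices to reproduce a run byte for byte.

## Known limitations

* The Laplace approximation's intervals are Gaussian in $\beta$; at the
  event counts used here the likelihood is near-quadratic and the MCMC
  cross-check agrees, but for very sparse subgroups the approximation is
  untested.
* The RW2 smoothness integration uses a fixed grid; posteriors
  concentrating outside (0.005, 1.5) on the SD scale would be clipped.
* The exclusion cascade defines duplicates as full-field equality
  (including the record id, which injected duplicates share) -- the
  conservative reading where the source system copies whole records.
  Genuinely distinct same-day re-admissions of one patient are *not*
  duplicates and are retained.
* Holiday coding is 1 = holiday internally; the inverse administrative
  coding (0 = holiday) is available as `holiday_coding = "inverse"` and
  flips only the holiday coefficient's sign.
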