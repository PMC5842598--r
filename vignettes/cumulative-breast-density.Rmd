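---
title: "Cumulative breast density and the two-stage model of breast carcinogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative breast density and the two-stage model of breast carcinogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbdens)
```

## The problem

Percent mammographic density (PMD) — the fraction of the mammographic
breast area occupied by radiodense fibroglandular tissue — is one of the
strongest known risk factors for breast cancer, yet it *decreases* with age
while incidence *increases*. The paradox dissolves if PMD is read as the
intensity of an exposure that accumulates: each year lived with dense
breast tissue contributes to a running total, and it is the total, not the
current level, that tracks the age-incidence curve.

`cbdens` implements that construction and the carcinogenesis model that
motivates it:

1. **Calibration** of MR percent breast water (the density proxy used in
   women too young for mammography) to a mammographic-density equivalent.
2. **Cumulative breast density (CBD)**: per-age-bin median density times
   bin width ("breast density years"), accumulated from age 15.
3. **Power-law incidence models**: log-log regressions of age-specific
   incidence on age, on CBD, and on both.
4. **Two-stage clonal expansion (TSCE) model**: the Moolgavkar framework in
   which susceptible cells mutate (rate $\mu_1$) to intermediate cells that
   divide ($\alpha_2$), die or differentiate ($\beta_2$), and mutate again
   ($\mu_2$) to malignancy, with a deterministic detection lag.
5. **Synthetic data** so the entire pipeline is testable without registry
   or cohort data, none of which is redistributable.

## Calibration

The shipped mapping from percent water $w$ to density equivalent is the
hyperbola

$$\widehat{\mathrm{PMD}}(w) = a - b/w, \qquad a = 80.00813,\; b = 1365.42571,$$

clamped to $[0, 100]$. It is linear in $1/w$, so `fit_calibration()` is
ordinary least squares of density on reciprocal water — no robust
alternative is offered, since the reference pairing (100 women measured by
both modalities) is not published and nothing is known about its outliers.
Predictions rise steeply at low water and saturate towards $a$; the root
$w = b/a \approx 17.1$ is the water content below which the predicted
equivalent is 0. Out-of-range predictions are clamped rather than
rejected, because downstream code needs a total function on $(0, \infty)$.

```{r calibration}
m <- default_calibration()
apply_calibration(m, c(20, 35, 50, 80))
```

## The CBD table

`default_bins()` gives the fourteen 5-year bins 15–19 … 80+ in which
registry incidence is reported. Bins are half-open and lower-inclusive
(age 20 belongs to 20–24); the paper's table is silent on boundaries, and
this is the convention registries use. The open-ended 80+ bin carries
width 5, because the reference table multiplies its median by 5. Medians
of even-count bins use the midpoint convention. Ages below 15 are
excluded.

For bin $j$ with median density $m_j$ and width $w_j$, density-years are
$m_j w_j$ and

$$\mathrm{CBD}(t) = \sum_{j : \text{bin } j \text{ ends} \le t} m_j w_j
  \;+\; m_{j(t)} \cdot (t - \text{start of bin } j(t)),$$

i.e. linear interpolation within the current bin, saturating at the end of
the last bin (age 85). Accumulating the published medians
(51.7 … 15.2) gives a final value of 2308.0 against the printed 2308.1:
the printed table evidently used unrounded medians upstream, and the
package recomputes from the published (rounded) values rather than trying
to reproduce hidden digits. Per-row recomputed density-years agree with
the printed column within 0.2 and the cumulative column within 0.5.

```{r cbd}
spec <- default_cohort_spec()
cohort <- generate_cohort(spec, seed = 1)
tab <- cbd_table(cohort, quiet = TRUE)
tab
```

## Incidence models

`fit_log_log()` regresses $\log$ rate on $\log$ predictor(s) by unweighted
OLS — the source analysis reports no person-years weighting, so weighting
is available only behind the `weights` argument for sensitivity analysis.
`compare_models()` fits the three candidate models (age; CBD; age + CBD)
and reports $r^2$ as the proportion of log-rate variance explained,
flagging whether adding age to CBD moves $r^2$ by more than a tolerance
(default $10^{-3}$).

Two conventions needed fixing where the source is silent:

* **Representative age per bin**: the bin's *upper* boundary by default
  (the exposure accumulated through the interval's end is what CBD(t)
  measures), with `"midpoint"` as the alternative.
* **The open 80+ bin** has no upper boundary; its representative age
  defaults to 82.5 (midpoint of a closed 80–85 bin), configurable via
  `open_bin_age`.

A saturated fit (bins = coefficients) is allowed and reports $r^2 = 1$:
two bins determine a one-predictor power law exactly.

```{r fit}
inc <- generate_incidence(tab, c0 = 2e-8, k = 3.5, noise = "poisson",
                          person_years = 1e7, seed = 1)
compare_models(inc, tab)
```

Because the model is fitted on logs, multiplying all rates by a constant
moves only the intercept, and the two-predictor model's $r^2$ can never
fall below either nested model's.

## The two-stage model

The susceptible-cell trajectory $X(t)$ is deterministic and piecewise
linear: zero before menarche, a linear ramp to a plateau over
`ramp_years`, multiplied by `parity_factor` at each birth and by
`menopause_factor` at menopause. The functional form the original
application used for these reproductive modifiers is not reproduced in the
source; this trajectory is a configurable stand-in, and its defaults
(plateau $10^7$ cells, 5-year ramp, 0.95 per birth, 0.5 at menopause, lag
5 years) are illustrative, not estimates. Normal-cell division/death
rates ($\alpha_1$, $\beta_1$) are carried in `tsce_params` but never
simulated, consistent with using $F(t)$ as a deterministic input.

With $F(t) = \int_0^t X(s)\,ds$ (exact on the segments), the hazard of
detection at age $t$ with lag $\tau$ is approximately

$$I(t) \approx \mu_1 \mu_2 F(t - \tau).$$

`expansion_hazard()` extends this with net clonal growth
$g = \alpha_2 - \beta_2$:

$$h(t) = \mu_1 \mu_2 \int_0^{t-\tau} X(s)\, e^{g\,(t - \tau - s)}\, ds,$$

again integrated in closed form segment by segment (the antiderivative of
a linear function against an exponential kernel); at $g = 0$ the code path
collapses exactly onto the approximation.

`simulate_tsce()` is the stochastic counterpart: first mutations arrive as
a nonhomogeneous Poisson process with intensity $\mu_1 X(t)$ (thinning
against the trajectory's maximum, which a piecewise-linear $X$ attains at
a knot), each founding an independent intermediate clone simulated
event-by-event as a birth/death/mutation branching process. A clone
passing `clone_cap` cells (default $10^6$) flags the subject rather than
looping; only the first tumor per subject counts. Everything is
reproducible from the `seed` argument.

In the *no-expansion regime* ($\alpha_2 = \beta_2 = 0$) intermediate cells
neither divide nor die and the analytic survival
$1 - \exp(-\int_0^t \mu_1\mu_2 F)$ is essentially exact (the residual
approximation error, of relative order $\mu_2 \tau_{\text{exposure}}$, is
kept well below Monte-Carlo noise at the test parameters). This is the
simulator's primary validation surface.

```{r tsce}
profile <- reproductive_profile(plateau_cells = 100)
params <- tsce_params(mu1 = 5e-3, mu2 = 2e-4, lag_tau = 5)
sim <- simulate_tsce(params, profile, n_subjects = 2000, horizon = 80,
                     seed = 1)
traj <- build_trajectory(profile)
c(simulated = mean(!is.na(sim$tumor_age)),
  analytic = cumulative_incidence_approx(params, traj, 80))
```

Tests use a *scaled* world — plateau 100 cells with
$\mu_1 = 5\times10^{-3}$, $\mu_2 = 2\times10^{-4}$ — chosen once so that
$\mu_1\mu_2 \cdot \text{plateau}$ gives hazards of registry magnitude
(hundreds per 100,000 person-years) while a 10,000-subject simulation runs
in about a second. The simulator-vs-analytic comparison is
scale-invariant in this regime, so nothing is lost by not simulating
$10^7$ cells.

## What the synthetic data do and do not establish

`generate_cohort()` is **median-exact**: within each bin, values are
placed as antithetic $\pm$ pairs around the target median (plus one value
exactly at the median for odd counts), so the sample median equals the
target for *every* seed. The published table is thereby an exact
acceptance surface, not an approximate one — appropriate because medians
are the only distributional feature the pipeline uses. Perturbation
magnitudes are truncated symmetrically so values stay in $[0,100]$ and,
for MR bins, so the inverted water value stays in $(0,100]$; truncation
(rather than reject/resample) keeps the median exact deterministically.
Ages are uniform within bins; the true within-bin dispersion of the source
population is unreported, so the default `noise_sd = 5` percent is a
placeholder.

What a green test therefore establishes: the arithmetic of calibration,
binning, medians, density-years, accumulation, and the model fits. What
it does not: anything about real within-bin density distributions,
measurement error, secular trends, or the longitudinal density trajectory
of any individual (the design is cross-sectional).

`generate_incidence()` draws rates from a power law in CBD (or from the
TSCE hazard), with optional lognormal noise or Poisson case counts. One
numerical caveat found while validating: fitting logs of Poisson-sampled
rates is biased when expected counts are small (Jensen's inequality), so
the scale `c0` in tests is set to give expected counts of registry
magnitude ($\gtrsim 50$ per bin).

## Reproducing the headline association

The published analysis reports a power-law exponent $k = 3.5$ with
$r^2 = 0.99$ for log incidence on log CBD using Canadian registry rates
(Cancer Incidence in Five Continents Vol. IX). That table is not
redistributable and is not bundled; users who have it can run

```r
inc <- read_incidence("canadian_rates.csv")
compare_models(inc, cbd_table(cohort))
```

to reproduce the comparison. The package's self-contained checks
exercise the identical machinery on synthetic rates generated from CBD
with $k = 3.5$.

## Numerical choices and limitations

* Half-open bins, lower-inclusive; midpoint medians for even counts;
  80+ bin width 5; ages under 15 excluded.
* Calibration outputs clamped to $[0,100]$; the hyperbola is shipped with
  the printed coefficients because the paired data behind them are not
  published and cannot be re-derived.
* All integrals of and against $X(t)$ are closed-form on the trajectory's
  segments — no quadrature error anywhere in the analytic path;
  trapezoid quadrature appears only as an independent oracle in tests.
* `empirical_hazard()` censors at the horizon; a bin with zero
  person-years reports a missing rate rather than zero.
* No parameter estimation for $(\mu_1, \mu_2, \alpha_2, \beta_2)$ from
  real incidence data is provided, and no image analysis: inputs are
  already-measured percentages.
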