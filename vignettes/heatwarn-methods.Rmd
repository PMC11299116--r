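---
title: "Methods and modelling choices in heatwarn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in heatwarn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatwarn)
```

`heatwarn` models daily heatstroke counts as a function of lagged,
non-linear heat exposure, and turns fitted risk into an operational warning
schedule. This vignette documents the statistical model, the defaults and
why they were chosen, what the synthetic generator does and does not
emulate, and the numerical decisions a maintainer would want written down.

## The distributed lag non-linear model

The core regression is a quasi-Poisson time-series model

$$\log E[Y_t] = \alpha + cb(x_t, \mathrm{lag}) + ns(\mathrm{date}, df) +
\mathrm{dow} + \mathrm{holiday},$$

where $Y_t$ is the daily count and $cb$ the cross-basis: for exposure
basis functions $w_j$ and lag basis functions $C_k$,

$$cb_{t,(j,k)} = \sum_{l=0}^{L} w_j(x_{t-l})\,C_k(l).$$

A coefficient vector over these columns encodes a full exposure-lag risk
surface. Relative risks are contrasts against a reference exposure
$x_{ref}$: $RR(x, l) = \exp\{[w(x) - w(x_{ref})] \otimes C(l)\cdot
\beta_{cb}\}$, and the cumulative RR sums the log-contrast over the lag
grid first. By construction $RR(x_{ref}, l) = 1$ at every lag, which the
test suite asserts for every fit.

Choices that the model text leaves open, and what this package does:

* **Lag basis.** Polynomial in the lag, default degree 4 over lags 0..30.
  Lags are scaled to $[0,1]$ and the power columns are QR-orthonormalised
  over the full lag grid; the transform is frozen in the spec so that
  evaluation at prediction time matches construction exactly. Predictions
  are invariant to this reparameterisation — it exists purely for
  conditioning (raw fourth powers of lag 30 span five orders of
  magnitude).
* **Exposure basis.** A natural cubic spline with df = 4 and
  quantile-placed interior knots is the default, matching standard DLNM
  practice for smooth J-shaped heat-response curves; polynomial and
  threshold-linear (hinge) alternatives are available. The spline is the
  truncated-power natural cubic basis, hand-assembled because the
  cross-basis needs explicit basis functions evaluable at arbitrary
  exposure values; tests verify it spans exactly the same function space
  as `splines::ns` (residuals < 1e-8 after mutual projection).
* **Seasonal control.** A natural spline on the within-study date index
  with df = 10 by default. This follows the convention of roughly
  two degrees of freedom per season for sub-seasonal trend control when
  five summer seasons are analysed; it is configurable.
* **Centering.** The reference exposure defaults to the sample median over
  rows with complete lag history — an interior point, so the identity
  $RR(ref) = 1$ is meaningful. It is configurable and a reference outside
  the observed range triggers a warning.
* **Family.** Quasi-Poisson by default (overdispersion is the norm for
  surveillance counts); the coefficient covariance is scaled by the
  Pearson dispersion. Plain Poisson is available; the two give identical
  point estimates, which is tested.
* **Incomplete lag histories.** The first `max_lag` rows of each
  contiguous date block are masked, never imputed; a calendar gap (winter
  between May–September seasons) starts a fresh block. Missing exposures
  inside a lag window likewise mask the row with a warning.
* **Weekday/holiday.** Weekday enters as six indicator contrasts with
  Monday as reference; holiday as a single indicator (dropped when no
  holiday falls in the series, to keep the design full-rank).
* **Confidence intervals.** Wald intervals on the log scale at 95 %
  (z = 1.96 via `qnorm`).

Fitting is IRLS through `stats::glm`. Rank deficiency is detected before
fitting and reported with the names of the collinear columns;
non-convergence is warned about and recorded in the fit object.

## Meteorological features

* **Heat index.** The 9-term apparent-temperature regression needs a
  concrete coefficient set; the package ships the NOAA/NWS Rothfusz
  coefficients, the de-facto standard realisation of this polynomial. They
  are Fahrenheit-native, so the computation runs in °F internally and all
  public interfaces are °C. Below the regression's applicability range
  (average of the simple formula and temperature under 80 °F) the NWS
  simple formula is used, plus the standard low-RH and high-RH
  adjustments. Coefficients live in a config object
  (`heat_index_coefs()`) so alternative sets can be swapped in.
* **Dew point.** Magnus formula with a = 17.27, b = 237.7 °C. At
  saturation the identity $T_d = T$ holds to machine precision, and tests
  pin the value at (30 °C, 70 %) against an independent evaluation.
* **Heatwaves.** A day is flagged iff it belongs to a maximal run of at
  least three consecutive calendar days with Tmax ≥ 35 °C. Runs cannot
  cross date gaps. The implementation is tested for equality with a
  brute-force oracle that enumerates every window.
* **Sanfu calendar.** The sanfu periods move with the lunisolar calendar,
  so they are a required configuration input with a validated schema
  (toufu and mofu exactly 10 days, zhongfu 10 or 20, ordered,
  non-overlapping) rather than dates hard-coded in the package. The
  shipped `sanfu_example.yaml` is synthetic, for demonstrations only.

## The synthetic generator

The generator exists so that every downstream stage can be checked against
known truth. Daily mean temperature is a seasonal sinusoid (default mean
26 °C, amplitude 4 °C, peak near day-of-year 207) plus AR(1) Gaussian
noise (innovation sd 2 °C, coefficient 0.6 — day-to-day weather is
autocorrelated); Tmax adds a positive offset (|N(5, 1.5²)|); relative
humidity is linearly anti-coupled to temperature (−1.5 % per °C around a
75 % base, noise sd 6 %) and clipped to [5, 100]. These values describe a
humid subtropical summer: mid-summer maxima around 35 °C, humid mornings,
drier heat spikes. Counts are Poisson with

$$\log \mu_t = \log(\mathrm{baseline}) + \beta \sum_l w_l \max(0,
x_{t-l} - \tau),$$

a threshold-linear surface chosen because heat-health risk typically shows
threshold behaviour with an approximately log-linear rise above it; the
weights $w_l$ sum to one so the cumulative RR of sustained exposure $x$
has the closed form $\exp\{\beta(x - \tau)\}$. The default baseline of 2
cases/day matches the scale of a single-city May–September surveillance
series. Equidispersed Poisson is the default; overdispersion can be
emulated by the user via the rate hook, and the quasi-Poisson fitter
estimates dispersion ≈ 1 on the default output (tested).

What the generator does **not** emulate: spatial structure, humidity
microphysics (RH is a linear-Gaussian proxy), reporting artefacts
(weekday effects in the counts, outbreak clusters), and long-range climate
trends. Passing recovery tests on this data therefore demonstrates
correctness of the estimation machinery — not that the model is adequate
for any particular city's real series.

Determinism: every draw flows from the configured seed; generators save
and restore the global RNG state so simulation cannot silently perturb a
user's session, and identical configurations are bit-identical (tested).

Burn-in: within each season the first `max_lag` days are generated with
truncated lag sums and flagged `burn_in = 1`, to be excluded from fitting.
This is simpler and more honest than wrap-around padding.

## Parameter recovery, and the scales used

Tests fit the DLNM to data from the threshold-linear surface (slope 0.05
above 30 °C, geometric weights over lags 0–5) at five seasons
(~765 days) and check that the 95 % interval for the cumulative RR at a
sustained 35 °C covers the truth $e^{0.25} \approx 1.284$ in at least
90 of 100 replicates. Five seasons, lag 5, and a degree-2 lag polynomial
keep one replicate around a tenth of a second, so the replicated study
runs comfortably inside a routine test session; the fitted exposure basis
is the default df-4 natural spline — deliberately *not* the generating
hinge — so the check also exercises smooth-basis approximation of a
kinked truth. The reference for these contrasts is 28 °C: any
sub-threshold reference leaves the closed-form truth unchanged.

## Boruta selection

The shadow-feature loop is implemented from scratch: each iteration
permutes every active feature into a shadow copy (padded to at least five
shadows so the percentile is stable), fits a `ranger` forest with
depth 4 (trees this shallow are the recommended regime for shadow
comparisons) and impurity importance, and scores a hit when a real
feature's importance exceeds the shadow maximum (perc = 100). Binomial
bookkeeping at α = 0.05 then promotes or demotes features: the two-step
scheme combines a Benjamini–Hochberg pass across features with a
Bonferroni correction over the iterations run so far; the single-step
alternative is a Bonferroni over the feature count. The automatic tree
count is $100 \cdot 2p / (\sqrt{2p}\,d)$ for $p$ features and depth $d$,
keeping the expected attention per column roughly constant.

A property of this procedure worth knowing: with enough iterations it
confirms any feature whose *in-sample* association consistently beats
freshly permuted shadows — including chance correlations of $|r| \approx
0.05$ at $n = 500$. This is inherent to shadow-importance comparison with
greedy forests (a reference scikit-learn implementation of the same loop
shows identical behaviour on identical data), not an implementation
artefact; the test suite therefore checks that false confirmations under
a null target are rare in aggregate rather than impossible, while the
power requirement (a real signal confirmed, noise not) is enforced
strictly.

## Prediction suite and metrics

The six model families are handled in two groups. Tabular learners —
CART regression tree, the bagged random forest, gradient-boosted trees
(`xgboost`), linear SVR (`e1071`) — are trained once on the training
years and predicted statically on the validation year. The random forest
is bootstrap aggregation of `rpart` trees with all features available at
every split (for regression this matches the scikit-learn default of
max_features = 1.0, which is what the printed hyper-parameters — depth 4,
min leaf 1, min split 4, 13 trees — presume); its prediction is the
plain mean over trees, and a one-tree forest provably equals its
constituent tree. ARIMA is a rolling one-step-ahead forecaster: refit on
the history through day $t-1$ to predict day $t$, with the order chosen
by AIC over the grid $p, q \le 2$, $d \le 1$ (the model text names no
order; the grid is deliberately small and documented). LSTM is out of
scope as a heavy optional dependency; requesting it raises an informative
error.

Metrics are MSE, RMSE = √MSE and $R^2 = 1 - SS_{res}/SS_{tot}$; a constant
observed series makes $R^2$ undefined, which is reported as `NA` with a
warning rather than silently. Percentage shares for descriptive tables are
rounded half-up to two decimals (base R's banker's rounding would turn
0.005 into 0.00, which never matches reported epidemiological tables).

Grid search is exhaustive with ties broken by first-in-grid order, making
selection deterministic. The sensitivity analysis perturbs one feature at
a time by a configured delta on the validation table and reports metric
deltas against the unperturbed baseline; a feature a tree ensemble never
split on yields exactly zero delta.

On the default synthetic scale (counts averaging ~2–3/day), most daily
variance is Poisson noise, so validation $R^2$ for the tabular models is
small — the suite's tests assert ordering and coherence properties
(forest beats the mean predictor under a strong exposure signal, RMSE² =
MSE, determinism), not a specific $R^2$.

## Warning engine

The composite mechanism is deterministic, rule by rule:

1. predicted count above the trigger → warning that day;
2. additionally any driver above threshold (HI > 30 °C, Td > 23 °C,
   Tmax > 35 °C) → reinforced warnings on that day and the next four
   (five consecutive days);
3. RH < 65 % → warnings on the 20th–25th day after;
4. RH > 85 % → warnings on the 22nd–28th day after.

Open design points and how they are resolved: the delayed humidity rules
act independently of the count trigger (the mechanism text ties them to
"that day" but does not require the count condition on the delayed days;
conjunction would be a guess, so independence is implemented and
documented). The 65–78 % humidity band's short-lag risk is covered by
rule 2's same-day reinforcement rather than a separate delayed rule. Both
delayed windows are inclusive. Overlaps merge to the highest level
(reinforced > warning) and every emitted date lists the rules and origin
dates that produced it, so any warning is traceable. Delayed warnings
past the end of the series are emitted as future-dated entries — an
operational system wants tomorrow's schedule, not just today's.

The count trigger has no universal value; the default used by the
pipeline is the 90th percentile of training-period counts, explicit in
the run log. Under the default synthetic conditions predicted counts
rarely clear that bar (predictions are conditional means, flatter than
the counts), so most warnings in the demo pipeline come from the humidity
rules; this is the honest behaviour of the mechanism at that
signal-to-noise, not a defect.

## Known limitations

* The seasonal spline and the exposure cross-basis compete for
  low-frequency variance; with few seasons and strongly seasonal
  exposure, cumulative RR estimates carry a mild upward bias at the
  default df = 10 (visible as mean recovered RR ≈ 1.3 against a truth of
  1.284 — inside sampling error but systematic in direction).
* The Boruta null-behaviour above: all-relevant selection is relevance
  *to the sample*, not to the population.
* Rolling ARIMA refits once per validation day; for multi-year validation
  spans this is the dominant cost of the suite.
* The warning engine consumes point predictions; predictive intervals
  (which would let the trigger account for forecast uncertainty) are not
  implemented.
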