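---
title: "Interrupted time series analysis of prescribing rates: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interrupted time series analysis of prescribing rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itsar)
```

## The problem

A drug regulator issues a safety advisory about a medicine; did prescribing
change? The quasi-experimental design of choice is the interrupted time
series (ITS): model the monthly utilisation rate over a window around the
advisory and ask whether the series' level and trend shifted at the
intervention. `itsar` implements this pipeline for monthly prescribing
rates (prescriptions per 100 000 population), with the estimation machinery
that drug-utilisation studies conventionally use: segmented regression with
month-of-year seasonal dummies, autoregressive (AR) errors fitted by
Yule-Walker feasible generalized least squares, a counterfactual obtained
by extrapolating the pre-advisory trend, percentile-bootstrap confidence
intervals on the mean percentage change in use, and the Altman-Bland test
for interaction when two subgroups are compared.

Real claims-database inputs of this kind (national pharmacy claims, GP
prescribing databases) are access-restricted, so the package ships a
synthetic-data generator that reproduces the statistical structure the
analysis assumes. All tests run end-to-end on generated panels.

## The model

For included month $t$ (indexed in calendar months from the series start),
the rate $y_t$ follows

$$
y_t = \beta_0 + \beta_1\,time_t + \beta_2\,step_t + \beta_3\,ptrend_t
      + \sum_{m \ne m_0} \gamma_m I(\text{month}_t = m) + e_t ,
$$

with AR($p$) errors $e_t = \sum_{j} \phi_j e_{t-j} + \nu_t$,
$\nu_t \sim (0, \sigma^2)$. The four structural terms are the modelled
level at the series start ($\beta_0$), the baseline monthly change
($\beta_1$), the abrupt change in level at the advisory ($\beta_2$) and the
additional monthly change after it ($\beta_3$); the $\gamma_m$ are
month-of-year offsets. The canonical window is 24 months before the
advisory and 11 after, with the advisory month itself excluded as a
*transition month*: exposure within it is mixed, so it contributes no row
to the fit, but the calendar spacing of the time codes is preserved (the
exclusion removes an observation, not a month).

### Coding choices

Three codings were genuinely open and are fixed (with switches) as follows.

* **Time origin.** `time = 0` at the first included month, so $\beta_0$ is
  the modelled level at the series start rather than a mid-series value —
  the natural anchor when reporting "level in the first study month".
* **Post-trend start.** `post_trend` is 1 (not 0) in the first modelled
  post-advisory month. With the transition month excluded, this keeps
  $\beta_2$ and $\beta_3$ separately identified and makes $\beta_2$ the
  displacement at the first post month net of one month of the new slope.
  `study_design(post_trend_start = 0)` selects the alternative coding.
* **Seasonal reference.** January is the omitted month, arbitrarily but
  reproducibly; predictions, fitted values and all effect estimates are
  invariant to this choice (a property the test suite checks), only the
  individual $\gamma$ coefficients change.

## Estimation

Estimation is two-step feasible GLS in the Yule-Walker tradition:

1. OLS on the segmented design.
2. **Detection.** Generalized Durbin-Watson statistics
   $d_j = \sum_{t>j}(e_t-e_{t-j})^2 / \sum_t e_t^2$ screen the OLS
   residuals for autocorrelation at lags $1..13$ (capped at $n/4$). Each
   $d_j$ is compared with its exact null mean and variance — the first two
   moments of the ratio of quadratic forms in the residuals of the actual
   design matrix — via a normal approximation, Bonferroni-corrected across
   lags. The correction matters: testing 13 lags at 5% each would flag
   pure white noise about half the time, while the familywise screen keeps
   the false-detection rate near 5%.
3. **Order selection.** Where autocorrelation is detected, backward
   stepwise autoregression prunes the full lag set: Yule-Walker fits at
   the current lags, the least significant $\hat\phi_j$ (approximate
   t-statistic from the Yule-Walker information matrix) is dropped while
   its p-value exceeds `alpha`, with ties resolved by dropping the higher
   lag and infeasible (non-stationary or singular) subsets resolved by
   shedding their highest lag.
4. **Whitening.** With $\hat\phi$ from the retained lags, response and
   design are transformed by the AR innovations filter; the first $p$
   observations are premultiplied by the inverse Cholesky factor of their
   stationary covariance rather than dropped — at $n = 35$, discarding
   rows is wasteful.
5. OLS on the whitened data yields $\hat\beta$, standard errors and
   two-sided t p-values with $df = n - k_{\text{regression}} - k_{AR}$,
   matching the usual accounting for estimated AR parameters.

The reported **total $R^2$** is $1 - SSE/SST$ where the SSE uses one-step-
ahead predictions including the AR forecast of the error
($\hat e_t = \sum_j \hat\phi_j \hat u_{t-j}$, zero where history is
unavailable), so it measures the combined structural + AR model; with no
retained lags it reduces to the OLS $R^2$. Stationarity of $\hat\phi$ is
enforced (all roots of $1-\sum\hat\phi_j z^j$ outside the unit circle);
non-stationary solutions raise an error rather than propagate.

## Effect estimation

The counterfactual rate for each post-advisory month is the deterministic
prediction with `step` and `post_trend` forced to zero — the pre-advisory
level, trend and seasonal profile extrapolated across the post window. The
headline effect is the arithmetic mean over post months of
$100\,(actual_t - expected_t)/expected_t$. By default `actual` is the
model's own deterministic post-period prediction (*fitted* mode): the
comparison is trend versus trend, which is what "change from the
extrapolated baseline trend to the observed trend" describes; *observed*
mode (raw rates in the numerator) is available as a switch.

Confidence intervals come from a residual (innovation) bootstrap:

* the base fit's structural residuals are whitened to innovations,
  centred, and rescaled by $\sqrt{n/df}$ — with 15 regression columns at
  $n = 35$ the raw residual variance understates the innovation variance
  substantially, and unscaled resampling would shrink every interval;
* each iteration resamples innovations with replacement, rebuilds an error
  series through the AR recursion with the base $\hat\phi$ (100-step
  burn-in so errors start in the stationary regime), adds the base
  deterministic fit, and refits with the AR lags frozen at the base
  selection (re-selection per iteration adds instability at this series
  length);
* the 95% interval is the 2.5th/97.5th percentile of the draws, with
  linear interpolation between order statistics (type-7 quantiles).

Case resampling is deliberately not offered — shuffling (month, rate)
pairs destroys the time ordering an ITS rests on. A moving-block variant
(blocks of 3 structural residuals) is provided as a robustness switch for
the case where the AR structure is suspected but not detected.

Subgroup contrasts use the Altman-Bland test for interaction: difference
of the two percentage changes, standard error $\sqrt{SE_1^2+SE_2^2}$,
normal 95% CI and two-sided normal p-value. When bootstrap draws are
available their standard deviation is the SE (the fuller use of the
bootstrap distribution); otherwise the SE is recovered from a reported 95%
interval as width$/(2 \times 1.959964)$.

## The synthetic-data generator

`simulation_config()` encodes the data-generating process; its defaults are
the package's reference study conditions and are deliberately not tuned per
experiment:

| parameter | default | why |
|---|---|---|
| window | 24 pre + transition + 11 post months from 2009-07 | canonical advisory window |
| $\beta$ | (182.03, -0.178, -13.12, -2.53) | realistic Australian national prescribing scale |
| seasonal amplitude | 10 (peak-to-trough, rate units) | mild seasonality, ~5% of the level, typical of chronic-therapy dispensing |
| $\phi$ | 0.5 | moderate positive monthly autocorrelation |
| innovation SD | 5 rate units | puts total $R^2$ near the ~0.95-0.99 range such series exhibit |
| population | 1 000 000 | round denominator; only ratios matter on the rate scale |

Noise is Gaussian on the rate scale by default, matching the model's own
error structure; a Poisson-on-count mode (counts drawn with mean
$population \times rate / 10^5$, rates recomputed) probes robustness to
count noise. Errors are drawn through the AR recursion with a 100-step
burn-in. Each simulated series carries its analytically implied true mean
percentage change — the estimand the pipeline targets — computed in closed
form from the configuration, which is what the coverage and recovery
checks compare against.

What the generator does *not* emulate: prescriber behaviour and switching
to substitute medicines, claims-processing lags between supply and
recording, population drift within the window, and co-interventions.
Passing tests therefore demonstrate that the estimation machinery recovers
the parameters of its own model class at realistic scales — not that the
model class captures everything in real claims data.

## Known limitations

* **Small-sample attenuation of $\hat\phi$.** With 15 regression columns
  in 35 observations, OLS residuals substantially understate the error
  autocorrelation, and Yule-Walker estimates inherit that attenuation;
  the Durbin-Watson screen also has limited power in this regime. The
  consequence, visible in the package's own simulations, is that
  bootstrap intervals computed under a partially detected AR structure
  are narrower than the true sampling spread of the effect estimate when
  errors are genuinely autocorrelated at $\phi \approx 0.5$. This is a
  property of the conventional two-step Yule-Walker ITS toolchain at this
  series length, not of a particular implementation; interval coverage
  and interaction-test calibration at these conditions are reported
  honestly by the test suite rather than patched over.
* Exactly one interruption per analysis; no multiple-advisory designs.
* No maximum-likelihood or exact-ML AR estimation, no seasonal ARIMA, no
  heteroscedasticity corrections, and no BCa/studentised bootstrap — the
  scope is the conventional Yule-Walker ITS toolchain.

## Problem sizes used by the test suite

Simulation-based checks use 200-1000 replicates per property and bootstrap
sizes of 100-1000 inside simulations (5000 for the worked analyses),
chosen to keep Monte-Carlo error well below the property margins being
checked. The numbered scripts under `analysis/` run the full pipeline —
simulate, fit, estimate effects, compare subgroups — at the canonical
study scale and write their tables under `results/`; they are the
package's command-line entry points.
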