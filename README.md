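# itsar — interrupted time series analysis of prescribing rates with AR errors

`itsar` quantifies the impact of a drug safety advisory (or any single,
dated intervention) on monthly medicine-utilisation rates. It is written
for pharmacoepidemiologists running interrupted time series (ITS) analyses
of prescribing panels — prescriptions per 100 000 population per month,
split by jurisdiction, sex or age band — where the question is: *by how
much did use change after the advisory, relative to what the pre-advisory
trend predicted, and did that change differ between subgroups?*

## The model

For included month *t*, the rate follows the segmented regression

  y_t = β₀ + β₁·time_t + β₂·step_t + β₃·ptrend_t + Σ_m γ_m·I(month_t = m) + e_t

with AR(p) errors e_t = Σ_j φ_j e_(t−j) + ν_t. β₀ is the level at the
series start, β₁ the baseline monthly change, β₂ the level change at the
advisory, β₃ the additional monthly change after it; γ_m are month-of-year
seasonal offsets. The advisory month itself is a *transition month*:
excluded from fitting (mixed exposure) while calendar spacing is kept.
Estimation is Yule-Walker feasible GLS: generalized Durbin-Watson tests
screen for residual autocorrelation, backward stepwise autoregression
picks the AR lags, and the model is refitted on exactly whitened data.
The advisory effect is the mean percentage change over the post window
between the model's post-advisory trend and the counterfactual obtained by
extrapolating the pre-advisory terms, with 95% percentile confidence
intervals from a residual (innovation) bootstrap and Altman-Bland
interaction tests between subgroup effects.

Because the claims databases such analyses run on are access-restricted,
the package includes a synthetic-data generator
(`simulation_config()` / `simulate_series()` / `simulate_panel()`) that
reproduces the statistical structure the analysis assumes — segmented
trend, seasonality, stationary AR errors, Gaussian-on-rate or
Poisson-on-count noise — and attaches each series' analytically true
effect, so the whole pipeline is testable end to end.

## Worked example

```r
library(itsar)

# a jurisdiction-level series at a realistic Australian national scale
cfg <- simulation_config("all", beta = c(182.03, -0.178, -13.12, -2.53),
                         phi = 0.5, innovation_sd = 5, seed = 19)
s   <- simulate_series(cfg)
des <- study_design("2011-07", n_pre = 24, n_post = 11)

fit <- fit_its(s, des)
fit
#> <its_fit> n = 35, df_resid = 19, AR lags {1}, total R^2 = 0.9222
#>              estimate        se        p
#> intercept  191.3927307 5.7749208 2.82e-18
#> time        -0.3474254 0.3301364 3.06e-01
#> step        -9.8763968 8.7991701 2.76e-01
#> post_trend  -2.5973458 1.0778745 2.63e-02
#> phi: lag1=0.423

eff <- bootstrap_effect(s, des, n_boot = 5000, seed = 7)
eff
#> <its_effect> mean % change = -14.30% (95% CI -20.77 to -6.70), n_boot = 5000, seed = 7
```

Reading the output: the fitted level at July 2009 is ~191 prescriptions
per 100 000; the Durbin-Watson screen detected residual autocorrelation
and backward stepwise autoregression retained lag 1 (φ̂ = 0.42), so the
coefficients come from the whitened (feasible GLS) fit. The advisory month
brings a drop of ~10 with a further −2.6/month thereafter. Averaged over
the 11 post-advisory months, use sits 14.3% below what the extrapolated
pre-advisory trend predicts (95% percentile CI −20.8% to −6.7%). The
generator's analytic truth for this configuration is −15.95%
(`attr(s, "true_effect")`), comfortably inside the interval. Subgroups are
compared with
`compare_effects(eff1, eff2)`, which applies the Altman-Bland z-test to
the difference of the two percentage changes.

## The analysis workflow

The numbered scripts under `analysis/` run the full study on a simulated
panel and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1   # panel.csv + analytic truth sidecar
Rscript analysis/02_fit.R          # coefficients.csv, diagnostics.csv
Rscript analysis/03_effects.R 1    # effects.csv, effects_by_month.csv
Rscript analysis/04_compare.R 1    # interactions.csv (sex and age contrasts)
```

The trailing integer seeds the simulation/bootstrap randomness.

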