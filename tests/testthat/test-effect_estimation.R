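# Build a noiseless fit with exactly known coefficients by generating the
# response from the design matrix itself.
fit_with_beta <- function(beta4, gamma = rep(0, 12), seasonal = FALSE) {
  cfg <- simulation_config(beta = beta4, gamma = gamma, phi = 0,
                           innovation_sd = 0, seed = 1L)
  s <- simulate_series(cfg)
  fit_its(s, design_for(cfg, seasonal = seasonal))
}

test_that("counterfactual extrapolates the baseline with advisory terms zeroed", {
  # flat baseline: expected 100 every post month regardless of the drop
  f <- fit_with_beta(c(100, 0, -20, 0))
  expect_equal(unname(counterfactual(f)), rep(100, 11), tolerance = 1e-8)

  # declining baseline: post months sit at time 25..35, expected 175..165
  f2 <- fit_with_beta(c(200, -1, 0, 0))
  expect_equal(unname(counterfactual(f2)), 200 - (25:35), tolerance = 1e-8)

  # seasonal offset carries into the counterfactual
  gam <- rep(0, 12); gam[8] <- 10 # August
  f3 <- fit_with_beta(c(100, 0, 0, 0), gamma = gam, seasonal = TRUE)
  cf <- counterfactual(f3)
  aug <- grepl("-08$", names(cf))
  expect_equal(unname(cf[aug]), 110, tolerance = 1e-7)
  expect_equal(unname(cf[!aug]), rep(100, 10), tolerance = 1e-7)

  # non-positive counterfactual is a domain error: force a level low enough
  # that the extrapolated baseline crosses zero inside the post window
  f4 <- f2
  f4$beta["intercept"] <- 20
  expect_error(counterfactual(f4), "counterfactual-domain")
})

test_that("mean percentage change matches direct month-by-month evaluation", {
  # constant -17% every post month
  f <- fit_with_beta(c(100, 0, -17, 0))
  expect_equal(as.numeric(pct_change(f)), -17, tolerance = 1e-8)

  # symmetric deviations cancel: observed post rates alternate 90/110 about
  # an exactly flat counterfactual of 100 (fit taken from the noiseless flat
  # series, observations then perturbed)
  cfg <- simulation_config(beta = c(100, 0, 0, 0), gamma = rep(0, 12),
                           phi = 0, innovation_sd = 0, n_post = 4, seed = 1L)
  s <- simulate_series(cfg)
  f2 <- fit_its(s, design_for(cfg, seasonal = FALSE))
  dstar <- build_design(s, design_for(cfg, seasonal = FALSE))
  dstar$y[dstar$is_post] <- c(90, 110, 90, 110)
  expect_equal(as.numeric(pct_change(f2, dstar, mode = "observed")), 0,
               tolerance = 1e-8)

  # the level-drop / slope-change pattern of the Australian overall series
  # on a flat baseline of 182: mean over 11 post months of
  # 100 * (-13.12 - 2.53 k) / 182, k = 1..11
  f3 <- fit_with_beta(c(182, 0, -13.12, -2.53))
  by_hand <- mean(100 * (-13.12 - 2.53 * (1:11)) / 182)
  expect_equal(by_hand, -15.54945054945, tolerance = 1e-9)
  expect_equal(as.numeric(pct_change(f3)), by_hand, tolerance = 1e-8)

  # per-month table has one row per post month
  pm <- attr(pct_change(f3), "per_month")
  expect_equal(nrow(pm), 11)
  expect_equal(pm$pct, 100 * (-13.12 - 2.53 * (1:11)) / 182,
               tolerance = 1e-8)
})

test_that("fitted and observed modes differ only in the numerator series", {
  cfg <- simulation_config(seed = 5L)
  s <- simulate_series(cfg)
  f <- fit_its(s, design_for(cfg))
  pf <- pct_change(f, mode = "fitted")
  po <- pct_change(f, mode = "observed")
  expect_false(isTRUE(all.equal(as.numeric(pf), as.numeric(po))))
  expect_equal(attr(pf, "per_month")$expected, attr(po, "per_month")$expected)
  expect_equal(attr(po, "per_month")$actual,
               build_design(s, design_for(cfg))$y[build_design(s, design_for(cfg))$is_post])
})

test_that("bootstrap is deterministic given a seed and collapses without noise", {
  cfg <- simulation_config(seed = 7L)
  s <- simulate_series(cfg)
  d <- design_for(cfg)
  # (the estimator may legitimately warn when the point estimate falls just
  # outside the percentile bounds at small n_boot; irrelevant to determinism)
  e1 <- suppressWarnings(bootstrap_effect(s, d, n_boot = 200, seed = 99))
  e2 <- suppressWarnings(bootstrap_effect(s, d, n_boot = 200, seed = 99))
  expect_identical(e1$ci_low, e2$ci_low)
  expect_identical(e1$ci_high, e2$ci_high)
  expect_identical(e1$draws, e2$draws)

  # a different seed moves the interval (point may sit just outside the
  # percentile bounds at small n_boot, which the estimator flags)
  e3 <- suppressWarnings(bootstrap_effect(s, d, n_boot = 200, seed = 100))
  expect_false(identical(e1$ci_low, e3$ci_low))

  # noiseless series with an exact -17% effect: the interval is a point
  sn <- simulate_series(simulation_config(beta = c(100, 0, -17, 0),
                                          gamma = rep(0, 12), phi = 0,
                                          innovation_sd = 0, seed = 1L))
  en <- bootstrap_effect(sn, design_for(attr(sn, "config"), seasonal = FALSE),
                         n_boot = 100, seed = 1)
  expect_equal(en$pct_change, -17, tolerance = 1e-8)
  expect_equal(en$ci_low, -17, tolerance = 1e-6)
  expect_equal(en$ci_high, -17, tolerance = 1e-6)
})

test_that("percentile bounds equal the sort-and-interpolate quantile oracle", {
  cfg <- simulation_config(seed = 13L)
  s <- simulate_series(cfg)
  e <- bootstrap_effect(s, design_for(cfg), n_boot = 500, seed = 42)
  draws <- e$draws[!is.na(e$draws)]
  expect_equal(e$ci_low, quantile_oracle(draws, 0.025), tolerance = 1e-12)
  expect_equal(e$ci_high, quantile_oracle(draws, 0.975), tolerance = 1e-12)
  expect_true(e$ci_low <= e$pct_change && e$pct_change <= e$ci_high)
})

test_that("the bootstrap interval tracks the injected effect direction", {
  set.seed(23)
  neg <- vapply(1:25, function(i) {
    cfg <- simulation_config(beta = c(182.03, -0.178, -35, 0),
                             seed = 2300L + i)
    s <- simulate_series(cfg)
    f <- fit_its(s, design_for(cfg))
    as.numeric(pct_change(f)) < 0
  }, logical(1))
  expect_equal(mean(neg), 1)
})

test_that("the moving-block variant runs and respects the seed", {
  cfg <- simulation_config(seed = 17L)
  s <- simulate_series(cfg)
  d <- design_for(cfg)
  b1 <- bootstrap_effect(s, d, n_boot = 150, seed = 5, scheme = "block")
  b2 <- bootstrap_effect(s, d, n_boot = 150, seed = 5, scheme = "block")
  expect_identical(b1$draws, b2$draws)
  expect_true(is.finite(b1$ci_low) && b1$ci_low < b1$ci_high)
})

test_that("bootstrap preconditions are enforced", {
  cfg <- simulation_config(seed = 19L)
  s <- simulate_series(cfg)
  d <- design_for(cfg)
  expect_error(bootstrap_effect(s, d, n_boot = 50, seed = 1), "n_boot")
  expect_error(bootstrap_effect(s, d, n_boot = 200), "seed")
})
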