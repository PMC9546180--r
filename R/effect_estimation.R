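#' Counterfactual (extrapolated baseline) rates for the post period
#'
#' Deterministic prediction of the prescribing rate in each post-advisory
#' month had the advisory not been issued: the fitted intercept, baseline
#' trend and seasonal terms evaluated with the level-change and
#' post-trend terms forced to zero.
#'
#' @param fit an `its_fit`.
#' @param design the `segmented_design` the fit corresponds to; defaults to
#'   the one embedded in `fit`.
#' @return Numeric vector of expected rates, one per post-window month
#'   (named by month).
#' @export
counterfactual <- function(fit, design = fit$design) {
  x0 <- design$x
  x0[, "step"] <- 0
  x0[, "post_trend"] <- 0
  exp_rate <- drop(x0[design$is_post, , drop = FALSE] %*% fit$beta)
  if (any(exp_rate <= 0)) {
    stop("counterfactual-domain error: extrapolated baseline rate is <= 0 ",
         "in some post month; percentage change is undefined", call. = FALSE)
  }
  names(exp_rate) <- format(design$months[design$is_post])
  exp_rate
}

#' Mean percentage change relative to the extrapolated baseline
#'
#' For each post-advisory month, computes the percentage difference between
#' the actual rate and the counterfactual baseline rate, and returns the
#' arithmetic mean over the post window. Negative values are reductions in
#' use. By default the "actual" rate is the model's deterministic post-period
#' prediction (trend vs trend); `mode = "observed"` uses the raw observed
#' rates instead.
#'
#' @param fit an `its_fit`.
#' @param design the corresponding `segmented_design` (default: embedded).
#' @param mode `"fitted"` (default) or `"observed"`.
#' @return Numeric scalar, with attribute `per_month` holding a `data.frame`
#'   of month, expected (counterfactual) rate, actual rate, and monthly
#'   percentage difference.
#' @export
pct_change <- function(fit, design = fit$design,
                       mode = c("fitted", "observed")) {
  mode <- match.arg(mode)
  expected <- counterfactual(fit, design)
  post <- design$is_post
  actual <- if (mode == "fitted") {
    drop(design$x[post, , drop = FALSE] %*% fit$beta)
  } else {
    design$y[post]
  }
  pm <- 100 * (actual - expected) / expected
  out <- mean(pm)
  attr(out, "per_month") <- data.frame(
    month = format(design$months[post]),
    expected = unname(expected), actual = actual, pct = pm,
    stringsAsFactors = FALSE)
  out
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# Whitened (innovation-scale) residuals of an its_fit.
fit_innovations <- function(fit) {
  if (length(fit$phi)) {
    drop(ar_whiten(matrix(fit$residuals, ncol = 1), fit$phi))
  } else {
    fit$residuals
  }
}

#' Bootstrap percentile confidence interval for the mean percentage change
#'
#' Residual (innovation) bootstrap of the interrupted time series effect.
#' The base model is fitted (AR lag selection included), its structural
#' residuals are whitened to innovations, and each bootstrap iteration
#' resamples innovations with replacement, rebuilds an AR error series by
#' the autoregressive recursion with the base AR parameters (with a burn-in
#' so errors start in the stationary regime), adds the base deterministic
#' fit to form a pseudo-series, refits the model with the AR lags fixed at
#' the base selection, and records the mean percentage change. The 95%
#' interval is the 2.5th and 97.5th percentile of the bootstrap draws
#' (linear interpolation between order statistics). A moving-block variant
#' (`scheme = "block"`, block length 3, resampling the structural residuals
#' directly) is available as a robustness switch.
#'
#' @param series a [prescription_series].
#' @param design a [study_design].
#' @param n_boot bootstrap iterations (>= 100; the analysis default is 5000).
#' @param seed integer seed; required, so runs are reproducible.
#' @param scheme `"innovation"` (default) or `"block"`.
#' @param block_length block length for the moving-block scheme.
#' @param mode passed to [pct_change()].
#' @param max_lag,alpha,detect passed to the base [fit_its()].
#' @param level confidence level for the percentile interval.
#' @return An object of class `its_effect`: `pct_change` (point estimate from
#'   the base fit), `ci_low`, `ci_high`, `se_boot` (SD of the draws),
#'   `n_boot`, `seed`, `draws`, `per_month`, `fit` (the base fit),
#'   `n_failed` (iterations that failed to refit).
#' @export
bootstrap_effect <- function(series, design, n_boot = 5000L, seed,
                             scheme = c("innovation", "block"),
                             block_length = 3L,
                             mode = c("fitted", "observed"),
                             max_lag = NULL, alpha = 0.05, detect = TRUE,
                             level = 0.95) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required for reproducibility", call. = FALSE)
  n_boot <- as.integer(n_boot)
  if (n_boot < 100L) stop("n_boot must be >= 100", call. = FALSE)
  base <- fit_its(series, design, max_lag = max_lag, alpha = alpha,
                  detect = detect)
  point <- pct_change(base, mode = mode)
  sdes <- base$design
  mu <- base$fitted
  n <- base$n
  phi <- base$phi
  p <- length(phi)
  # whiten to innovations, centre, and rescale: raw residuals understate the
  # error variance by df_resid/n (15 regression + AR parameters at n = 35),
  # which would otherwise propagate into every pseudo-series
  innov <- fit_innovations(base)
  innov <- (innov - mean(innov)) * sqrt(n / base$df_resid)
  u <- base$residuals * sqrt(n / (n - ncol(sdes$x)))
  burn <- 100L
  draws <- rep(NA_real_, n_boot)
  n_failed <- 0L
  post <- sdes$is_post
  x_post <- sdes$x[post, , drop = FALSE]
  x0_post <- x_post
  x0_post[, "step"] <- 0
  x0_post[, "post_trend"] <- 0
  pct_from <- function(beta, ystar) {
    expected <- drop(x0_post %*% beta)
    if (any(expected <= 0)) return(NA_real_)
    actual <- if (mode == "fitted") drop(x_post %*% beta) else ystar[post]
    mean(100 * (actual - expected) / expected)
  }
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      if (scheme == "innovation") {
        nu <- sample(innov, n + burn, replace = TRUE)
        e <- if (p > 0) {
          as.numeric(stats::filter(nu, phi, method = "recursive"))[(burn + 1):(burn + n)]
        } else {
          nu[(burn + 1):(burn + n)]
        }
      } else {
        nblock <- ceiling(n / block_length)
        starts <- sample.int(n - block_length + 1L, nblock, replace = TRUE)
        idx <- as.vector(outer(0:(block_length - 1L), starts, `+`))[seq_len(n)]
        e <- u[idx]
      }
      ystar <- mu + e
      beta_star <- tryCatch(gls_beta(sdes$x, ystar, base$lags),
                            error = function(err) NULL)
      if (is.null(beta_star)) {
        n_failed <- n_failed + 1L
        next
      }
      draws[b] <- pct_from(beta_star, ystar)
      if (is.na(draws[b])) n_failed <- n_failed + 1L
    }
  })
  if (n_failed > 0.05 * n_boot) {
    stop("bootstrap-instability error: ", n_failed, " of ", n_boot,
         " bootstrap refits failed (", round(100 * n_failed / n_boot, 1),
         "%)", call. = FALSE)
  }
  draws_ok <- draws[!is.na(draws)]
  a <- (1 - level) / 2
  ci <- stats::quantile(draws_ok, c(a, 1 - a), names = FALSE, type = 7)
  est <- as.numeric(point)
  tol <- 1e-8 * max(1, abs(est))
  if (est < ci[1] - tol || est > ci[2] + tol) {
    warning("percentile CI excludes the point estimate (a rare but possible ",
            "outcome of the percentile method)", call. = FALSE)
  }
  structure(
    list(pct_change = est, ci_low = ci[1], ci_high = ci[2],
         se_boot = stats::sd(draws_ok), n_boot = n_boot, seed = seed,
         draws = draws, per_month = attr(point, "per_month"),
         scheme = scheme, mode = mode, n_failed = n_failed, fit = base),
    class = "its_effect")
}

#' @export
print.its_effect <- function(x, ...) {
  cat(sprintf("<its_effect> mean %% change = %.2f%% (95%% CI %.2f to %.2f), n_boot = %d, seed = %d\n",
              x$pct_change, x$ci_low, x$ci_high, x$n_boot, as.integer(x$seed)))
  invisible(x)
}

#' Effect results as a one-row table
#' @param effects an `its_effect` or named list of them.
#' @return `data.frame` with group, pct_change, ci_low, ci_high, se_boot,
#'   n_boot, seed.
#' @export
effect_table <- function(effects) {
  if (inherits(effects, "its_effect")) effects <- list(all = effects)
  out <- do.call(rbind, lapply(names(effects), function(g) {
    e <- effects[[g]]
    data.frame(group = g, pct_change = e$pct_change, ci_low = e$ci_low,
               ci_high = e$ci_high, se_boot = e$se_boot, n_boot = e$n_boot,
               seed = e$seed, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
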