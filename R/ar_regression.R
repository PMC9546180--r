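#' Ordinary least squares on a segmented design
#'
#' First stage of the feasible GLS procedure; also the final fit when no
#' autoregressive lags are retained.
#'
#' @param design a `segmented_design` from [build_design()], or any list with
#'   elements `x` (full-column-rank model matrix) and `y`.
#' @return List with `beta`, `fitted`, `residuals`, `se` (classical),
#'   `sigma2`, `df_resid`.
#' @export
ols_fit <- function(design) {
  x <- design$x
  y <- design$y
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    stop("singular design: model matrix is rank deficient (rank ", qx$rank,
         " < ", ncol(x), " columns)", call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(x %*% beta)
  res <- y - fitted
  df <- length(y) - ncol(x)
  sigma2 <- if (df > 0) sum(res^2) / df else NA_real_
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- names(beta) <- colnames(x)
  list(beta = beta, fitted = fitted, residuals = res, se = se,
       sigma2 = sigma2, df_resid = df)
}

#' Generalized Durbin-Watson statistic
#'
#' \eqn{d_j = \sum_{t>j} (e_t - e_{t-j})^2 / \sum_t e_t^2}, sensitive to
#' lag-j autocorrelation in the residual series; approximately 2 under
#' independence at lag 1, with values toward 0 signalling positive and
#' toward 4 negative autocorrelation.
#'
#' @param residuals numeric residual series.
#' @param lag positive integer lag(s), each `< length(residuals)`.
#' @return Numeric vector of statistics, one per lag, each in `[0, 4]`.
#' @examples
#' durbin_watson(c(1, -1, 1, -1), 1) # 3
#' @export
durbin_watson <- function(residuals, lag = 1L) {
  lag <- as.integer(lag)
  n <- length(residuals)
  if (any(lag < 1L) || any(lag >= n)) {
    stop("lag must satisfy 1 <= lag < length(residuals)", call. = FALSE)
  }
  denom <- sum(residuals^2)
  if (denom == 0) {
    stop("undefined statistic: residuals are identically zero", call. = FALSE)
  }
  vapply(lag, function(j) {
    sum((residuals[(j + 1):n] - residuals[1:(n - j)])^2) / denom
  }, numeric(1))
}

#' Yule-Walker estimation of autoregressive parameters
#'
#' Method-of-moments fit of an AR model at the given lags from the sample
#' autocovariances \eqn{c_j = n^{-1} \sum_{t>j} e_t e_{t-j}}, solving the
#' (possibly subset) Yule-Walker system \eqn{R\phi = r}. For the full lag set
#' `1..p` the solution is guaranteed stationary when the autocovariance
#' matrix is positive definite; subset solutions are checked explicitly.
#'
#' @param residuals numeric series (regression residuals).
#' @param order highest AR lag; shorthand for `lags = 1:order`.
#' @param lags integer set of lags to fit (supports subset autoregression).
#' @return List with `phi` (named by lag), `se_phi` (asymptotic, from the
#'   Yule-Walker information matrix), `sigma2` (innovation variance), `lags`.
#' @examples
#' yule_walker(c(1, 1, -1, -1), order = 1)$phi # 0.25
#' @export
yule_walker <- function(residuals, order = NULL, lags = NULL) {
  if (is.null(lags)) {
    if (is.null(order)) stop("supply order or lags", call. = FALSE)
    lags <- seq_len(order)
  }
  lags <- sort(as.integer(lags))
  if (!length(lags)) return(list(phi = numeric(0), se_phi = numeric(0),
                                 sigma2 = stats::var(residuals) * (length(residuals) - 1) / length(residuals),
                                 lags = integer(0)))
  if (any(lags < 1L)) stop("lags must be positive", call. = FALSE)
  n <- length(residuals)
  p <- max(lags)
  if (n < p + 2L) stop("need at least max(lags) + 2 residuals", call. = FALSE)
  acov <- vapply(0:p, function(j) {
    sum(residuals[(j + 1):n] * residuals[1:(n - j)]) / n
  }, numeric(1))
  if (acov[1] <= 0) stop("undefined autocovariances: zero-variance residuals",
                         call. = FALSE)
  gam <- outer(lags, lags, function(i, j) acov[abs(i - j) + 1L])
  r <- acov[lags + 1L]
  phi <- tryCatch(solve(gam, r), error = function(e) {
    stop("numerical error: singular autocovariance matrix in Yule-Walker ",
         "system", call. = FALSE)
  })
  full <- numeric(p)
  full[lags] <- phi
  if (!ar_stationary(full)) {
    stop("stationarity error: Yule-Walker solution at lags {",
         paste(lags, collapse = ","), "} is non-stationary", call. = FALSE)
  }
  sigma2 <- acov[1] - sum(phi * r)
  se_phi <- sqrt(pmax(0, sigma2 * diag(solve(gam)) / n))
  names(phi) <- names(se_phi) <- paste0("lag", lags)
  list(phi = phi, se_phi = se_phi, sigma2 = sigma2, lags = lags)
}

#' Is an AR coefficient vector stationary?
#'
#' Checks that all roots of \eqn{1 - \sum_j \phi_j z^j} lie outside the unit
#' circle.
#'
#' @param phi full AR coefficient vector (coefficient for lag j at position j).
#' @return `TRUE` if the process is stationary.
#' @export
ar_stationary <- function(phi) {
  if (!length(phi) || all(phi == 0)) return(TRUE)
  all(Mod(polyroot(c(1, -phi))) > 1 + 1e-10)
}

#' Detect and order residual autocorrelation
#'
#' Two-stage procedure mirroring the usual autoregressive-regression
#' workflow: generalized Durbin-Watson statistics first screen the residuals
#' for autocorrelation, and only where it is detected is the autoregressive
#' order determined by backward stepwise autoregression.
#'
#' Detection tests each \eqn{d_j}, `j = 1..max_lag`, against its exact null
#' mean and standard deviation (first two moments of the ratio of quadratic
#' forms in the regression residuals, so the design matrix and the lag are
#' both accounted for) with a normal approximation, Bonferroni-corrected
#' across the `max_lag` lags so the familywise false-detection rate is about
#' `alpha`; without this screen, testing 13 lags at `alpha` each would
#' retain a spurious lag in roughly half of white-noise series.
#'
#' Selection then fits all lags `1..max_lag` to the residuals by
#' Yule-Walker and iteratively removes the lag whose approximate
#' t-statistic \eqn{\hat\phi_j / SE(\hat\phi_j)} has the largest p-value
#' above `alpha`, refitting the remaining subset each time, until every
#' retained lag is significant or none remain. Ties in p-value are broken
#' by dropping the higher lag.
#'
#' @param design a `segmented_design` (OLS residuals are computed from it),
#'   or a numeric vector of residuals.
#' @param max_lag highest lag considered; must be `<= 13` and `< n/4`.
#' @param alpha significance level (familywise for detection, per-lag for
#'   the stepwise retention).
#' @param detect run the Durbin-Watson detection stage first (default)?
#'   `FALSE` goes straight to backward stepwise selection.
#' @return Sorted integer vector of retained lags (possibly empty).
#' @export
select_order <- function(design, max_lag = 13L, alpha = 0.05,
                         detect = TRUE) {
  if (is.numeric(design)) {
    e <- design
    yscale <- sum(e^2)
  } else {
    e <- ols_fit(design)$residuals
    yscale <- sum(design$y^2)
  }
  n <- length(e)
  max_lag <- as.integer(max_lag)
  if (max_lag == 0L) return(integer(0))
  if (max_lag > 13L || max_lag >= n / 4) {
    stop("max_lag must be <= 13 and < n/4 (n = ", n, ")", call. = FALSE)
  }
  # a (numerically) perfect structural fit leaves nothing to autocorrelate
  if (sum(e^2) <= 1e-20 * max(yscale, 1)) return(integer(0))
  if (isTRUE(detect)) {
    lags_dw <- seq_len(max_lag)
    d <- durbin_watson(e, lags_dw)
    mom <- dw_null_moments(n, lags_dw,
                           x = if (is.numeric(design)) NULL else design$x)
    p_dw <- 2 * stats::pnorm(-abs(d - mom$mean) / mom$sd)
    if (min(p_dw) > alpha / max_lag) return(integer(0))
  }
  lags <- seq_len(max_lag)
  while (length(lags)) {
    fit <- tryCatch(yule_walker(e, lags = lags), error = function(err) NULL)
    if (is.null(fit)) {
      # subset Yule-Walker solutions are not guaranteed stationary (and can
      # be singular); treat an infeasible subset by shedding its highest lag
      lags <- lags[-length(lags)]
      next
    }
    df <- n - length(lags)
    pv <- 2 * stats::pt(-abs(fit$phi / fit$se_phi), df = df)
    worst <- max(pv)
    if (worst <= alpha) break
    # ties broken by dropping the higher lag
    drop_idx <- max(which(pv == worst))
    lags <- lags[-drop_idx]
  }
  lags
}

# Autocovariance function (relative to innovation variance = 1) of a
# stationary AR process, lags 0..lag_max, from the extended Yule-Walker
# system g_k = sum_j phi_j g_|k-j| + [k = 0].
ar_acov <- function(phi, lag_max) {
  p <- length(phi)
  a <- diag(p + 1)
  for (k in 0:p) for (j in seq_len(p)) {
    m <- abs(k - j)
    a[k + 1, m + 1] <- a[k + 1, m + 1] - phi[j]
  }
  g <- solve(a, c(1, rep(0, p)))
  if (lag_max > p) {
    g <- c(g, numeric(lag_max - p))
    for (k in (p + 1):lag_max) g[k + 1] <- sum(phi * g[k + 1 - seq_len(p)])
  }
  g[1:(lag_max + 1)]
}

# Whitening transform for an AR(p) error structure: rows t > p get the
# innovations filter, the first p rows are premultiplied by the inverse
# Cholesky factor of their stationary covariance (scaled to innovation
# variance), so no observations are discarded.
ar_whiten <- function(mat, phi) {
  mat <- as.matrix(mat)
  p <- length(phi)
  n <- nrow(mat)
  if (p == 0L) return(mat)
  if (n <= p) stop("not enough rows to whiten AR(", p, ") structure",
                   call. = FALSE)
  out <- mat
  idx <- (p + 1):n
  for (j in seq_len(p)) {
    if (phi[j] != 0) out[idx, ] <- out[idx, ] - phi[j] * mat[idx - j, , drop = FALSE]
  }
  g <- ar_acov(phi, p - 1)
  gmat <- if (p == 1L) matrix(g[1], 1, 1) else stats::toeplitz(g)
  L <- t(chol(gmat))
  out[1:p, ] <- forwardsolve(L, mat[1:p, , drop = FALSE])
  out
}

# Null mean and SD of the generalized Durbin-Watson ratio d_j for residuals
# of a regression on x (or a raw iid series when x is NULL), from the exact
# first two moments of the ratio of quadratic forms in spherical normal
# errors: with M the residual projector of rank nu, P = tr(A M),
# Q = tr((A M)^2), E[d] = P/nu and E[d^2] = (P^2 + 2 Q)/(nu (nu + 2)).
dw_null_moments <- function(n, lags, x = NULL) {
  if (is.null(x)) {
    nu <- n
    P <- 2 * (n - lags)
    Q <- 4 * (n - lags) + 2 * pmax(0, n - 2 * lags)
  } else {
    qx <- qr(x)
    qq <- qr.Q(qx)
    m <- diag(n) - tcrossprod(qq)
    nu <- n - ncol(x)
    P <- Q <- numeric(length(lags))
    for (i in seq_along(lags)) {
      j <- lags[i]
      d <- matrix(0, n - j, n)
      d[cbind(seq_len(n - j), seq_len(n - j))] <- -1
      d[cbind(seq_len(n - j), seq_len(n - j) + j)] <- 1
      am <- crossprod(d) %*% m
      P[i] <- sum(diag(am))
      Q[i] <- sum(am * t(am))
    }
  }
  mu <- P / nu
  ex2 <- (P^2 + 2 * Q) / (nu * (nu + 2))
  list(mean = mu, sd = sqrt(pmax(ex2 - mu^2, 0)))
}

# Lean two-step feasible GLS returning only the coefficient vector; the
# bootstrap's inner loop uses this to avoid the bookkeeping of fit_gls.
# Must stay numerically identical to the estimation path of fit_gls.
gls_beta <- function(x, y, lags) {
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop("singular design", call. = FALSE)
  if (!length(lags)) return(qr.coef(qx, y))
  e <- y - drop(x %*% qr.coef(qx, y))
  yw <- yule_walker(e, lags = lags)
  phi <- numeric(max(lags))
  phi[lags] <- yw$phi
  xs <- ar_whiten(x, phi)
  ys <- drop(ar_whiten(matrix(y, ncol = 1), phi))
  qxs <- qr(xs)
  if (qxs$rank < ncol(x)) stop("singular whitened design", call. = FALSE)
  qr.coef(qxs, ys)
}

#' Segmented regression with autoregressive errors (Yule-Walker feasible GLS)
#'
#' Two-step feasible generalized least squares: (1) OLS on the segmented
#' design; (2) Yule-Walker estimation of the AR parameters at the given lags
#' from the OLS residuals; (3) exact whitening of response and design (the
#' innovations filter for observations beyond the AR order, the stationary
#' covariance factorization for the first `p` observations, so no rows are
#' dropped); (4) OLS on the whitened data, giving coefficient estimates,
#' standard errors and two-sided t-based p-values with
#' `df_resid = n - k_regression - k_AR`.
#'
#' The total R-squared, `1 - SSE/SST`, uses one-step-ahead predictions that
#' include the AR forecast of the error term, so it measures the fit of the
#' combined structural + autoregressive model; with no retained lags it
#' reduces to the OLS R-squared.
#'
#' @param design a `segmented_design` from [build_design()].
#' @param lags integer set of retained AR lags (empty for plain OLS), e.g.
#'   from [select_order()].
#' @param dw_max_lag highest lag for the reported generalized Durbin-Watson
#'   diagnostics; default `min(13, n %/% 4)`.
#' @return An object of class `its_fit`: coefficients `beta`, `se`,
#'   `p_values`, AR parameters `phi` (full vector to `max(lags)`), retained
#'   `lags`, innovation variance `sigma2`, structural `residuals`, `dw`
#'   statistics, `r2_total`, `df_resid`, plus the embedded `design`.
#' @export
fit_gls <- function(design, lags = integer(0), dw_max_lag = NULL) {
  x <- design$x
  y <- design$y
  n <- length(y)
  k <- ncol(x)
  lags <- sort(as.integer(lags))
  ols <- ols_fit(design)
  if (is.null(dw_max_lag)) dw_max_lag <- max(1L, min(13L, n %/% 4L))
  if (length(lags)) {
    yw <- yule_walker(ols$residuals, lags = lags)
    p <- max(lags)
    phi <- numeric(p)
    phi[lags] <- yw$phi
    df <- n - k - length(lags)
    if (df <= 0) stop("overparameterization: df_resid = ", df, " <= 0",
                      call. = FALSE)
    xs <- ar_whiten(x, phi)
    ys <- drop(ar_whiten(matrix(y, ncol = 1), phi))
    qx <- qr(xs)
    if (qx$rank < k) stop("singular design after whitening", call. = FALSE)
    beta <- qr.coef(qx, ys)
    wres <- ys - drop(xs %*% beta)
    sigma2 <- sum(wres^2) / df
    se <- sqrt(sigma2 * diag(chol2inv(qr.R(qx))))
  } else {
    yw <- NULL
    phi <- numeric(0)
    p <- 0L
    df <- ols$df_resid
    beta <- ols$beta
    se <- ols$se
    sigma2 <- ols$sigma2
  }
  names(beta) <- names(se) <- colnames(x)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  u <- y - drop(x %*% beta) # structural residuals
  # one-step-ahead prediction error: structural prediction + AR forecast of
  # the error (zero forecast where insufficient history)
  efor <- numeric(n)
  if (p > 0) {
    for (j in lags) {
      idx <- (j + 1):n
      efor[idx] <- efor[idx] + phi[j] * u[idx - j]
    }
    efor[seq_len(p)] <- 0
  }
  sse <- sum((u - efor)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  dw <- if (sum(u^2) > 0) durbin_watson(u, seq_len(min(dw_max_lag, n - 1L)))
        else rep(NA_real_, dw_max_lag)
  structure(
    list(beta = beta, se = se, t_values = tval, p_values = pval,
         phi = phi, lags = lags,
         se_phi = if (length(lags)) yw$se_phi else numeric(0),
         sigma2 = sigma2, residuals = u, fitted = drop(x %*% beta),
         dw = dw, r2_total = r2, df_resid = df, n = n,
         design = design),
    class = "its_fit")
}

#' Fit an interrupted time series model to one series
#'
#' Convenience pipeline: builds the segmented design, screens the OLS
#' residuals for autocorrelation by backward stepwise autoregression, and
#' fits the final model by Yule-Walker feasible GLS with the retained lags
#' (plain OLS when none are retained).
#'
#' @param series a [prescription_series].
#' @param design a [study_design].
#' @param max_lag highest AR lag considered; default `min(13, floor(n/4))`
#'   where `n` is the number of modelled months.
#' @param alpha significance level for lag retention.
#' @param detect passed to [select_order()]: screen with Durbin-Watson
#'   tests before stepwise selection (default `TRUE`).
#' @return An `its_fit` (see [fit_gls()]).
#' @export
fit_its <- function(series, design, max_lag = NULL, alpha = 0.05,
                    detect = TRUE) {
  sd_ <- build_design(series, design)
  n <- length(sd_$y)
  if (is.null(max_lag)) max_lag <- min(13L, (n - 1L) %/% 4L)
  lags <- select_order(sd_, max_lag = max_lag, alpha = alpha, detect = detect)
  fit_gls(sd_, lags = lags)
}

#' @export
print.its_fit <- function(x, ...) {
  cat("<its_fit> n = ", x$n, ", df_resid = ", x$df_resid,
      ", AR lags {", paste(x$lags, collapse = ","), "}",
      ", total R^2 = ", round(x$r2_total, 4), "\n", sep = "")
  tab <- data.frame(estimate = x$beta, se = x$se, p = signif(x$p_values, 3))
  print(utils::head(tab, 4))
  if (length(x$lags)) {
    cat("phi:", paste(sprintf("%s=%.3f", paste0("lag", x$lags),
                              x$phi[x$lags]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.its_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.its_fit")
}

#' @export
print.summary.its_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("Durbin-Watson (lags 1..", length(f$dw), "): ",
      paste(round(f$dw, 2), collapse = " "), "\n", sep = "")
  invisible(x)
}
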