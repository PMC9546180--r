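#' Standard error from a 95% confidence interval
#'
#' Recovers the standard error of an estimate from a symmetric 95% CI as
#' `(ci_high - ci_low) / (2 * 1.959964)` — the usual preprocessing step for
#' the Altman-Bland test for interaction when only interval bounds are
#' reported.
#'
#' @param ci_low,ci_high interval bounds, `ci_high > ci_low`.
#' @return Numeric standard error.
#' @examples
#' se_from_ci(-1.96, 1.96) # 1
#' @export
se_from_ci <- function(ci_low, ci_high) {
  if (any(ci_high <= ci_low)) {
    stop("ci_high must exceed ci_low", call. = FALSE)
  }
  (ci_high - ci_low) / (2 * stats::qnorm(0.975))
}

#' Altman-Bland test for interaction between two subgroup effects
#'
#' z-test on the difference between two independent estimates (here, mean
#' percentage changes in prescribing for two subgroups): the difference
#' `e1 - e2`, its standard error `sqrt(se1^2 + se2^2)`, a normal 95% CI, and
#' a two-sided p-value from the standard normal distribution.
#'
#' @param e1,e2 the two effect estimates (percentage points).
#' @param se1,se2 their standard errors (> 0).
#' @param labels optional character pair naming the groups.
#' @return An object of class `its_interaction`: `difference`, `se_diff`,
#'   `ci_low`, `ci_high`, `z`, `p_value`.
#' @examples
#' interaction_test(-18, 2, -16, 2)
#' @export
interaction_test <- function(e1, se1, e2, se2, labels = c("group1", "group2")) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive",
                                 call. = FALSE)
  diff <- e1 - e2
  se_diff <- sqrt(se1^2 + se2^2)
  zcrit <- stats::qnorm(0.975)
  z <- diff / se_diff
  structure(
    list(difference = diff, se_diff = se_diff,
         ci_low = diff - zcrit * se_diff, ci_high = diff + zcrit * se_diff,
         z = z, p_value = 2 * stats::pnorm(-abs(z)),
         labels = labels, e1 = e1, e2 = e2, se1 = se1, se2 = se2),
    class = "its_interaction")
}

#' Compare two bootstrap effect estimates
#'
#' Applies [interaction_test()] to two [bootstrap_effect()] results. By
#' default each effect's standard error is the standard deviation of its
#' bootstrap draws (the fuller use of the bootstrap distribution);
#' `se_source = "ci"` instead recovers SEs from the percentile interval via
#' [se_from_ci()], the fallback when only intervals are available.
#'
#' @param eff1,eff2 `its_effect` objects.
#' @param se_source `"draws"` (default) or `"ci"`.
#' @param labels optional character pair naming the groups.
#' @return An `its_interaction`.
#' @export
compare_effects <- function(eff1, eff2, se_source = c("draws", "ci"),
                            labels = c("group1", "group2")) {
  se_source <- match.arg(se_source)
  se_of <- function(e) {
    if (se_source == "draws") e$se_boot else se_from_ci(e$ci_low, e$ci_high)
  }
  interaction_test(eff1$pct_change, se_of(eff1),
                   eff2$pct_change, se_of(eff2), labels = labels)
}

#' @export
print.its_interaction <- function(x, ...) {
  cat(sprintf("<its_interaction> %s vs %s: difference = %.2f%% (SE %.3f), 95%% CI %.2f to %.2f, z = %.3f, p = %.3g\n",
              x$labels[1], x$labels[2], x$difference, x$se_diff,
              x$ci_low, x$ci_high, x$z, x$p_value))
  invisible(x)
}

#' @export
as.data.frame.its_interaction <- function(x, ...) {
  data.frame(group1 = x$labels[1], group2 = x$labels[2],
             effect1 = x$e1, effect2 = x$e2,
             difference = x$difference, se_diff = x$se_diff,
             ci_low = x$ci_low, ci_high = x$ci_high,
             z = x$z, p_value = x$p_value, stringsAsFactors = FALSE)
}
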