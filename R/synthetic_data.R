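#' Configuration for a synthetic prescribing series
#'
#' Defines the true data-generating process for one group's monthly
#' prescribing series: the segmented mean structure (level at series start,
#' baseline monthly change, level change at the advisory, monthly change
#' after it), month-of-year seasonality, a stationary AR error process with
#' Gaussian innovations, and the population denominator. Defaults emulate
#' the Australian national pioglitazone series: a level near 182
#' prescriptions per 100 000, a slightly declining baseline, an abrupt drop
#' of about 13 at the advisory followed by a steeper decline of about 2.5
#' per month, moderate positive autocorrelation and an innovation SD of 5
#' rate units over a 24-month pre / 11-month post window.
#'
#' @param label group label (used by [simulate_panel()]).
#' @param n_pre,n_post months before/after the advisory month.
#' @param start_month first month of the series (`month_index` or ISO
#'   string); the advisory month is `start_month + n_pre`.
#' @param beta true `(beta0, beta1, beta2, beta3)`: level at series start,
#'   baseline monthly change, level change at the advisory, additional
#'   monthly change post-advisory, in rate units per 100 000.
#' @param seasonal_amp peak-to-trough seasonal amplitude (rate units); used
#'   to build a sinusoidal month-of-year profile when `gamma` is not given.
#' @param gamma optional explicit 12-vector of month-of-year offsets
#'   (January first), overriding `seasonal_amp`.
#' @param phi true AR coefficient vector (must be stationary); `numeric(0)`
#'   for white noise.
#' @param innovation_sd SD of the Gaussian innovations (rate units).
#' @param population population denominator: scalar or per-month vector.
#' @param noise_model `"gaussian"` (noise added on the rate scale, the
#'   model's own error structure) or `"poisson"` (counts drawn with mean
#'   `population * rate / 1e5`, probing robustness to count noise).
#' @param seed integer seed for this group's randomness.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(label = "all",
                              n_pre = 24L, n_post = 11L,
                              start_month = "2009-07",
                              beta = c(182.03, -0.178, -13.12, -2.53),
                              seasonal_amp = 10,
                              gamma = NULL,
                              phi = 0.5,
                              innovation_sd = 5,
                              population = 1e6,
                              noise_model = c("gaussian", "poisson"),
                              seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(beta) == 4, innovation_sd >= 0)
  phi <- as.numeric(phi)
  if (length(phi) == 1 && phi == 0) phi <- numeric(0)
  if (!ar_stationary(phi)) stop("phi must define a stationary AR process",
                                call. = FALSE)
  if (is.null(gamma)) {
    gamma <- seasonal_amp / 2 * sin(2 * pi * (0:11) / 12)
  }
  if (length(gamma) != 12) stop("gamma must have length 12", call. = FALSE)
  if (any(population <= 0)) stop("population must be positive", call. = FALSE)
  structure(
    list(label = label, n_pre = as.integer(n_pre), n_post = as.integer(n_post),
         start_month = parse_month(start_month), beta = as.numeric(beta),
         gamma = as.numeric(gamma), phi = phi,
         innovation_sd = innovation_sd, population = population,
         noise_model = noise_model, seed = as.integer(seed)),
    class = "sim_config")
}

# Deterministic mean rate of the generating model at every month of the
# series (including the transition month, which keeps the pre-advisory
# regime: its exposure is mixed and it is excluded from fitting anyway).
sim_mean <- function(config, counterfactual = FALSE) {
  n <- config$n_pre + 1L + config$n_post
  months <- month_seq(config$start_month, n)
  code <- unclass(months)
  adv <- code[1] + config$n_pre
  time <- code - code[1]
  post <- code > adv
  step <- as.numeric(post & !counterfactual)
  ptrend <- ifelse(post & !counterfactual, code - adv, 0)
  b <- config$beta
  mu <- b[1] + b[2] * time + b[3] * step + b[4] * ptrend +
    config$gamma[month_of_year(months)]
  list(months = months, mu = mu, is_post = post)
}

#' True mean percentage change implied by a simulation configuration
#'
#' Closed-form effect: for each post-advisory month, the percentage
#' difference between the generating mean with and without the advisory
#' terms, averaged over the post window. This is the estimand the pipeline's
#' [pct_change()] targets.
#'
#' @param config a [simulation_config()].
#' @return Numeric scalar (percent).
#' @export
true_effect <- function(config) {
  full <- sim_mean(config, counterfactual = FALSE)
  cf <- sim_mean(config, counterfactual = TRUE)
  if (any(cf$mu[cf$is_post] <= 0)) {
    stop("counterfactual mean rate <= 0; true effect undefined", call. = FALSE)
  }
  mean(100 * (full$mu[full$is_post] - cf$mu[cf$is_post]) / cf$mu[cf$is_post])
}

#' Simulate one monthly prescribing series
#'
#' Draws a [prescription_series] from the segmented-trend + seasonal + AR
#' error model described by `config`. Errors are generated by the AR
#' recursion with Gaussian innovations and a 100-step burn-in so they start
#' in the stationary regime. Under the Gaussian noise model the series
#' carries rates (and the population denominator) only; under the Poisson
#' model counts are drawn with mean `population * rate / 1e5` and rates are
#' recomputed from them. The analytic true mean percentage change implied by
#' the configuration is attached as attribute `"true_effect"`.
#'
#' @param config a [simulation_config()].
#' @return A [prescription_series] with attributes `true_effect` and
#'   `config`.
#' @export
simulate_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  det <- sim_mean(config)
  if (any(det$mu < 0)) {
    stop("config rejected: implied mean rate is negative at ",
         format(det$months[which(det$mu < 0)[1]]), call. = FALSE)
  }
  n <- length(det$mu)
  p <- length(config$phi)
  burn <- 100L
  e <- with_seed(config$seed, {
    nu <- stats::rnorm(n + burn, 0, config$innovation_sd)
    if (p > 0) {
      as.numeric(stats::filter(nu, config$phi,
                               method = "recursive"))[(burn + 1):(burn + n)]
    } else {
      nu[(burn + 1):(burn + n)]
    }
  })
  rate <- det$mu + e
  rate <- pmax(rate, 0)
  pop <- rep_len(config$population, n)
  if (config$noise_model == "poisson") {
    counts <- with_seed(config$seed + 1L, {
      stats::rpois(n, lambda = pmax(pop * rate / 1e5, 0))
    })
    out <- prescription_series(c(group = config$label), det$months,
                               counts = counts, populations = pop)
  } else {
    out <- prescription_series(c(group = config$label), det$months,
                               populations = pop, rates = rate)
  }
  attr(out, "true_effect") <- true_effect(config)
  attr(out, "config") <- config
  out
}

#' Simulate a multi-group panel and write it to disk
#'
#' Simulates one series per configuration and writes a single CSV panel
#' readable by [read_panel()], plus a "truth" sidecar CSV recording each
#' group's analytic true effect and seed.
#'
#' @param configs non-empty list of [simulation_config()] objects with
#'   distinct labels.
#' @param path output CSV path; the sidecar is written to
#'   `paste0(path, ".truth.csv")`.
#' @return Invisibly, the named list of simulated series.
#' @export
simulate_panel <- function(configs, path) {
  if (!length(configs)) stop("config error: empty configuration list",
                             call. = FALSE)
  if (inherits(configs, "sim_config")) configs <- list(configs)
  labels <- vapply(configs, function(cf) cf$label, character(1))
  if (anyDuplicated(labels)) {
    stop("config error: duplicate group labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  series <- lapply(configs, simulate_series)
  names(series) <- labels
  write_panel(series, path)
  truth <- data.frame(
    group = labels,
    true_effect = vapply(series, function(s) attr(s, "true_effect"), numeric(1)),
    seed = vapply(configs, function(cf) cf$seed, integer(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(truth, paste0(path, ".truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(series)
}

#' Study design matching a simulation configuration
#'
#' Convenience: the [study_design()] whose window, advisory month and
#' transition month correspond to the generating process of `config`.
#'
#' @param config a [simulation_config()].
#' @param ... passed to [study_design()] (e.g. `seasonal = FALSE`).
#' @return A `study_design`.
#' @export
design_for <- function(config, ...) {
  study_design(month_add(config$start_month, config$n_pre),
               n_pre = config$n_pre, n_post = config$n_post, ...)
}
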