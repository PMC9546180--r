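# Shared fixtures for the itsar test suite. Everything is built in code.

# The study's canonical design: advisory July 2011, 24 pre / 11 post months,
# July 2011 itself transitional.
canonical_design <- function(...) {
  study_design("2011-07", n_pre = 24, n_post = 11, ...)
}

# A noiseless series following the segmented model exactly.
exact_series <- function(beta = c(182.03, -0.178, -13.12, -2.53),
                         gamma = rep(0, 12), label = "exact") {
  cfg <- simulation_config(label = label, beta = beta, gamma = gamma,
                           phi = 0, innovation_sd = 0, seed = 1L)
  simulate_series(cfg)
}

# Simulate a stationary AR(p) error series with unit-variance innovations.
sim_ar <- function(n, phi, sd = 1, burn = 100L) {
  nu <- rnorm(n + burn, 0, sd)
  if (!length(phi) || all(phi == 0)) return(nu[(burn + 1):(burn + n)])
  as.numeric(stats::filter(nu, phi, method = "recursive"))[(burn + 1):(burn + n)]
}

# Independent GLS oracle: explicit error-covariance solve, no whitening.
# V is built from the stationary AR autocovariances implied by phi.
gls_oracle <- function(x, y, phi) {
  n <- length(y)
  g <- ARMAacf(ar = phi, lag.max = n - 1)
  v <- stats::toeplitz(unname(g))
  vi <- solve(v)
  solve(t(x) %*% vi %*% x, t(x) %*% vi %*% y)
}

# Independent type-7 quantile oracle: sort and linearly interpolate order
# statistics.
quantile_oracle <- function(draws, p) {
  s <- sort(draws)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
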