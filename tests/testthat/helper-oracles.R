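# Independent phase-level oracles for the synthetic generator.
#
# These bypass the whole signal path (synthesis, filtering, Hilbert) and
# simulate the jitter process directly from its definition, so pipeline
# measurements can be compared against an implementation-independent
# reference.

# one jitter trajectory: AR(1) Gaussian -> uniform -> von Mises quantile,
# written with base building blocks (stats::filter recursion, numeric CDF
# inversion) rather than the package's synthesis kernels
oracle_jitter <- function(n, kappa, rate, tau) {
  rho <- exp(-1 / (rate * tau))
  g <- as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - rho^2)), rho,
                                method = "recursive", init = rnorm(1)))
  u <- pnorm(g)
  if (kappa == 0) return((u - 0.5) * 2 * pi)
  theta <- seq(-pi, pi, length.out = 8192)
  cdf <- cumsum(exp(kappa * (cos(theta) - 1)))
  cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  approx(cdf, theta, xout = u, rule = 2)$y
}

# Monte-Carlo distribution of the per-segment PLV estimator for a channel
# pair with independent jitter of concentration kappa
oracle_segment_plv <- function(kappa, n_seg, rate = 1024, dur = 3,
                               tau = 0.25) {
  n <- rate * dur
  replicate(n_seg, {
    d <- oracle_jitter(n, kappa, rate, tau) - oracle_jitter(n, kappa, rate, tau)
    Mod(mean(exp(1i * d)))
  })
}
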