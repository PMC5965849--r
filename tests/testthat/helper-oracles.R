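# Independent oracles used across the suite: brute-force adaptive
# integration and direct summation, never the quadrature/closed-form code
# paths they are checking.

# marginal Pr(y) of a Poisson count mixed over heterogeneity density `dens`,
# by adaptive quadrature; the lower limit reaches -40 because the log-gamma
# left tail decays only exponentially (like e^(eps/alpha^2)), far slower
# than a Gaussian
oracle_mixture_pmf <- function(y, lin_pred, dens) {
  stats::integrate(function(e) stats::dpois(y, exp(lin_pred + e)) * dens(e),
                   lower = -40, upper = 12, rel.tol = 1e-10,
                   abs.tol = 0)$value
}

# direct evaluation of the squared-polynomial-times-normal density with the
# normalization computed by adaptive integration (not the moment table)
oracle_snp_pdf <- function(eps, a) {
  poly <- function(e) {
    vapply(e, function(ei) sum(a * ei^(seq_along(a) - 1L)), 0)
  }
  C <- stats::integrate(function(e) poly(e)^2 * stats::dnorm(e),
                        lower = -10, upper = 10, rel.tol = 1e-12,
                        abs.tol = 0)$value
  poly(eps)^2 * stats::dnorm(eps) / C
}

# brute-force double-loop Gaussian KDE
oracle_kde <- function(sample, grid, h) {
  out <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- 0
    for (j in seq_along(sample)) {
      s <- s + stats::dnorm((grid[i] - sample[j]) / h) / h
    }
    out[i] <- s / length(sample)
  }
  out
}

# numeric trapezoid integral of a tabulated curve
trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

# small deterministic dataset for fast fitting tests
toy_loggamma_data <- function(n = 300, alpha2 = 0.8, seed = 7) {
  gen_dataset(simulation_spec(n = n, hetero_kind = "loggamma",
                              hetero_params = c(alpha2 = alpha2),
                              seed = seed))
}
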