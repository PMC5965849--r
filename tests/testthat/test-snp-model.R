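test_that("quadrature likelihood matches adaptive integration at K = 0", {
  # the Poisson kernel narrows like 1/sqrt(y), so the fixed 30-point rule
  # resolves small counts far better than large ones; see the vignette
  r <- hermite_rule(30)
  for (y in c(0, 1, 2, 4)) {
    for (lp in c(-0.5, 0, 1)) {
      d <- count_dataset(y, matrix(1, 1, 1, dimnames = list(NULL, "x")))
      got <- snp_loglik(lp, snp_coef(1), d, r)
      want <- log(oracle_mixture_pmf(y, lp, stats::dnorm))
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
  # the y = 0, x*beta = 0 case: ln int exp(-e^eps) phi(eps) d eps
  d0 <- count_dataset(0, matrix(0, 1, 1, dimnames = list(NULL, "x")))
  want0 <- log(stats::integrate(function(e) exp(-exp(e)) * stats::dnorm(e),
                                -12, 12, rel.tol = 1e-12)$value)
  expect_equal(snp_loglik(0, snp_coef(1), d0, r), want0, tolerance = 1e-6)
})

test_that("quadrature likelihood matches adaptive integration for K <= 5", {
  r <- hermite_rule(30)
  set.seed(8)
  for (K in c(1, 3, 5)) {
    a <- c(1, stats::rnorm(K, 0, 0.3))
    for (y in c(0, 2, 6)) {
      lp <- stats::runif(1, -1, 1)
      d <- count_dataset(y, matrix(1, 1, 1, dimnames = list(NULL, "x")))
      got <- snp_loglik(lp, snp_coef(a), d, r)
      want <- log(oracle_mixture_pmf(y, lp,
                                     function(e) snp_pdf(e, snp_coef(a))))
      expect_equal(got, want, tolerance = 1e-5)
    }
  }
})

test_that("likelihood is invariant to shifting offset against intercept", {
  sim <- toy_loggamma_data(n = 100, seed = 17)
  d <- sim$data
  beta <- c(0.8, -0.25, 0.35)
  a <- snp_coef(c(1, -0.1, 0.05))
  r <- hermite_rule(30)
  ll1 <- snp_loglik(beta, a, d, r)
  cc <- 0.7
  d2 <- count_dataset(d$y, d$X, offset = rep(cc, d$N))
  ll2 <- snp_loglik(beta - c(cc, 0, 0), a, d2, r)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("fitting recovers slopes and approximates the log-gamma truth", {
  sim <- gen_dataset(simulation_spec(n = 1000, hetero_kind = "loggamma",
                                     hetero_params = c(alpha2 = 0.8),
                                     seed = 11))
  nb <- fit_nb(sim$data)
  snp <- fit_snp(sim$data, K = 4, fixed_intercept = nb$beta[1])
  expect_true(snp$converged)
  expect_equal(snp$coef$a[1], 1)
  expect_equal(snp$k, 6L)  # 2 slopes + a1..a4; fixed intercept excluded
  expect_lt(abs(snp$loglik - nb$loglik), 2)
  slopes <- snp$beta[c("x1", "x2")]
  expect_true(all(abs(slopes - c(-0.3, 0.4)) <
                    3 * snp$se[c("x1", "x2")]))
})

test_that("K = 2 captures normal heterogeneity", {
  sim <- gen_dataset(simulation_spec(n = 1000, hetero_kind = "normal",
                                     hetero_params = c(mu = 0, sigma = 0.8),
                                     seed = 23))
  snp <- fit_snp(sim$data, K = 2)
  slopes <- snp$beta[c("x1", "x2")]
  expect_true(all(abs(slopes - c(-0.3, 0.4)) < 3 * snp$se[c("x1", "x2")]))
  # fitted heterogeneity density close to N(0, 0.8^2) in sup-norm
  g <- seq(-4, 4, by = 0.01)
  gap <- max(abs(snp_pdf(g, snp$coef) - stats::dnorm(g, 0, 0.8)))
  expect_lt(gap, 0.05)
})

test_that("nested fits are monotone in K", {
  sim <- toy_loggamma_data(n = 300, seed = 29)
  nb <- fit_nb(sim$data)
  f2 <- fit_snp(sim$data, K = 2, fixed_intercept = nb$beta[1], n_starts = 2)
  f1 <- fit_snp(sim$data, K = 1, fixed_intercept = nb$beta[1], n_starts = 2,
                start = list(beta = f2$beta, a = f2$coef$a[2]))
  expect_gte(f2$loglik, f1$loglik - 1e-4)
})

test_that("freeing the intercept never lowers the likelihood", {
  sim <- toy_loggamma_data(n = 300, seed = 41)
  nb <- fit_nb(sim$data)
  fixed <- fit_snp(sim$data, K = 2, fixed_intercept = nb$beta[1],
                   n_starts = 2)
  free <- fit_snp(sim$data, K = 2, fixed_intercept = NULL, n_starts = 2,
                  start = list(beta = fixed$beta, a = fixed$coef$a))
  expect_gte(free$loglik, fixed$loglik - 1e-4)
  expect_equal(free$k, fixed$k + 1L)
})

test_that("heterogeneity summary finds the modes of the fitted density", {
  # K = 0: a single mode at zero
  s0 <- heterogeneity_summary(snp_coef(1))
  expect_equal(nrow(s0$modes), 1L)
  expect_equal(s0$modes$epsilon, 0, tolerance = 1e-6)
  expect_equal(s0$E_eps, 0)

  # empirical-style coefficients: three modes, the major one at negative eps
  a <- snp_coef(c(1, -0.3242, -0.1714, 0.0408))
  s <- heterogeneity_summary(a)
  expect_equal(nrow(s$modes), 3L)
  major <- s$modes[which.max(s$modes$density), ]
  expect_lt(major$epsilon, 0)
  expect_gt(major$mass, 0.9)
  # refinement agrees with a brute-force fine-grid argmax
  fine <- seq(-6, 6, by = 1e-4)
  dens <- snp_pdf(fine, a)
  expect_equal(major$epsilon, fine[which.max(dens)], tolerance = 1e-3)
  # total basin mass accounts for the whole distribution
  expect_equal(sum(s$modes$mass), 1, tolerance = 1e-3)
})

test_that("likelihood evaluation rejects impossible inputs", {
  d <- count_dataset(c(1, 2), cbind(x = c(1, 2)))
  expect_error(snp_loglik(c(1, 2), snp_coef(1), d), "length\\(beta\\)")
  expect_error(fit_snp(d, K = -1), "non-negative")
})
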