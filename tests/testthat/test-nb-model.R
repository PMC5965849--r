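test_that("the pmf reduces to the geometric at unit mean and dispersion", {
  y <- 0:8
  expect_equal(nb_pmf(y, lin_pred = 0, alpha2 = 1), 0.5^(y + 1),
               tolerance = 1e-12)
})

test_that("the pmf is a proper distribution", {
  for (lp in c(0, 1, 2)) {
    for (a2 in c(0.5, 0.8, 1.2)) {
      expect_equal(sum(nb_pmf(0:5000, lp, a2)), 1, tolerance = 1e-10)
    }
  }
})

test_that("the pmf approaches the Poisson as dispersion vanishes", {
  y <- 0:20
  expect_equal(nb_pmf(y, lin_pred = 1, alpha2 = 1e-8),
               stats::dpois(y, exp(1)), tolerance = 1e-5)
})

test_that("closed form equals numeric Poisson-log-gamma integration", {
  for (a2 in c(0.5, 0.8, 1.2)) {
    for (lp in c(-0.5, 0, 1.5)) {
      for (y in c(0, 1, 3, 10)) {
        want <- oracle_mixture_pmf(y, lp, function(e) loggamma_pdf(e, a2))
        expect_equal(nb_pmf(y, lp, a2), want, tolerance = 1e-6)
      }
    }
  }
})

test_that("log-gamma heterogeneity density is correct", {
  for (a2 in c(0.5, 0.8, 1.2)) {
    expect_equal(
      stats::integrate(loggamma_pdf, -40, 8, alpha2 = a2,
                       rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
    # change of variables from the gamma density of t = e^eps
    for (eps in c(-1, 0, 0.5)) {
      want <- stats::dgamma(exp(eps), shape = 1 / a2, scale = a2) * exp(eps)
      expect_equal(loggamma_pdf(eps, a2), want, tolerance = 1e-12)
    }
    # unit-mean construction: E[e^eps] = 1
    Ee <- stats::integrate(function(e) exp(e) * loggamma_pdf(e, a2),
                           -40, 8, rel.tol = 1e-10)$value
    expect_equal(Ee, 1, tolerance = 1e-6)
  }
  expect_error(loggamma_pdf(0, -1), "positive")
  expect_error(nb_pmf(0, 0, 0), "positive")
})

test_that("MLE recovers the generating parameters", {
  sim <- gen_dataset(simulation_spec(n = 1000, hetero_kind = "loggamma",
                                     hetero_params = c(alpha2 = 0.8),
                                     seed = 101))
  fit <- fit_nb(sim$data)
  expect_true(fit$converged)
  truth <- c(1.0, -0.3, 0.4)
  expect_true(all(abs(fit$beta - truth) < 3 * fit$se[1:3]))
  expect_lt(abs(fit$alpha2 - 0.8), 3 * fit$se[["alpha2"]])
  # optimum dominates the generating parameters
  ll_truth <- sum(nb_pmf(sim$data$y, drop(sim$data$X %*% truth), 0.8,
                         log = TRUE))
  expect_gte(fit$loglik, ll_truth)
})

test_that("MLE agrees with an independent NB implementation", {
  skip_if_not_installed("MASS")
  sim <- toy_loggamma_data(n = 500, seed = 13)
  fit <- fit_nb(sim$data)
  df <- data.frame(y = sim$data$y, x1 = sim$data$X[, "x1"],
                   x2 = sim$data$X[, "x2"])
  ref <- MASS::glm.nb(y ~ x1 + x2, data = df)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$alpha2, 1 / ref$theta, tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("dispersion collapses on pure Poisson data", {
  set.seed(55)
  n <- 800
  x <- stats::runif(n, 0, 5)
  y <- stats::rpois(n, exp(0.5 + 0.2 * x))
  d <- count_dataset(y, cbind("(Intercept)" = 1, x = x))
  fit <- fit_nb(d)
  expect_lt(fit$alpha2, 0.05)
  pois <- stats::glm(y ~ x, family = stats::poisson())
  expect_equal(unname(fit$beta), unname(coef(pois)), tolerance = 5e-3)
})

test_that("the fit is invariant to row permutations", {
  sim <- toy_loggamma_data(n = 300, seed = 3)
  fit1 <- fit_nb(sim$data)
  set.seed(1)
  idx <- sample(sim$data$N)
  d2 <- count_dataset(sim$data$y[idx], sim$data$X[idx, ])
  fit2 <- fit_nb(d2)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-8)
  expect_equal(fit1$alpha2, fit2$alpha2, tolerance = 1e-8)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-8)
})

test_that("fixed coefficients and offsets are honored", {
  sim <- toy_loggamma_data(n = 400, seed = 21)
  d <- sim$data
  fit_free <- fit_nb(d)
  # fixing x1 at its estimate reproduces the free fit
  fit_fix <- fit_nb(d, fixed = c(x1 = fit_free$beta[["x1"]]))
  expect_equal(fit_fix$loglik, fit_free$loglik, tolerance = 1e-6)
  expect_equal(fit_fix$k, fit_free$k - 1L)
  # moving x1 into an offset with unit coefficient
  d_off <- count_dataset(d$y, d$X[, c("(Intercept)", "x2")],
                         offset = fit_free$beta[["x1"]] * d$X[, "x1"])
  fit_off <- fit_nb(d_off)
  expect_equal(fit_off$loglik, fit_free$loglik, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_nb(count_dataset(c(0, 0, 0, 0),
                                    cbind(1, c(1, 2, 3, 4)))),
               "all counts are zero")
})

test_that("estimates are unbiased across replicates", {
  reps <- 100
  est <- matrix(NA_real_, reps, 4)
  for (r in seq_len(reps)) {
    sim <- gen_dataset(simulation_spec(n = 300, hetero_kind = "loggamma",
                                       hetero_params = c(alpha2 = 0.8),
                                       seed = 1000 + r))
    f <- fit_nb(sim$data)
    est[r, ] <- c(f$beta, f$alpha2)
  }
  truth <- c(1.0, -0.3, 0.4, 0.8)
  bias <- colMeans(est) - truth
  mc_se <- apply(est, 2, stats::sd) / sqrt(reps)
  expect_true(all(abs(bias) < 3 * mc_se))
})
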