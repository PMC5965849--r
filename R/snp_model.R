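# log(sum(exp(x))) rowwise, tolerating -Inf entries
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

# log f_SNP(s_j) + log w~_j at the quadrature nodes; -Inf at polynomial roots
snp_node_logweights <- function(coef, rule) {
  coef <- as_snp_coef(coef)
  p <- drop(outer(rule$nodes, 0:coef$K, "^") %*% coef$a)
  log(rule$weights) + 2 * log(abs(p)) + stats::dnorm(rule$nodes, log = TRUE) -
    log(norm_constant(coef))
}

#' Marginal log-likelihood of the Poisson-SNP model
#'
#' The sample log-likelihood
#' \deqn{LL(\beta, a) = \sum_i \ln \sum_j \tilde w_j\,
#'   \mathrm{Pois}(y_i \mid e^{x_i\beta + o_i + s_j})\,
#'   f_{SNP}(s_j; a),}
#' the Gauss-Hermite approximation to the intractable marginal over the
#' heterogeneity. The inner sum is evaluated in log-sum-exp form with
#' \eqn{\ln y!} via `lgamma`, so it is stable for large counts and extreme
#' linear predictors.
#'
#' @param beta coefficient vector, one entry per column of `data$X`.
#' @param coef an [snp_coef()] object (or coefficient vector with `a0 = 1`).
#' @param data a [count_dataset()].
#' @param rule a [hermite_rule()]; an order of at least `2 * K + 2` is
#'   recommended so the squared polynomial is integrated exactly.
#' @return The log-likelihood (a single number).
#' @export
snp_loglik <- function(beta, coef, data, rule = hermite_rule(30)) {
  stopifnot(inherits(data, "count_dataset"))
  if (length(beta) != ncol(data$X)) {
    stop("length(beta) must match ncol(data$X)", call. = FALSE)
  }
  lw <- snp_node_logweights(coef, rule)
  lp <- drop(data$X %*% beta) + dataset_offset(data)
  eta <- outer(lp, rule$nodes, "+")            # N x J
  terms <- sweep(data$y * eta - exp(eta), 2L, lw, "+")
  li <- row_logsumexp(terms) - lgamma(data$y + 1)
  bad <- which(!is.finite(li))
  if (length(bad)) {
    stop(sprintf(
      "marginal probability underflowed to zero at observation %d", bad[1L]),
      call. = FALSE)
  }
  sum(li)
}

snp_negloglik <- function(par, data, rule, K, free, beta_fixed) {
  beta <- beta_fixed
  beta[free] <- par[seq_along(free)]
  a <- c(1, par[length(free) + seq_len(K)])
  tryCatch(-snp_loglik(beta, snp_coef(a), data, rule),
           error = function(e) 1e10)
}

#' Fit the Poisson regression model with SNP heterogeneity
#'
#' Maximizes the quadrature marginal likelihood over the free regression
#' coefficients and the polynomial coefficients \eqn{a_1, \ldots, a_K}
#' (\eqn{a_0} fixed at 1 for identification). Because the flexible
#' heterogeneity mean and the regression intercept are not jointly
#' identified, the intercept is by default held fixed — conventionally at
#' the Negative Binomial estimate from the same data — via
#' `fixed_intercept`; pass `NULL` to estimate it freely (then recentre using
#' the reported `E_eps`).
#'
#' The likelihood can be multimodal in `a`, so estimation is multi-started:
#' from `a = 0` (the Gaussian-heterogeneity special case) plus `n_starts`
#' seeded random perturbations, with optional warm starts supplied through
#' `start`. The best converged optimum wins.
#'
#' @param data a [count_dataset()].
#' @param K polynomial length (`K >= 1`; `K = 0` gives the degenerate
#'   Poisson-normal model with no free density parameters).
#' @param fixed_intercept value at which to fix the intercept column, or
#'   `NULL` to leave it free. Ignored when `data$X` has no constant column.
#' @param rule a [hermite_rule()] (default 30 points).
#' @param start optional list(s) with elements `beta` and/or `a` used as
#'   additional starting points (warm starts).
#' @param n_starts number of random perturbation starts around `a = 0`.
#' @param start_seed seed for the perturbation starts (the caller's RNG
#'   state is preserved).
#' @return An object of class `"snp_fit"`: `beta`, `coef` ([snp_coef()]),
#'   `se` (free parameters only), `loglik`, `K`, `fixed_intercept`, `k`
#'   (free-parameter count), `converged`, `vcov`.
#' @export
fit_snp <- function(data, K, fixed_intercept = NULL,
                    rule = hermite_rule(30), start = NULL,
                    n_starts = 5L, start_seed = 1L) {
  stopifnot(inherits(data, "count_dataset"))
  if (length(K) != 1L || K < 0 || K != round(K)) {
    stop("'K' must be a single non-negative integer", call. = FALSE)
  }
  K <- as.integer(K)
  if (rule$order < 2 * K + 2) {
    warning("quadrature order below 2K + 2; increase for accuracy")
  }
  # normalization constant conditioning guard
  if (K > 0) {
    cond <- max(normal_moment(2 * K))
    if (!is.finite(cond) || cond > 1e15) {
      stop("polynomial length K too large for a stable normalization; ",
           "use a smaller K", call. = FALSE)
    }
  }
  p <- ncol(data$X)
  ic <- intercept_column(data)

  beta_fixed <- rep(0, p)
  names(beta_fixed) <- data$names
  is_fixed <- rep(FALSE, p)
  if (!is.null(fixed_intercept) && !is.na(ic)) {
    beta_fixed[ic] <- fixed_intercept
    is_fixed[ic] <- TRUE
  }
  free <- which(!is_fixed)

  # base beta start: Poisson regression on the free columns
  lp_fix <- dataset_offset(data) +
    drop(data$X[, is_fixed, drop = FALSE] %*% beta_fixed[is_fixed])
  beta_start <- if (length(free)) {
    stats::glm.fit(data$X[, free, drop = FALSE], data$y, offset = lp_fix,
                   family = stats::poisson())$coefficients
  } else numeric(0)

  starts <- list(list(beta = beta_start, a = rep(0, K)))
  if (K > 0 && n_starts > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(start_seed)
    for (i in seq_len(n_starts)) {
      starts[[length(starts) + 1L]] <-
        list(beta = beta_start, a = stats::rnorm(K, 0, 0.15))
    }
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }
  if (!is.null(start)) {
    if (!is.null(start$beta) || !is.null(start$a)) start <- list(start)
    for (s in start) {
      b <- if (is.null(s$beta)) beta_start else s$beta[free]
      a <- if (is.null(s$a)) rep(0, K) else {
        a1 <- s$a
        if (length(a1) == K + 1L) a1 <- a1[-1L]  # drop a0 if supplied
        c(a1, rep(0, K - length(a1)))[seq_len(K)]
      }
      starts <- c(list(list(beta = b, a = a)), starts)  # warm starts first
    }
  }

  best <- NULL
  any_converged <- FALSE
  for (s in starts) {
    par0 <- c(s$beta, s$a)
    opt <- tryCatch(
      stats::optim(par0, snp_negloglik, method = "BFGS",
                   data = data, rule = rule, K = K, free = free,
                   beta_fixed = beta_fixed,
                   control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0L) any_converged <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("optimization failed from every starting point", call. = FALSE)
  }

  beta <- beta_fixed
  beta[free] <- best$par[seq_along(free)]
  a <- c(1, best$par[length(free) + seq_len(K)])
  nf <- length(best$par)

  hess <- tryCatch(
    stats::optimHess(best$par, snp_negloglik, data = data, rule = rule,
                     K = K, free = free, beta_fixed = beta_fixed),
    error = function(e) NULL)
  vcov <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) NULL) else NULL
  se <- rep(NA_real_, nf)
  if (!is.null(vcov) && all(is.finite(diag(vcov))) && all(diag(vcov) > 0)) {
    se <- sqrt(diag(vcov))
  } else {
    vcov <- NULL
  }
  names(se) <- c(data$names[free], if (K > 0) paste0("a", 1:K))

  structure(
    list(beta = beta, coef = snp_coef(a), se = se, loglik = -best$value,
         K = K,
         fixed_intercept = if (any(is_fixed)) beta_fixed[ic] else NULL,
         k = nf, converged = any_converged, vcov = vcov, n = data$N,
         model = "SNP"),
    class = "snp_fit"
  )
}

#' @export
print.snp_fit <- function(x, ...) {
  cat(sprintf("Poisson-SNP regression fit (polynomial length K = %d)\n", x$K))
  est <- data.frame(
    Value = c(x$beta, stats::setNames(x$coef$a, paste0("a", 0:x$K))))
  est$SE <- NA_real_
  est[names(x$se), "SE"] <- x$se
  print(round(est, 4))
  if (!is.null(x$fixed_intercept)) {
    cat(sprintf("  (intercept fixed at %.4f; a0 fixed at 1)\n",
                x$fixed_intercept))
  }
  cat(sprintf("logLik %.2f on %d free parameters (n = %d)%s\n",
              x$loglik, x$k, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.snp_fit <- function(object, ...) {
  c(object$beta, stats::setNames(object$coef$a, paste0("a", 0:object$K)))
}

#' @export
logLik.snp_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Summarize a fitted SNP heterogeneity distribution
#'
#' Diagnostics for the estimated heterogeneity density: the density curve on
#' a grid, the modal points (local maxima located by grid search and refined
#' by golden-section optimization in the bracketing interval), the
#' probability mass in the basin around each mode (between adjacent local
#' minima, by trapezoidal integration), and the moments
#' \eqn{E[\varepsilon]} (exact) and \eqn{E[e^\varepsilon]} (30-point
#' quadrature, approximate).
#'
#' Multiple modes indicate latent groups of observation units exposed to
#' different baseline risk levels even after conditioning on the covariates.
#'
#' @param fit an `"snp_fit"` (or an [snp_coef()] directly).
#' @param grid evaluation grid; default -6 to 6 in steps of 0.01.
#' @param min_mass basin-mass floor below which a local maximum is not
#'   reported as a mode: a squared degree-K polynomial times the normal
#'   density can have up to K + 1 local maxima, some carrying negligible
#'   probability.
#' @return A list with `curve` (data frame), `modes` (data frame with
#'   `epsilon`, `density`, `mass`), `E_eps`, `E_exp_eps`.
#' @export
heterogeneity_summary <- function(fit, grid = seq(-6, 6, by = 0.01),
                                  min_mass = 1e-6) {
  coef <- if (inherits(fit, "snp_fit")) fit$coef else as_snp_coef(fit)
  dens <- snp_pdf(grid, coef)
  n <- length(grid)
  is_max <- c(FALSE, dens[2:(n - 1)] > dens[1:(n - 2)] &
                dens[2:(n - 1)] >= dens[3:n], FALSE)
  is_min <- c(TRUE, dens[2:(n - 1)] < dens[1:(n - 2)] &
                dens[2:(n - 1)] <= dens[3:n], TRUE)
  max_idx <- which(is_max)
  min_idx <- which(is_min)

  modes <- lapply(max_idx, function(i) {
    o <- stats::optimize(function(e) snp_pdf(e, coef),
                         lower = grid[max(i - 1L, 1L)],
                         upper = grid[min(i + 1L, n)], maximum = TRUE,
                         tol = 1e-9)
    lo <- max(min_idx[min_idx < i])
    hi <- min(min_idx[min_idx > i])
    seg <- lo:hi
    mass <- sum(diff(grid[seg]) * (dens[seg[-length(seg)]] +
                                     dens[seg[-1L]]) / 2)
    c(epsilon = o$maximum, density = o$objective, mass = mass)
  })
  modes <- as.data.frame(do.call(rbind, modes))
  modes <- modes[modes$mass >= min_mass, , drop = FALSE]
  rownames(modes) <- NULL

  rule <- hermite_rule(30)
  list(
    curve = data.frame(epsilon = grid, density = dens),
    modes = modes,
    E_eps = snp_moment(coef, 1L),
    E_exp_eps = gh_integrate(function(e) exp(e) * snp_pdf(e, coef), rule)
  )
}
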