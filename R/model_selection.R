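#' Goodness-of-fit report
#'
#' Deviance, AIC and BIC from a maximized log-likelihood:
#' \deqn{\mathrm{Deviance} = -2\,LL, \quad \mathrm{AIC} = 2(k - LL), \quad
#'   \mathrm{BIC} = \ln(n)\,k - 2\,LL,}
#' where `k` counts only the freely estimated parameters (a fixed intercept
#' and the identification constant \eqn{a_0} are excluded).
#'
#' @param fit an `"nb_fit"` or `"snp_fit"` (anything with `loglik` and `k`),
#'   or a single log-likelihood value together with `k`.
#' @param n sample size.
#' @param k free-parameter count; taken from `fit` when absent.
#' @return An object of class `"gof_report"` with fields `loglik`,
#'   `deviance`, `aic`, `bic`, `n`, `k`.
#' @examples
#' gof(list(loglik = -100, k = 3), n = 50)
#' @export
gof <- function(fit, n, k = NULL) {
  ll <- if (is.numeric(fit) && length(fit) == 1L) fit else fit$loglik
  if (is.null(k)) k <- fit$k
  if (!is.finite(ll)) stop("log-likelihood must be finite", call. = FALSE)
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  structure(
    list(loglik = ll, deviance = -2 * ll, aic = 2 * (k - ll),
         bic = log(n) * k - 2 * ll, n = n, k = k),
    class = "gof_report"
  )
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("LL %.2f  Deviance %.2f  AIC %.2f  BIC %.2f  (k = %d, n = %d)\n",
              x$loglik, x$deviance, x$aic, x$bic, x$k, x$n))
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' Tests whether the richer model significantly improves the fit:
#' the statistic \eqn{2(LL_1 - LL_0)} is compared against the chi-squared
#' distribution with `df` degrees of freedom (one per added free parameter).
#'
#' @param fit_null,fit_alt nested fits (objects with `loglik` and `k`), the
#'   alternative containing the null.
#' @param df degrees of freedom; defaults to the difference in
#'   free-parameter counts.
#' @param level significance level (default 0.05, i.e. the 5.99 critical
#'   value at 2 degrees of freedom).
#' @return An object of class `"lrt_result"` with `statistic`, `df`,
#'   `critical_value`, `p_value`, `significant`.
#' @export
lrt <- function(fit_null, fit_alt, df = NULL, level = 0.05) {
  if (is.null(df)) df <- fit_alt$k - fit_null$k
  if (length(df) != 1L || df <= 0 || df != round(df)) {
    stop("'df' must be a positive integer", call. = FALSE)
  }
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (stat < -1e-6) {
    stop("fits are not nested: alternative log-likelihood is lower",
         call. = FALSE)
  }
  stat <- max(stat, 0)
  crit <- stats::qchisq(1 - level, df)
  structure(
    list(statistic = stat, df = as.integer(df), critical_value = crit,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         significant = stat > crit, level = level),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf(
    "LR statistic %.2f on %d df; critical value %.2f at level %.2f; p = %.4g %s\n",
    x$statistic, x$df, x$critical_value, x$level, x$p_value,
    if (x$significant) "(significant)" else "(not significant)"))
  invisible(x)
}

#' Forward selection of the SNP polynomial length
#'
#' Fits Poisson-SNP models of increasing polynomial length K = 1, 2, ...,
#' each warm-started from the previous optimum (the added coefficient
#' initialized at zero, which guarantees the maximized log-likelihood is
#' non-decreasing in K), and stops at the first K whose one-coefficient
#' increment fails the likelihood-ratio test, or at `K_max`. The chosen K is
#' the last significant step. In addition to the stepwise df = 1 tests, the
#' overall test of the chosen model against K = 1 is reported.
#'
#' @param data a [count_dataset()].
#' @param K_max largest polynomial length to consider.
#' @param level significance level of each incremental test.
#' @param fixed_intercept passed to [fit_snp()]; defaults to the Negative
#'   Binomial intercept estimate when the data have an intercept column.
#' @param rule a [hermite_rule()].
#' @param ... further arguments to [fit_snp()].
#' @return An object of class `"k_selection"`: `fits` (list indexed by K),
#'   `chosen_K`, `tests` (stepwise [lrt()] results), `overall` (chosen K
#'   vs K = 1, when chosen K > 1), `table` (per-model goodness of fit).
#' @export
select_K <- function(data, K_max, level = 0.05, fixed_intercept = NULL,
                     rule = hermite_rule(30), ...) {
  if (K_max < 1) stop("'K_max' must be at least 1", call. = FALSE)
  if (is.null(fixed_intercept) && !is.na(intercept_column(data))) {
    fixed_intercept <- fit_nb(data)$beta[intercept_column(data)]
  }
  fits <- list()
  tests <- list()
  chosen <- 1L
  prev <- NULL
  for (K in seq_len(K_max)) {
    warm <- if (is.null(prev)) NULL else
      list(beta = prev$beta, a = c(prev$coef$a[-1L], 0))
    fit <- tryCatch(
      fit_snp(data, K = K, fixed_intercept = fixed_intercept, rule = rule,
              start = warm, ...),
      error = function(e) {
        stop(sprintf("fit failed at K = %d: %s", K, conditionMessage(e)),
             call. = FALSE)
      })
    # warm starts make LL non-decreasing in K up to optimizer tolerance; if
    # the optimizer drifted below, fall back to the feasible warm-start point
    # (previous optimum with the added coefficient at zero)
    if (!is.null(prev) && fit$loglik < prev$loglik) {
      fit$beta <- prev$beta
      fit$coef <- snp_coef(c(prev$coef$a, 0))
      fit$loglik <- prev$loglik
    }
    fits[[K]] <- fit
    if (!is.null(prev)) {
      tst <- lrt(prev, fit, df = 1L, level = level)
      tests[[K - 1L]] <- tst
      if (!tst$significant) break
      chosen <- K
    }
    prev <- fit
  }
  overall <- if (chosen > 1L) {
    lrt(fits[[1L]], fits[[chosen]], df = chosen - 1L, level = level)
  } else NULL
  tab <- do.call(rbind, lapply(seq_along(fits), function(K) {
    g <- gof(fits[[K]], n = data$N)
    data.frame(K = K, loglik = g$loglik, deviance = g$deviance,
               aic = g$aic, bic = g$bic, k = g$k)
  }))
  structure(
    list(fits = fits, chosen_K = chosen, tests = tests, overall = overall,
         table = tab, level = level),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("Forward selection of the SNP polynomial length: chosen K = %d\n",
              x$chosen_K))
  print(x$table, row.names = FALSE)
  if (!is.null(x$overall)) {
    cat(sprintf("Chosen K vs K = 1: "))
    print(x$overall)
  }
  invisible(x)
}

#' Export a model-comparison table
#'
#' One row per fitted model with LL, Deviance, AIC, BIC and the
#' free-parameter count, written as CSV or JSON.
#'
#' @param fits named list of fits (`"nb_fit"` / `"snp_fit"`).
#' @param n sample size.
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @return The comparison data frame, invisibly.
#' @export
export_comparison <- function(fits, n, path) {
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    g <- gof(fits[[nm]], n = n)
    data.frame(model = nm, loglik = g$loglik, deviance = g$deviance,
               aic = g$aic, bic = g$bic, k = g$k)
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(tab)
}
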