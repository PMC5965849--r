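#' Moments of the standard normal distribution
#'
#' Returns \eqn{I(n) = \int \varepsilon^n \phi(\varepsilon)\,d\varepsilon} by
#' the recursion \eqn{I(0) = 1}, \eqn{I(1) = 0},
#' \eqn{I(n) = (n-1)\,I(n-2)}: the odd moments vanish and the even moments are
#' the double factorials \eqn{(n-1)!!}. These appear in the normalization
#' constant of the semi-nonparametric density and in its moments.
#'
#' @param n moment order(s); non-negative integers (vectorized).
#' @return `I(n)`, exact integers stored as doubles.
#' @examples
#' normal_moment(0:6) # 1 0 1 0 3 0 15
#' @export
normal_moment <- function(n) {
  if (any(!is.finite(n)) || any(n < 0) || any(n != round(n))) {
    stop("'n' must be non-negative integer(s)", call. = FALSE)
  }
  nmax <- max(n, 1)
  tab <- numeric(nmax + 1L)  # tab[i] = I(i-1)
  tab[1L] <- 1
  if (nmax >= 1L) tab[2L] <- 0
  if (nmax >= 2L) {
    for (i in 2:nmax) tab[i + 1L] <- (i - 1) * tab[i - 1L]
  }
  tab[n + 1L]
}

#' Coefficients of the semi-nonparametric density
#'
#' Constructs and validates the coefficient vector \eqn{a_0, \ldots, a_K} of
#' the semi-nonparametric (SNP) density
#' \deqn{f(\varepsilon) = \frac{(\sum_{m=0}^K a_m \varepsilon^m)^2\,
#'   \phi(\varepsilon)}{\sum_m \sum_n a_m a_n I(m+n)},}
#' a squared polynomial of length K times the standard normal density,
#' normalized in closed form. The leading coefficient is fixed at
#' \eqn{a_0 = 1}: the density is invariant to flipping the sign of the whole
#' coefficient vector, so a sign convention is needed for identification.
#'
#' @param a numeric vector `c(a0, a1, ..., aK)` with `a[1] == 1`.
#' @return An object of class `"snp_coef"` with fields `a` and `K`.
#' @examples
#' snp_coef(c(1, -0.3242, -0.1714, 0.0408))
#' @export
snp_coef <- function(a) {
  a <- as.numeric(a)
  if (length(a) < 1L || any(!is.finite(a))) {
    stop("'a' must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (a[1L] != 1) {
    stop("a0 must be fixed at 1 (identification constraint)", call. = FALSE)
  }
  structure(list(a = a, K = length(a) - 1L), class = "snp_coef")
}

#' @export
print.snp_coef <- function(x, ...) {
  cat(sprintf("SNP density coefficients, polynomial length K = %d\n", x$K))
  print(stats::setNames(x$a, paste0("a", 0:x$K)))
  invisible(x)
}

as_snp_coef <- function(coef) {
  if (inherits(coef, "snp_coef")) coef else snp_coef(coef)
}

#' Normalization constant of the SNP density
#'
#' The denominator \eqn{\sum_{m=0}^K \sum_{n=0}^K a_m a_n I(m+n)} that makes
#' the squared-polynomial-times-normal density integrate to one. It is the
#' second moment of the polynomial under the standard normal and is strictly
#' positive whenever `a` is non-zero (guaranteed here by `a0 = 1`).
#'
#' @param coef an [snp_coef()] object (or a coefficient vector with `a0 = 1`).
#' @return The normalization constant, a positive number.
#' @examples
#' norm_constant(snp_coef(c(1, 0, 1)))  # I(0) + 2 I(2) + I(4) = 6
#' @export
norm_constant <- function(coef) {
  coef <- as_snp_coef(coef)
  a <- coef$a
  idx <- 0:coef$K
  m <- outer(idx, idx, "+")
  sum(outer(a, a) * normal_moment(m))
}

#' Evaluate the SNP probability density
#'
#' @param eps evaluation point(s); finite numeric vector.
#' @param coef an [snp_coef()] object (or a coefficient vector with `a0 = 1`).
#' @return Density values, non-negative.
#' @examples
#' snp_pdf(0, snp_coef(1))  # dnorm(0): K = 0 is the standard normal
#' @export
snp_pdf <- function(eps, coef) {
  coef <- as_snp_coef(coef)
  if (any(!is.finite(eps))) stop("'eps' must be finite", call. = FALSE)
  p <- drop(outer(eps, 0:coef$K, "^") %*% coef$a)
  p^2 * stats::dnorm(eps) / norm_constant(coef)
}

#' Moments of the SNP density
#'
#' Closed-form raw moments: \eqn{E[\varepsilon^r] = \sum_m \sum_n a_m a_n
#' I(m+n+r) / C} with `C` the normalization constant, using the exact normal
#' moment table rather than quadrature.
#'
#' @param coef an [snp_coef()] object (or a coefficient vector with `a0 = 1`).
#' @param r moment order, non-negative integer.
#' @return \eqn{E[\varepsilon^r]}.
#' @examples
#' snp_moment(snp_coef(1), 2)  # unit variance of the standard normal
#' @export
snp_moment <- function(coef, r) {
  coef <- as_snp_coef(coef)
  if (length(r) != 1L || !is.finite(r) || r < 0 || r != round(r)) {
    stop("'r' must be a single non-negative integer", call. = FALSE)
  }
  a <- coef$a
  idx <- 0:coef$K
  m <- outer(idx, idx, "+") + r
  sum(outer(a, a) * normal_moment(m)) / norm_constant(coef)
}

#' Tabulate the SNP density on a grid
#'
#' Convenience wrapper used for curve export and plotting overlays.
#'
#' @param coef an [snp_coef()] object (or a coefficient vector with `a0 = 1`).
#' @param grid finite numeric vector of evaluation points.
#' @return A data frame with columns `epsilon` and `density`.
#' @export
density_curve <- function(coef, grid) {
  if (any(!is.finite(grid))) stop("'grid' must be finite", call. = FALSE)
  data.frame(epsilon = grid, density = snp_pdf(grid, coef))
}

#' Write a density curve to CSV
#'
#' Two-column CSV (`epsilon`, `density`), the export format shared by SNP
#' density curves, log-gamma curves and kernel density estimates so they can
#' be overlaid downstream.
#'
#' @param curve a data frame with columns `epsilon` and `density`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(is.data.frame(curve),
            all(c("epsilon", "density") %in% names(curve)))
  utils::write.csv(curve[, c("epsilon", "density")], path, row.names = FALSE)
  invisible(path)
}
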