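---
title: "Semi-nonparametric heterogeneity in Poisson count regression: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-nonparametric heterogeneity in Poisson count regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcount)
```

## The model

Counts per observation unit are Poisson with a log-linear mean carrying a
random disturbance:

$$\ln \lambda_i = x_i'\beta + o_i + \varepsilon_i, \qquad
  y_i \mid \varepsilon_i \sim \mathrm{Poisson}(\lambda_i),$$

where $o_i$ is an optional exposure offset entering with coefficient 1. The
distribution of $\varepsilon$ is the modelling decision. Two families are
implemented.

**Negative Binomial.** $t = e^\varepsilon \sim \Gamma(1/\alpha^2, \alpha^2)$,
unit mean, variance $\alpha^2$. The marginal pmf is closed form
(`nb_pmf()`), and the implied density of $\varepsilon$ is log-gamma
(`loggamma_pdf()`): unimodal and left-skewed, always. The count variance is
$\mu + \alpha^2\mu^2$.

**Semi-nonparametric (SNP).** The density of $\varepsilon$ is a squared
polynomial of length $K$ times the standard normal density,

$$f(\varepsilon) =
  \frac{\big(\sum_{m=0}^{K} a_m \varepsilon^m\big)^2 \phi(\varepsilon)}
       {\sum_{m=0}^{K}\sum_{n=0}^{K} a_m a_n I(m+n)},$$

with $I(n) = \int \varepsilon^n\phi(\varepsilon)\,d\varepsilon$ given exactly
by the recursion $I(0)=1$, $I(1)=0$, $I(n)=(n-1)I(n-2)$. Squaring makes the
polynomial factor non-negative; the closed-form denominator makes the density
integrate to one for *any* coefficient vector, so estimation is
unconstrained. As $K$ grows the family absorbs skewness and multimodality;
at $K = 0$ it is exactly the standard normal.

Two identification facts shape the implementation:

* $f$ is invariant to flipping the sign of the whole coefficient vector, so
  $a_0$ is fixed at $+1$;
* the mean of $\varepsilon$ trades off against the regression intercept
  (only $E[e^{x\beta+\varepsilon}]$ is identified), so by default the SNP
  intercept is *fixed at the NB estimate* from the same data, which makes NB
  and SNP coefficient tables directly comparable. `fit_snp(...,
  fixed_intercept = NULL)` frees it; `heterogeneity_summary()` then reports
  $E[\varepsilon]$ and $E[e^\varepsilon]$ so results can be re-centred. The
  free-parameter count `k` used by AIC/BIC counts neither the fixed intercept
  nor $a_0$.

## Quadrature

The SNP marginal probability has no closed form. It is evaluated with a
$J$-point Gauss–Hermite rule in the physicists' convention (nodes are roots
of $H_J$), computed at run time by the Golub–Welsch eigendecomposition of the
Jacobi matrix of the Hermite three-term recurrence — never from a stored
table. Two conventions matter:

* **Modified weights.** The stored weights are $\tilde w_j = w_j e^{s_j^2}$,
  so $\int g(s)\,ds \approx \sum_j \tilde w_j\, g(s_j)$ for any integrand
  that carries its own Gaussian decay (here the $\phi$ factor inside
  $f_{SNP}$). Raw weights underflow at the extreme nodes of a 30-point rule
  ($\approx 3\times10^{-21}$ at $s = \pm 6.86$); the modified ones are
  $O(1)$.
* **No $\sqrt2$ rescaling.** The integrand is evaluated at the raw Hermite
  roots; no change of variables is applied. This matches the printed rule the
  method is defined with.

The default order is $J = 30$. The rule integrates
$p(s)e^{-s^2}$ exactly for polynomial degree $\le 2J-1$, but the likelihood
integrand is a Poisson kernel whose width shrinks like $1/\sqrt{y}$ against a
node spacing of roughly $0.4$: per-observation log-likelihood error is
$\sim10^{-7}$ for counts up to 4, $\sim10^{-5}$ around $y = 6$, and
$\sim10^{-3}$–$10^{-2}$ by $y = 20$. This is a property of the method's fixed
rule, not of this implementation (the test suite verifies the implementation
against adaptive integration on small counts, where the rule is sharp, and
documents the envelope at larger ones). For data dominated by very large
counts, raise `order` — any `hermite_rule(J)` can be passed through the
fitting functions — at linear cost in $J$.

## Estimation

`fit_nb()` maximizes the closed-form log-likelihood over
$(\beta, \ln\alpha^2)$ by BFGS; the log parameterization enforces positivity
without box constraints, and the reported $\alpha^2$ standard error is
delta-method. Starting values are Poisson-regression estimates for $\beta$
and a Pearson-residual moment estimate for $\alpha^2$. Standard errors come
from the inverse of the numerically evaluated observed information; a
non-invertible Hessian yields `NA` standard errors rather than an error.

`fit_snp()` maximizes the quadrature log-likelihood, computed throughout in
log-sum-exp form with $\ln y!$ via `lgamma`, over the free $\beta$ and
$a_1,\dots,a_K$. The likelihood can be multimodal in $a$ (the squared
polynomial makes distinct coefficient vectors yield similar densities), so
estimation is multi-started: $a = 0$ — the Gaussian special case — plus
`n_starts = 5` seeded $N(0, 0.15^2)$ perturbations, with any user-supplied
warm starts tried first; the best optimum wins. The perturbation seed is an
explicit argument (`start_seed`) and the caller's RNG state is saved and
restored, so fits never perturb simulation reproducibility. Convergence is
BFGS with relative tolerance $10^{-12}$ and up to 1000 iterations; the
`converged` flag records whether any start converged by that criterion.

`select_K()` fits $K = 1, 2, \dots$, warm-starting each fit from the
previous optimum with the added coefficient at zero. That warm start
guarantees the likelihood path is non-decreasing in $K$ (the start point
already attains the previous optimum; if the optimizer somehow drifts below
it, the feasible warm-start point itself is returned). Each increment is
tested by a likelihood-ratio test with one degree of freedom at level 0.05
(the 5% $\chi^2_1$ threshold, 3.84); selection stops at the first
non-significant increment or at `K_max`. Because the stopping rule could
also be read as testing blocks of added coefficients, the overall test of
the chosen model against $K = 1$ (df = chosen $K - 1$; the familiar
$\chi^2_2$ critical value 5.99 when the chosen $K$ is 3) is reported
alongside the stepwise path rather than instead of it.

Degenerate inputs are rejected with descriptive errors: all-zero responses,
non-integer or negative counts, dispersion or bandwidth $\le 0$, polynomial
lengths whose moment table would overflow the normalization constant. A
marginal probability that underflows to zero at some observation raises an
error naming that observation rather than returning `-Inf`.

## The simulation designs

`gen_dataset()` reproduces four reference designs. All draw
$x_1, x_2 \sim$ i.i.d. $U(0,5)$ and $y \sim
\mathrm{Poisson}(e^{x'\beta + \varepsilon})$; they differ in the
heterogeneity law:

| design     | $\varepsilon$ | default $\beta$ | default $n$ |
|------------|----------------------------------------------------------------|------------------|------|
| `loggamma` | $\ln t$, $t \sim \Gamma(1/\alpha^2, \alpha^2)$, $\alpha^2=0.8$  | $(1.0,-0.3,0.4)$ | 1000 |
| `normal`   | $N(\mu,\sigma^2)$, $\mu=0$, $\sigma=0.8$                        | $(0,-0.3,0.4)$, no intercept | 1000 |
| `bimodal`  | $3\cdot\mathbf 1(u_1>0.4) + 1.5u_2 + 0.5\eta - 2.5$             | $(0,-0.3,0.4)$, no intercept | 500  |
| `trimodal` | $3\cdot\mathbf 1(u_1>0.8) - 3\cdot\mathbf 1(u_2>0.7) + 2u_3 + 0.5\eta - 1.0$ | $(0,-0.3,0.4)$, no intercept | 500  |

The normal designs also arise with $\sigma = 1.2$; the `sigma = 0.8` default
is the first of the two study conditions. The two mixture designs have means
$0.05$ and $-0.3$ and variances $2.60$ and $3.91$; their analytic densities
are awkward, which is why `kde_density()` (Gaussian kernel, explicit
bandwidth, default $h = 0.3$ for the bimodal and $0.4$ for the trimodal
sample, evaluated on the $-6.0, -5.9, \dots, 6.0$ grid) is provided for
visual comparison with fitted SNP curves. No bandwidth selection rule is
implemented — the bandwidth is part of the design.

One root seed is split deterministically into three sub-streams (covariates,
heterogeneity, Poisson draws), so designs sharing a root seed share covariate
draws across heterogeneity kinds, and every dataset is bit-reproducible.

What the generators deliberately do *not* emulate about real crash data:
covariates are independent and uniform (real roadway variables are skewed and
collinear), there is no exposure offset, no excess zeros beyond what the
mixed Poisson implies, and counts are moderate (means around $e^{1.5}$).
Passing the recovery tests on these designs shows the estimator is correct
and the SNP family flexible; it does not show robustness to covariate
collinearity, measurement error, or the extreme count ranges (maxima in the
hundreds) seen in long-period crash panels.

## Behaviour under misspecification worth knowing

* **Pure Poisson data.** Every SNP member carries diffuse heterogeneity
  (at small $K$ the density cannot concentrate much beyond the standard
  normal), so on homogeneous data the SNP likelihood sits *below* a plain
  Poisson fit and climbs toward that bound as $K$ grows, with the fitted
  heterogeneity variance shrinking. The selection path is not flat, and the
  chosen $K$ can reach `K_max`. The NB model degenerates gracefully instead
  ($\hat\alpha^2 \to 0$). Fit both; if $\hat\alpha^2$ is tiny, the
  heterogeneity machinery is not needed.
* **Modes with negligible mass.** A squared degree-$K$ polynomial times
  $\phi$ has up to $K+1$ local maxima, and fitted densities routinely carry
  extra maxima with $\sim10^{-7}$ probability mass in the far tails.
  `heterogeneity_summary()` therefore reports a mode only when the
  probability mass in its basin (between adjacent local minima, by
  trapezoidal integration on a 0.01 grid, with the mode location refined by
  golden-section search) exceeds `min_mass` ($10^{-6}$ by default).
* **Large-count accuracy.** See the quadrature section: with the default
  30-point rule, per-observation likelihood contributions of counts beyond a
  few dozen are increasingly approximate. The estimator remains usable (the
  error is smooth in the parameters) but reported log-likelihoods on such
  data carry quadrature error in the second or third decimal.

## Problem sizes in the test suite

The suite verifies parameter recovery at the reference design sizes
($n = 1000$ for the log-gamma and normal designs, $n = 500$ for the mixture
designs) with single seeded replicates, replicate batteries where a rate is
asserted (10 bimodal replicates for slope recovery, 3 normal replicates for
the selected $K$, 100 replicates at $n = 300$ for NB unbiasedness), and
$n = 10^5$ draws for generator moment checks. Oracle comparisons use
adaptive quadrature (`stats::integrate`) on $(-40, 12)$ — the lower limit
reaches $-40$ because the log-gamma left tail decays only like
$e^{\varepsilon/\alpha^2}$ and a $(-12,12)$ window would truncate
$\sim4\times10^{-5}$ of its mass at $\alpha^2 = 1.2$. Independent
cross-checks come from `MASS::glm.nb` (with $\theta = 1/\alpha^2$) for the
NB fit and `pracma::gaussHermite` for the quadrature rule; both are used
only as oracles.

## Known limitations

* No random-variate generation, CDF or quantiles for the SNP density; the
  package estimates and evaluates it.
* No random-parameter (random-slope) formulations, zero inflation, or NB1
  variants.
* Standard errors are observed-information based; no sandwich or bootstrap
  options.
* The SNP likelihood is multimodal in the polynomial coefficients; the
  seeded multi-start is a guard, not a guarantee. For final results increase
  `n_starts` and check stability.
* Forward selection tests each increment at a fixed level with no
  multiplicity correction, mirroring the method's published usage.
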