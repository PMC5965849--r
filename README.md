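# snpcount

Count regression with flexibly distributed unobserved heterogeneity, for
overdispersed event-frequency data such as motor-vehicle crash counts on
highway segments.

## The problem

Counts `y_i` (e.g. crashes on road section *i* over a study period) are
modelled as Poisson with a log-linear mean that carries a random disturbance:

```
ln(lambda_i) = x_i' beta + eps_i,      y_i | eps_i ~ Poisson(lambda_i)
```

The disturbance `eps_i` represents unobserved heterogeneity — risk factors
that were never measured — and its distribution determines how the counts are
overdispersed. The ubiquitous Negative Binomial (NB) model is the special
case where `exp(eps)` is gamma distributed with unit mean and variance
`alpha^2`: analytically convenient (the marginal pmf is closed form), but the
implied log-gamma law for `eps` is unimodal and skewed by construction, so it
cannot represent symmetric, let alone multimodal, heterogeneity.

`snpcount` replaces the log-gamma assumption with a semi-nonparametric (SNP)
density: a squared polynomial of length `K` times the standard normal
density,

```
f(eps) = (sum_{m=0}^K a_m eps^m)^2 phi(eps) / sum_{m,n} a_m a_n I(m+n)
```

with `a_0 = 1` for identification and `I(n)` the standard normal moments
(`I(0) = 1`, `I(1) = 0`, `I(n) = (n-1) I(n-2)`). As `K` grows this family
approximates a wide class of densities — normal, log-gamma-like, bimodal,
trimodal. The marginal likelihood has no closed form and is evaluated by
30-point Gauss–Hermite quadrature; `beta` and `a_1..a_K` are estimated by
maximum likelihood, and `K` is selected forward by likelihood-ratio testing
(add a coefficient while the chi-squared test at the 5% level says it pays).
Multimodality in the fitted `f(eps)` is directly interpretable: latent groups
of observation units exposed to different baseline risk even after
conditioning on the covariates.

The package provides, as plain R functions with S3 fit objects:

* `hermite_rule()` / `gh_integrate()` — the Gauss–Hermite rule (modified
  weights `w * exp(s^2)`, computed by Golub–Welsch, never hard-coded);
* `snp_coef()`, `snp_pdf()`, `snp_moment()`, `norm_constant()` — the SNP
  density and its exact moment algebra;
* `fit_nb()` — the NB benchmark (own MLE over `beta, ln alpha^2`);
* `fit_snp()`, `snp_loglik()`, `heterogeneity_summary()` — the Poisson-SNP
  model, with the intercept conventionally fixed at the NB estimate (the
  heterogeneity mean and the intercept are not jointly identified);
* `gof()`, `lrt()`, `select_K()` — deviance/AIC/BIC, likelihood-ratio tests
  and forward selection of `K`;
* `simulation_spec()` / `gen_dataset()` / `run_experiment()` — seeded
  generators for the four reference designs (log-gamma, normal, bimodal,
  trimodal heterogeneity);
* `kde_density()` — Gaussian kernel density estimation for visual comparison
  of heterogeneity samples with fitted curves;
* `model_config()` / `load_dataset()` / `run_analysis()` and a CLI
  (`inst/cli/snpcount.R` with verbs `simulate`, `fit`, `select-k`,
  `summarize`, `convert`) for CSV data with declared column transforms and
  exposure offsets.

## Worked example

Simulate the log-gamma reference design (n = 1000, `x1, x2 ~ U(0,5)`,
`beta = (1.0, -0.3, 0.4)`, `alpha^2 = 0.8`) and compare the NB fit with the
SNP fit of polynomial length 4:

```r
library(snpcount)

spec <- simulation_spec(n = 1000, hetero_kind = "loggamma",
                        hetero_params = c(alpha2 = 0.8), seed = 42)
sim <- gen_dataset(spec)

nb <- fit_nb(sim$data)
nb
#> Negative Binomial (Poisson-gamma) regression fit
#>               Value     SE
#> (Intercept)  0.9890 0.0877
#> x1          -0.3348 0.0223
#> x2           0.4351 0.0229
#> alpha2       0.7443 0.0489
#> logLik -2448.85 on 4 free parameters (n = 1000)

snp <- fit_snp(sim$data, K = 4, fixed_intercept = nb$beta[1])
snp
#> Poisson-SNP regression fit (polynomial length K = 4)
#>               Value     SE
#> (Intercept)  0.9890     NA
#> x1          -0.3378 0.0216
#> x2           0.4535 0.0240
#> a0           1.0000     NA
#> a1          -0.0442 0.0723
#> a2          -0.2119 0.0367
#> a3          -0.0584 0.0130
#> a4           0.0300 0.0058
#>   (intercept fixed at 0.9890; a0 fixed at 1)
#> logLik -2448.40 on 6 free parameters (n = 1000)
```

Both models recover the generating coefficients within sampling error; the
dispersion estimate 0.744 sits within two standard errors of the true 0.8,
and the SNP log-likelihood tracks the NB one to within half a unit — at
`K = 4` the SNP family has learned a log-gamma-shaped density from the data
without being told its form. Goodness of fit per model:

```r
gof(nb, n = 1000)
#> LL -2448.85  Deviance 4897.71  AIC 4905.71  BIC 4925.34  (k = 4, n = 1000)
gof(snp, n = 1000)
#> LL -2448.40  Deviance 4896.81  AIC 4908.81  BIC 4938.25  (k = 6, n = 1000)
```

Here AIC/BIC favour the NB model, as they should: the data were generated
from it, and the two extra SNP coefficients buy almost no likelihood. On data
whose heterogeneity the log-gamma cannot express (multimodal risk groups),
the ranking flips — see the simulation designs `"bimodal"` and `"trimodal"`
and the methods vignette. The fitted heterogeneity can be inspected directly:

```r
heterogeneity_summary(snp)$modes
#>   epsilon density   mass
#> 1 -0.0482  0.4630 0.9993
```

(modes carrying less than `min_mass` probability are suppressed).

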