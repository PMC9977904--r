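# bifcop

Bi-factor and second-order **copula** models for ordinal item response data.

Psychological scales and educational tests group their items into
non-overlapping domains (testlets, facets).  The classical bi-factor model
(a common factor plus one factor per group) and second-order model (group
factors linked through a single higher-order factor) assume joint normality
of the underlying scores, which cannot represent items with excess
probability in the joint tails — e.g. items answered from a worst-case or
best-case recollection (discretised minima/maxima) or by a heterogeneous
population (mixtures of means).  `bifcop` replaces every item–factor and
factor–factor link with a parametric bivariate copula (bivariate normal,
Student t with fixed df, Gumbel, survival Gumbel, and reflected Gumbel for
negative dependence), keeping the Gaussian models as the all-BVN special
case while allowing asymmetric and tail dependence.

With `K` ordinal categories, uniform-scale cutpoints `a[j,k]` and copula
conditional cdfs `h(u|v) = dC(u,v)/dv`, the bi-factor joint pmf is

    pi(y) = ∫₀¹ ∏_g { ∫₀¹ ∏_{j∈g} [ h_{jg|Vg;V0}( h_{jg|V0}(a[j,y+1] | v0) | vg )
                                   − (same at a[j,y]) ] dvg } dv0

evaluated by nested Gauss–Legendre quadrature (default 25 points per
dimension); the second-order pmf has the same nested form with *dependent*
inner quadrature points `C⁻¹(v_q2 | v_q1; δ_g)` that follow the one-factor
copula of the group factors.  Only one-dimensional integrals are needed
regardless of the number of groups.

The package provides:

* `bicop()`, `pbicop()`, `dbicop()`, `hbicop()`, `hinv_bicop()`,
  `reflect_bicop()`, `tau_to_par()` — the bivariate copula toolbox;
* `bifactor_model()`, `secondorder_model()`, `model_pmf()`,
  `model_margin()`, `gaussian_loadings()` — model objects and probabilities;
* `simulate_responses()` — exact seeded simulation;
* `fit_factor_copula()` — two-step IFM (cutpoints from sample proportions,
  copula parameters by quasi-Newton with a compiled likelihood kernel) or
  full ML; `tidy()`/`glance()`/`autoplot()` methods; `vuong_test()`;
* `semicorr_table()`, `sample_polychoric()`, `sample_semicorr()`,
  `theoretical_semicorr()` — polychoric semi-correlation diagnostics of
  tail asymmetry;
* `select_families()` — heuristic AIC-based assignment of one copula family
  per factor;
* `m2_test()`, `max_discrepancy()` — limited-information M2 goodness of
  fit (bivariate-margin residuals, chi-square with `s − q` df, RMSEA2) and
  maximum bivariate discrepancies;
* `read_responses()`/`write_responses()` and a CLI wrapper
  (`inst/cli/bifcop`) with `simulate`, `fit`, `select`, `gof`, `diagnose`
  subcommands.

## Worked example

```r
library(bifcop)

## an all-Gumbel bi-factor model: 8 items in two groups of 4, K = 3,
## group Kendall taus 0.45/0.55 (common factor) and 0.30/0.35 (group factors)
m   <- study_bifactor_model(d = 8, G = 2, K = 3, family = "gumbel",
                            tau_theta = c(0.45, 0.55),
                            tau_delta = c(0.30, 0.35))
dat <- simulate_responses(m, 500, seed = 1)

fit <- fit_factor_copula(dat, groups = c(4, 4), families = "gumbel")
glance(fit)
#> # A tibble: 1 × 12
#>   model    method     n     d     G     K logLik npar_copula     q   AIC   n_q converged
#>   <chr>    <chr>  <int> <int> <int> <int>  <dbl>       <int> <int> <dbl> <int> <lgl>
#> 1 bifactor ifm      500     8     2     3 -3677.          16    32 7385.    25 TRUE

tidy(fit)[1:3, c("term", "factor", "family", "tau", "se_tau")]
#> # A tibble: 3 × 5
#>   term         factor family   tau se_tau
#>   <chr>        <chr>  <chr>  <dbl>  <dbl>
#> 1 theta[item1] common gumbel 0.532 0.0336
#> 2 theta[item2] common gumbel 0.456 0.0436
#> 3 theta[item3] common gumbel 0.568 0.0348

m2_test(fit)
#> # A tibble: 1 × 7
#>   statistic     s     q    df p_value  rmsea2     n
#>       <dbl> <int> <int> <int>   <dbl>   <dbl> <int>
#> 1      97.0   128    32    96   0.451 0.00463   500
```

The fitted taus sit near the generating values 0.45/0.55 (standard errors
≈ 0.03–0.04 at `n = 500`), and `M2 = 97.0` on 96 degrees of freedom
(`p = 0.45`, `RMSEA2 = 0.005`) shows the expected fit of a well-specified
model.  `semicorr_table(dat, c(4, 4))` prints an observed upper
semi-correlation of 0.44 against 0.29 for a matched BVN copula — the
heavier upper tail that motivates the Gumbel choice (at `K = 3` the lower
quadrant holds a single category and its semi-correlation is undefined) —
and `select_families(dat, c(4, 4))` recovers the Gumbel family for the
common factor from the default candidate set.

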