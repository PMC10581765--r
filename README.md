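# zoodemog

Bayesian Siler demography for census data from zoological institutions.

## What problem this solves, and for whom

Zoos, aquaria and sanctuaries keep studbook-style census records: one row
per animal with its sex, provenance (captive- or wild-born), birth date
(sometimes only an interval), entry date, departure date and whether the
departure was a death. Population biologists and animal-welfare
researchers use such records to ask whether survival has improved over
time, how it compares with wild populations, and whether the sexes
differ — but the records are statistically awkward: wild-born animals
enter observation years after birth (left truncation), transfers and
ongoing animals are right-censored, and many birth dates are uncertain.

`zoodemog` implements the full analysis pipeline for this setting:

* **Siler mortality model.** The hazard at age `x` (years) is
  `mu(x) = exp(a0 - a1 x) + c + exp(b0 + b1 x)` — declining juvenile
  mortality, a constant background hazard, and Gompertz senescence. The
  cumulative hazard `U(x)` has a closed form; survival is
  `S(x) = exp(-U(x))`.
* **Bayesian estimation.** Metropolis–Hastings MCMC on the five Siler
  parameters (optionally a proportional-hazards provenance effect
  `exp(gamma)`), with the left-truncated right-censored likelihood
  `f(x)/S(xt)` (death) or `S(x)/S(xt)` (censored), and latent birth
  times for interval-birth records. Compiled (Rcpp) likelihood kernel;
  Gelman–Rubin R-hat convergence diagnostics.
* **Demographic functionals.** Remaining life expectancy
  `e_x = int_x S(t) dt / S(x)`, lifespan equality
  `eps_x = -log H_x` (with `H_x` the survival-weighted accumulation of
  mortality after `x`), first-year mortality `q1 = 1 - S(1)`; posterior
  densities of all of them. Product-limit (Kaplan–Meier) life tables and
  the discrete life-expectancy approximation `sum(l_i)/l_x`.
* **Calibrated Kullback–Leibler comparison.** KL discrepancies between
  posterior densities across periods or sexes, calibrated to [0, 1] via
  the Bernoulli device `cal = sqrt(1 - exp(-2 KL))` (0 = identical
  densities, 1 = no overlap).
* **Wild-population reconstruction.** Least-squares Siler fits to
  published stage-specific survival probabilities (weighted by
  cumulative survival) or cumulative-survival curves, with an
  age-at-maturity penalty tied to the age at minimum hazard, and
  quantile placement of the wild point estimates on the zoo posteriors.
* **Synthetic censuses with known truth.** A generator that emulates
  staggered entry, period strata, wild-born truncation, censoring and
  interval births, so the whole pipeline is testable without any
  restricted data.

## Worked example

Simulate a census whose truth is known, fit the females, and read off the
posterior demography:

```r
library(zoodemog)

p_truth <- siler_params(a0 = -0.7, a1 = 1, c = 0.03, b0 = -5, b1 = 0.16)
spec <- scenario_spec(true_params = list(F = p_truth, M = p_truth),
                      window = c(1985, 2021), period_breaks = 2003,
                      n_per_period = 150, frac_wild = 0.2,
                      censor_rate = 0.03, seed = 42)
sim <- generate_census(spec)

cfg <- mcmc_config(n_chains = 4, n_iter = 6000, burn_in = 1500,
                   thinning = 10, seed = 1)
fit <- run_mcmc(subset(sim$records, sex == "F"), cfg)
fit
#> Siler posterior chains: 4 chains x 450 retained draws; 300 records
#> psrf (Gelman-Rubin R-hat):
#>     a0     a1      c     b0     b1
#> 0.9999 1.0030 1.0131 1.0094 1.0091

posterior_functionals(fit, ages = 1)$summary
#>   functional lower median  upper
#> 1         e1 9.328 10.338 11.451
#> 2       eps1 0.353  0.484  0.625
#> 3         q1 0.200  0.253  0.311
```

All three 95% credible intervals cover the generating truth
(`e1 = 10.56` yr of remaining life expectancy at age 1,
`eps1 = 0.397`, `q1 = 0.296`): the sampler has recovered the mortality
schedule from 300 truncated, censored records. `run_full_analysis()`
wraps the same machinery per sex-by-period stratum and adds the
calibrated KL tables, wild-fit placement and a data-preparation audit;
the `zoodemog` CLI (`inst/exec/zoodemog`) exposes `simulate`, `fit`,
`metrics`, `compare`, `wildfit` and `report` subcommands.

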