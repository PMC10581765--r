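test_that("psrf behaves like the Gelman-Rubin diagnostic", {
  set.seed(1)
  ch <- rnorm(5000)
  # copies of one chain: B = 0, so R-hat = sqrt((n-1)/n) ~ 1
  expect_equal(psrf(list(ch, ch, ch)), 1, tolerance = 1e-3)
  # i.i.d. chains from the same distribution
  chains <- replicate(4, rnorm(1e4), simplify = FALSE)
  expect_lt(psrf(chains), 1.01)
  # well-separated chains
  expect_gt(psrf(list(rnorm(1000), rnorm(1000, 10))), 1.1)
  expect_error(psrf(list(rnorm(100))), "2 chains")
  expect_error(psrf(list(rnorm(100), rnorm(50))), "equal lengths")
  # oracle: coda's (non-corrected) point estimate on the same draws
  if (requireNamespace("coda", quietly = TRUE)) {
    ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
    gd <- coda::gelman.diag(ml, autoburnin = FALSE, transform = FALSE)
    expect_equal(psrf(chains), unname(gd$psrf[1, 1]), tolerance = 0.005)
  }
})

test_that("identical seeds give bit-identical chains", {
  sim <- simulate_cohort(p_baseline, 150, censor_frac = 0.2,
                         trunc_frac = 0.15, seed = 12)
  ch1 <- run_mcmc(sim$records, cfg_smoke(seed = 33))
  ch2 <- run_mcmc(sim$records, cfg_smoke(seed = 33))
  expect_identical(ch1$chains, ch2$chains)
  ch3 <- run_mcmc(sim$records, cfg_smoke(seed = 34))
  expect_false(identical(ch1$chains, ch3$chains))
})

test_that("posterior functionals map draws through the demography layer", {
  # chains collapsed to one repeated parameter vector -> zero-width CIs
  th <- as.numeric(unclass(p_baseline))
  m <- matrix(rep(th, each = 50), 50, 5,
              dimnames = list(NULL, c("a0", "a1", "c", "b0", "b1")))
  fake <- structure(list(chains = list(m, m),
                         par_names = colnames(m),
                         unknown_ids = character(0), n_records = 50),
                    class = "posterior_chains")
  fn <- suppressWarnings(posterior_functionals(fake, ages = 1))
  expect_equal(fn$summary$lower, fn$summary$upper, tolerance = 1e-12)
  e1_direct <- life_expectancy(p_baseline, 1)
  expect_equal(fn$summary$median[fn$summary$functional == "e1"], e1_direct,
               tolerance = 1e-8)
  expect_equal(fn$summary$median[fn$summary$functional == "q1"],
               first_year_mortality(p_baseline), tolerance = 1e-10)
  # constant-hazard posterior concentrated near c = 0.2 -> e1 near 5
  thc <- as.numeric(unclass(p_const(0.2)))
  set.seed(3)
  mc <- matrix(rep(thc, each = 300), 300, 5,
               dimnames = list(NULL, c("a0", "a1", "c", "b0", "b1")))
  mc[, "c"] <- 0.2 + rnorm(300, 0, 0.002)
  fake2 <- structure(list(chains = list(mc), par_names = colnames(mc),
                          unknown_ids = character(0), n_records = 300),
                     class = "posterior_chains")
  fn2 <- suppressWarnings(posterior_functionals(fake2, ages = 1))
  e1m <- fn2$summary$median[fn2$summary$functional == "e1"]
  expect_equal(e1m, 5, tolerance = 0.02)
})

test_that("posterior mean approaches the MLE on a large cohort", {
  set.seed(14)
  x <- sample_ages_at_death(p_baseline, 2000)
  rec <- data.frame(x = x, xt = 0, death = TRUE)
  cfg <- mcmc_config(n_chains = 3, n_iter = 5000, burn_in = 1500,
                     thinning = 5, seed = 15)
  ch <- run_mcmc(rec, cfg)
  post <- as.matrix(ch)
  nll <- function(eta) {
    p <- try(siler_params(eta[1], exp(eta[2]), exp(eta[3]), eta[4],
                          exp(eta[5])), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    -cohort_loglik(rec, p)
  }
  fit <- stats::optim(c(-0.5, 0, log(0.05), -4.5, log(0.12)), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-12))
  mle <- c(fit$par[1], exp(fit$par[2]), exp(fit$par[3]), fit$par[4],
           exp(fit$par[5]))
  pm <- colMeans(post[, 1:5])
  ps <- apply(post[, 1:5], 2, sd)
  # posterior mean within ~3 posterior SDs of the MLE, parameter by parameter
  expect_true(all(abs(pm - mle) < 3 * ps + 1e-3))
})

test_that("proportional-hazards effect is recovered", {
  p <- p_baseline
  set.seed(16)
  n <- 1000
  g_true <- log(1.5)
  prov <- rep(c("captive_born", "wild_born"), each = n / 2)
  eg <- ifelse(prov == "wild_born", exp(g_true), 1)
  x <- zoodemog:::rsiler_conditional(p, rep(0, n), eg = eg)
  rec <- data.frame(x = x, xt = 0, death = TRUE, provenance = prov)
  cfg <- mcmc_config(n_chains = 2, n_iter = 4000, burn_in = 1500,
                     thinning = 5, seed = 17)
  ch <- run_mcmc(rec, cfg, proportional_hazards = TRUE)
  expect_true("gamma_wild_born" %in% ch$par_names)
  g <- as.matrix(ch)[, "gamma_wild_born"]
  ci <- stats::quantile(g, c(0.025, 0.975))
  expect_gt(ci[1], 0)          # excludes 0
  expect_lt(abs(mean(g) - g_true), 0.25)
})

test_that("latent birth times are sampled within their intervals", {
  sim <- simulate_cohort(p_baseline, 200, censor_frac = 0.15,
                         trunc_frac = 0.3, interval_frac = 0.3, seed = 18)
  ch <- run_mcmc(sim$records, cfg_smoke(seed = 19))
  expect_equal(length(ch$unknown_ids), sum(sim$truth$unknown_birth))
  bd <- do.call(rbind, ch$birth_chains)
  tms <- zoodemog:::census_times(sim$records)
  unk <- which(!tms$known)
  for (k in seq_along(unk)) {
    expect_gte(min(bd[, k]), tms$bmin[unk[k]] - 1e-9)
    expect_lte(max(bd[, k]), tms$bmax[unk[k]] + 1e-9)
  }
  # posterior mean births lie inside their intervals and are returned by id
  pmb <- posterior_mean_births(ch)
  expect_setequal(pmb$id, ch$unknown_ids)
})

test_that("small cohorts trigger the sample-size warning", {
  sim <- simulate_cohort(p_baseline, 50, seed = 20)
  expect_warning(run_mcmc(sim$records, cfg_smoke(seed = 21)),
                 "fewer than 100")
})
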