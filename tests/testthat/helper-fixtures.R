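# Shared fixtures for the test suite.

# canonical mixed-phase parameter set used across modules
p_mixed <- siler_params(0, 1, 0.1, -2, 0.2)

# effectively constant hazard: both exponential terms suppressed
p_const <- function(c) siler_params(-40, 1, c, -40, 0.01)

# species-shaped truth used for recovery experiments
p_baseline <- siler_params(-0.7, 1.0, 0.03, -5.0, 0.16)

# random valid parameter sets in the mammalian range
random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    siler_params(a0 = runif(1, -2, 1), a1 = runif(1, 0.5, 2),
                 c = runif(1, 0.005, 0.1), b0 = runif(1, -7, -2),
                 b1 = runif(1, 0.05, 0.3)))
}

# quadrature oracle for the cumulative hazard (independent of the closed form)
U_quad <- function(p, x)
  stats::integrate(function(t) siler_hazard(p, t), 0, x,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value

# small fast MCMC config for smoke tests
cfg_smoke <- function(seed = 1, n_chains = 2)
  mcmc_config(n_chains = n_chains, n_iter = 1500, burn_in = 500,
              thinning = 5, seed = seed)
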