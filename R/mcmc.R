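#' MCMC configuration
#'
#' Defaults follow the analysis protocol for zoo census data: eight parallel
#' chains of 50,000 Metropolis-Hastings iterations, a burn-in of 10,000 and
#' thinning every 20 iterations. Proposal standard deviations adapt during
#' burn-in toward an acceptance rate of about 0.25 and are then frozen.
#'
#' @param n_chains Number of parallel chains (>= 2 for convergence
#'   diagnostics).
#' @param n_iter Iterations per chain.
#' @param burn_in Burn-in iterations discarded from each chain.
#' @param thinning Keep every `thinning`-th post-burn-in iteration.
#' @param seed Base integer seed; chain `k` uses `seed + k - 1`.
#' @param proposal_sd Initial per-coordinate random-walk proposal scales on
#'   the sampling scale (a0, log a1, log c, b0, log b1); `NULL` (the
#'   default) derives them from the curvature of the log-posterior at its
#'   mode, which the burn-in adaptation then refines.
#' @param adapt_interval Iterations between proposal-scale adaptations
#'   during burn-in.
#' @param target_acceptance Acceptance rate targeted by the adaptation.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 8, n_iter = 50000, burn_in = 10000,
                        thinning = 20, seed = 1, proposal_sd = NULL,
                        adapt_interval = 50, target_acceptance = 0.25) {
  if (burn_in >= n_iter) stop("burn_in must be < n_iter")
  if (thinning < 1) stop("thinning must be >= 1")
  if (n_chains < 2) warning("fewer than 2 chains: convergence diagnostics ",
                            "will be unavailable")
  structure(list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 thinning = thinning, seed = seed, proposal_sd = proposal_sd,
                 adapt_interval = adapt_interval,
                 target_acceptance = target_acceptance),
            class = "mcmc_config")
}

#' Default weakly-informative prior
#'
#' Normal(0, 10) on the unconstrained log-level parameters a0 and b0,
#' half-Normal(1) on the positive parameters a1, c and b1, and Normal(0, 2)
#' on proportional-hazard coefficients. Proper and diffuse on the scales on
#' which mammalian Siler parameters live.
#'
#' @param mean Prior means for a0 and b0.
#' @param sd Prior standard deviations for (a0, a1, c, b0, b1); for the
#'   positive parameters this is the half-normal scale.
#' @param gamma_sd Prior standard deviation of proportional-hazard
#'   coefficients.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(mean = c(a0 = 0, b0 = 0),
                       sd = c(a0 = 10, a1 = 1, c = 1, b0 = 10, b1 = 1),
                       gamma_sd = 2) {
  structure(list(mean = mean, sd = sd, gamma_sd = gamma_sd),
            class = "prior_spec")
}

# Central finite-difference Hessian of a scalar function (used for the
# curvature of the log-posterior at its mode; 2k^2 + 1 evaluations).
fd_hessian <- function(f, x, rel = 1e-3) {
  k <- length(x)
  h <- pmax(abs(x) * rel, 1e-4)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  (H + t(H)) / 2
}

# Coerce run_mcmc input to the internal representation. Accepts either the
# dated census schema or a pre-computed age schema with columns
# x (age at exit), xt (entry age), death, and optionally provenance/id.
mcmc_data <- function(records) {
  if (all(c("x", "xt", "death") %in% names(records))) {
    x <- records$x
    xt <- records$xt
    if (any(xt < 0) || any(x < xt)) stop("require 0 <= xt <= x")
    x[x <= xt] <- xt[x <= xt] + HALF_DAY_YR
    n <- length(x)
    list(id = if (!is.null(records$id)) records$id else as.character(seq_len(n)),
         entry_t = xt, depart_t = x, birth = rep(0, n),
         bmin = rep(0, n), bmax = rep(0, n), known = rep(TRUE, n),
         death = as.logical(records$death),
         sex = if (!is.null(records$sex)) records$sex else rep("F", n),
         provenance = if (!is.null(records$provenance)) records$provenance
                      else rep("captive_born", n),
         origin = as.Date("1970-01-01"))
  } else {
    census_times(records)
  }
}

#' Fit a Siler model to census records by Metropolis-Hastings MCMC
#'
#' Samples the joint posterior of the five Siler parameters, optional
#' proportional-hazard provenance coefficients, and a latent birth time for
#' every record whose birth is known only to an interval. Records enter the
#' likelihood through the left-truncated, right-censored form
#' (see [record_loglik()]); latent births are updated by an independence
#' proposal uniform on their interval, shifting both the entry and exit ages
#' of the record.
#'
#' @param records A census data frame (see [read_census()]) or an age-schema
#'   data frame with columns `x`, `xt`, `death` (and optionally
#'   `provenance`, `id`).
#' @param config An [mcmc_config()].
#' @param prior A [prior_spec()].
#' @param proportional_hazards If `TRUE`, include provenance as a
#'   proportional hazard with `captive_born` (or the first factor level) as
#'   reference.
#' @param init Optional named vector of starting values (a0, a1, c, b0, b1);
#'   by default a crude data-driven start jittered per chain.
#' @return A `posterior_chains` object: per-chain matrices of retained
#'   draws, latent-birth draws, acceptance rates and metadata.
#' @export
run_mcmc <- function(records, config = mcmc_config(), prior = prior_spec(),
                     proportional_hazards = FALSE, init = NULL) {
  dat <- mcmc_data(records)
  n <- length(dat$depart_t)
  if (n < 100)
    warning("fewer than 100 individuals (n = ", n, "); mortality estimates ",
            "may be biased")
  lev <- "captive_born"
  level <- rep(0L, n)
  if (proportional_hazards) {
    z <- factor(dat$provenance)
    if ("captive_born" %in% levels(z))
      z <- stats::relevel(z, ref = "captive_born")
    lev <- levels(z)
    level <- as.integer(z) - 1L
  }
  n_levels <- length(lev)
  n_gamma <- n_levels - 1L
  par_names <- c("a0", "a1", "c", "b0", "b1",
                 if (n_gamma > 0) paste0("gamma_", lev[-1]))

  unknown_idx <- which(!dat$known) - 1L  # 0-based for C++
  x_mean <- mean(dat$depart_t - dat$birth)
  hbar <- 1 / max(x_mean, 0.5)
  crude_z <- c(log(hbar) + 1, 0, log(hbar / 2), log(hbar) - 1, log(0.1))
  # Locate the posterior mode on the unconstrained scale
  # z = (a0, log a1, log c, b0, log b1), with births held at their interval
  # midpoints, then take the local curvature: chains start near the bulk,
  # per-coordinate proposal scales start at the conditional SDs, and the
  # Cholesky factor of the inverse Hessian drives the joint ridge proposal.
  # Burn-in adaptation refines all scales.
  x0 <- dat$depart_t - dat$birth
  xt0 <- pmax(dat$entry_t - dat$birth, 0)
  dth <- as.integer(dat$death)
  ones <- rep(1, n)
  nlp <- function(z) {
    th <- c(z[1], exp(z[2]), exp(z[3]), z[4], exp(z[5]))
    ll <- cpp_cohort_loglik(th, x0, xt0, dth, ones)
    lp <- stats::dnorm(z[1], prior$mean[["a0"]], prior$sd[["a0"]],
                       log = TRUE) +
      stats::dnorm(z[4], prior$mean[["b0"]], prior$sd[["b0"]], log = TRUE) -
      0.5 * (th[2] / prior$sd[["a1"]])^2 + z[2] -
      0.5 * (th[3] / prior$sd[["c"]])^2 + z[3] -
      0.5 * (th[5] / prior$sd[["b1"]])^2 + z[5]
    if (!is.finite(ll)) 1e10 else -(ll + lp)
  }
  z_mode <- crude_z
  mode_fit <- try(stats::optim(crude_z, nlp, method = "Nelder-Mead",
                               control = list(maxit = 1200,
                                              reltol = 1e-10)),
                  silent = TRUE)
  if (!inherits(mode_fit, "try-error") && mode_fit$value < 1e9)
    z_mode <- mode_fit$par
  hess <- try(fd_hessian(nlp, z_mode), silent = TRUE)
  Sig <- NULL
  if (!inherits(hess, "try-error")) {
    Sig <- try(solve(hess), silent = TRUE)
    if (inherits(Sig, "try-error") || any(diag(Sig) <= 0) ||
        any(!is.finite(Sig))) Sig <- NULL
  }
  if (!is.null(Sig)) {
    auto_sd <- pmin(pmax(sqrt(1 / pmax(diag(hess), 1e-8)), 1e-4), 2)
    L <- try(t(chol(Sig)), silent = TRUE)
    if (inherits(L, "try-error")) {
      L <- diag(auto_sd)
    }
  } else {
    auto_sd <- rep(0.1, 5)
    L <- diag(auto_sd)
  }
  use_joint <- TRUE
  joint_L <- L * (2.38 / sqrt(5))
  if (!is.null(init)) {
    init <- as_siler_params(init)
    z_mode <- c(init[["a0"]], log(init[["a1"]]),
                log(max(init[["c"]], 1e-8)), init[["b0"]],
                log(init[["b1"]]))
  }
  prop_sd <- if (is.null(config$proposal_sd)) auto_sd
             else as.numeric(config$proposal_sd[c("a0", "a1", "c", "b0",
                                                  "b1")])
  prop_sd <- c(prop_sd, rep(0.1, n_gamma))
  prior_mean <- c(prior$mean[["a0"]], 0, 0, prior$mean[["b0"]], 0)
  prior_sd <- prior$sd[c("a0", "a1", "c", "b0", "b1")]

  chains <- vector("list", config$n_chains)
  birth_chains <- vector("list", config$n_chains)
  acc <- matrix(NA_real_, config$n_chains, 5 + n_gamma,
                dimnames = list(NULL, par_names))
  for (k in seq_len(config$n_chains)) {
    set.seed(config$seed + k - 1)
    # overdispersed starts: jitter along the posterior's own geometry,
    # shrinking the jitter if it lands outside the likelihood's support
    fac <- 2
    repeat {
      z0 <- z_mode + fac * as.numeric(L %*% stats::rnorm(5))
      if (nlp(z0) < 1e9 || fac < 1e-3) break
      fac <- fac / 2
    }
    res <- cpp_siler_mh(dat$entry_t, dat$depart_t, dat$birth,
                        as.integer(dat$death), level, n_levels,
                        as.integer(unknown_idx), dat$bmin, dat$bmax,
                        as.numeric(z0), rep(0, max(n_gamma, 0)),
                        as.numeric(prior_mean), as.numeric(prior_sd),
                        prior$gamma_sd, config$n_iter, config$burn_in,
                        config$thinning, as.numeric(prop_sd), joint_L,
                        use_joint, config$adapt_interval,
                        config$target_acceptance)
    colnames(res$draws) <- par_names
    chains[[k]] <- res$draws
    birth_chains[[k]] <- res$birth_draws
    acc[k, ] <- res$acceptance
  }
  structure(list(chains = chains, birth_chains = birth_chains,
                 acceptance = acc, par_names = par_names,
                 unknown_ids = dat$id[!dat$known],
                 origin = dat$origin, n_records = n,
                 levels = lev, config = config, prior = prior),
            class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat("Siler posterior chains:", length(x$chains), "chains x",
      nrow(x$chains[[1]]), "retained draws;", x$n_records, "records\n")
  cat("parameters:", paste(x$par_names, collapse = ", "), "\n")
  if (length(x$unknown_ids) > 0)
    cat(length(x$unknown_ids), "latent birth times\n")
  rh <- try(psrf_all(x), silent = TRUE)
  if (!inherits(rh, "try-error")) {
    cat("psrf (Gelman-Rubin R-hat):\n")
    print(round(rh, 4))
  }
  cat("posterior means:\n")
  print(round(colMeans(as.matrix(x)), 4))
  invisible(x)
}

#' Pool retained draws across chains
#'
#' @param x A `posterior_chains` object.
#' @param ... Unused.
#' @return Matrix with one row per retained draw (all chains stacked).
#' @export
as.matrix.posterior_chains <- function(x, ...) {
  do.call(rbind, x$chains)
}

#' Posterior mean birth dates for uncertain-birth individuals
#'
#' @param chains A `posterior_chains` object.
#' @return Data frame `id`, `mean_birth_date` (Date), `mean_birth_t`
#'   (years since the internal origin).
#' @export
posterior_mean_births <- function(chains) {
  if (length(chains$unknown_ids) == 0)
    return(data.frame(id = character(0), mean_birth_date = as.Date(character(0)),
                      mean_birth_t = numeric(0)))
  bm <- colMeans(do.call(rbind, chains$birth_chains))
  data.frame(id = chains$unknown_ids,
             mean_birth_date = chains$origin + round(bm * DAYS_PER_YEAR),
             mean_birth_t = bm)
}

#' Potential scale reduction factor (Gelman-Rubin R-hat)
#'
#' Plain (non-rank) form: with m chains of length n, within-chain variance
#' W and between-chain variance B, \eqn{\hat R = \sqrt{((n-1)/n\,W + B/n)/W}}.
#'
#' @param draws A list of equal-length numeric vectors (one per chain) or a
#'   matrix with one column per chain.
#' @return Scalar R-hat, approximately 1 at convergence.
#' @export
psrf <- function(draws) {
  if (is.matrix(draws)) draws <- lapply(seq_len(ncol(draws)), function(j) draws[, j])
  m <- length(draws)
  if (m < 2) stop("psrf requires at least 2 chains")
  n <- unique(lengths(draws))
  if (length(n) != 1) stop("chains must have equal lengths")
  if (n < 10) stop("chains too short for psrf")
  means <- vapply(draws, mean, numeric(1))
  W <- mean(vapply(draws, stats::var, numeric(1)))
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @rdname psrf
#' @param chains A `posterior_chains` object; returns R-hat per parameter.
#' @export
psrf_all <- function(chains) {
  vapply(seq_along(chains$par_names), function(j)
    psrf(lapply(chains$chains, function(ch) ch[, j])), numeric(1)) |>
    stats::setNames(chains$par_names)
}

#' Posterior draws of demographic functionals
#'
#' Maps every retained parameter draw through the demographic functionals:
#' remaining life expectancy `ex` and lifespan equality `epsx` at each
#' requested age, and first-year mortality `q1`. Draws for which a
#' functional fails to evaluate (e.g. survival underflow) are dropped and
#' counted.
#'
#' @param chains A `posterior_chains` object.
#' @param ages Ages (years) at which to evaluate `ex` and `epsx`.
#' @param rhat_threshold Warn if any parameter R-hat exceeds this.
#' @return A list with `draws` (data frame of functional draws), `summary`
#'   (median and equal-tailed 95% credible interval per functional) and
#'   `n_failed`.
#' @export
posterior_functionals <- function(chains, ages = c(0, 1),
                                  rhat_threshold = 1.05) {
  rh <- try(psrf_all(chains), silent = TRUE)
  if (!inherits(rh, "try-error") && any(rh > rhat_threshold))
    warning("chains may not have converged: max R-hat = ",
            round(max(rh), 3))
  draws <- as.matrix(chains)
  out <- list()
  failed <- 0L
  per_draw <- function(f) {
    apply(draws, 1, function(d) {
      p <- try(as_siler_params(d[1:5]), silent = TRUE)
      if (inherits(p, "try-error")) return(NA_real_)
      v <- try(f(p), silent = TRUE)
      if (inherits(v, "try-error")) NA_real_ else v
    })
  }
  for (a in ages) {
    out[[paste0("e", a)]] <- per_draw(function(p) life_expectancy(p, a))
    out[[paste0("eps", a)]] <- per_draw(function(p) lifespan_equality(p, a))
  }
  out[["q1"]] <- per_draw(first_year_mortality)
  df <- as.data.frame(out)
  failed <- sum(!stats::complete.cases(df))
  dfc <- df[stats::complete.cases(df), , drop = FALSE]
  summ <- do.call(rbind, lapply(names(dfc), function(nm) {
    q <- stats::quantile(dfc[[nm]], c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(functional = nm, lower = q[1], median = q[2], upper = q[3])
  }))
  list(draws = dfc, summary = summ, n_failed = failed)
}

#' Export pooled posterior draws to CSV
#'
#' One row per retained draw, one column per parameter, plus a `chain`
#' index column.
#'
#' @param chains A `posterior_chains` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chains <- function(chains, path) {
  dfs <- lapply(seq_along(chains$chains), function(k)
    data.frame(chain = k, chains$chains[[k]], check.names = FALSE))
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}
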