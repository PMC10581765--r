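#' Stage-structured survival data for a wild population
#'
#' Published wild-population survival typically comes as stage-specific
#' survival probabilities over age intervals, often with an age at maturity.
#'
#' @param stages Data frame with columns `start_age`, `end_age` (integer
#'   years, interval \[start, end)) and `survival` in (0, 1\].
#' @param maturity_age Optional age at maturity (years), used as a penalty
#'   target for the age at minimum hazard.
#' @param label Optional source label.
#' @return An object of class `stage_survival_data`.
#' @export
stage_survival_data <- function(stages, maturity_age = NULL, label = NULL) {
  need <- c("start_age", "end_age", "survival")
  if (!all(need %in% names(stages)))
    stop("stages must have columns ", paste(need, collapse = ", "))
  stages <- stages[order(stages$start_age), , drop = FALSE]
  if (any(stages$end_age <= stages$start_age))
    stop("each stage must have end_age > start_age")
  if (nrow(stages) > 1 &&
      any(stages$start_age[-1] < stages$end_age[-nrow(stages)]))
    stop("stages must be non-overlapping and ordered")
  if (any(stages$survival <= 0 | stages$survival > 1))
    stop("stage survival must be in (0, 1]")
  structure(list(stages = stages, maturity_age = maturity_age,
                 label = label),
            class = "stage_survival_data")
}

#' Stage-specific survival implied by a Siler model
#'
#' The weighted average of one-year age-specific survival probabilities
#' \eqn{p_i = l_i / l_{i-1}} over the stage, weighted by the cumulative
#' survival \eqn{l_i = S(i)}:
#' \deqn{p_{x,x+n} = \sum_i p_i l_i \,/\, \sum_i l_i,}
#' with the index running over the one-year classes of the stage
#' (i = start .. end - 1 for a stage \[start, end); the i = 0 term, whose
#' \eqn{p_0} is undefined, starts at 1).
#'
#' @inheritParams siler_hazard
#' @param start_age,end_age Integer stage bounds, interval \[start, end).
#' @return Stage survival probability in (0, 1\].
#' @export
stage_survival_from_siler <- function(p, start_age, end_age) {
  p <- as_siler_params(p)
  if (end_age <= start_age) stop("end_age must be > start_age")
  lo <- max(start_age, 1)
  i <- seq(lo, max(end_age - 1, lo))
  li <- siler_survival(p, i)
  lim1 <- siler_survival(p, i - 1)
  if (sum(li) < 1e-300 || any(lim1 == 0))
    stop("cumulative survival underflows in stage [", start_age, ", ",
         end_age, "); stage beyond support")
  sum((li / lim1) * li) / sum(li)
}

# Shared multi-start bounded optimizer over eta = (a0, log a1, log c, b0,
# log b1). Starts are fixed (no RNG): a default mammalian-shaped start plus
# deterministic perturbations.
fit_siler_ls <- function(objective, n_starts = 5) {
  base <- c(-0.5, 0, log(0.05), -5, log(0.15))
  offsets <- list(c(0, 0, 0, 0, 0),
                  c(1, 0.5, -1, 1, 0.5),
                  c(-1, -0.5, 1, -2, -0.5),
                  c(2, 1, -2, 2, 1),
                  c(-2, 0.8, 0.5, -4, -1))
  obj_eta <- function(eta) {
    p <- try(siler_params(eta[1], exp(eta[2]), exp(eta[3]), eta[4],
                          exp(eta[5])), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    v <- try(objective(p), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (k in seq_len(min(n_starts, length(offsets)))) {
    eta0 <- base + offsets[[k]]
    fit <- stats::optim(eta0, obj_eta, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    fit <- stats::optim(fit$par, obj_eta, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    fit2 <- try(stats::optim(fit$par, obj_eta, method = "BFGS",
                             control = list(maxit = 500,
                                            reltol = 1e-15)),
                silent = TRUE)
    if (!inherits(fit2, "try-error") && fit2$value <= fit$value) fit <- fit2
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$value >= 1e10)
    stop("least-squares optimizer failed to find any valid Siler fit")
  p <- siler_params(best$par[1], exp(best$par[2]), exp(best$par[3]),
                    best$par[4], exp(best$par[5]))
  attr(p, "objective") <- best$value
  attr(p, "convergence") <- best$convergence
  p
}

#' Fit a Siler model to stage-specific survival data
#'
#' Least squares on the stage-specific survival probabilities implied by the
#' Siler model (see [stage_survival_from_siler()]), plus a penalty
#' `weight_maturity` times the squared difference (in years) between the
#' observed age at maturity and the fitted age at minimum hazard. Five
#' deterministic multi-starts over (a0, log a1, log c, b0, log b1) guard
#' against local minima.
#'
#' @param data A [stage_survival_data()] object.
#' @param weight_maturity Weight of the maturity penalty (squared-years
#'   scale); ignored when the data carry no maturity age.
#' @return Fitted `siler_params` with attributes `residuals` (observed minus
#'   fitted stage survival), `objective` and `convergence`.
#' @export
fit_stage_data <- function(data, weight_maturity = 1) {
  if (!inherits(data, "stage_survival_data"))
    data <- stage_survival_data(data)
  st <- data$stages
  if (nrow(st) < 3 && is.null(data$maturity_age))
    warning("fewer than 3 stages and no maturity age: the five-parameter ",
            "Siler fit is under-determined")
  objective <- function(p) {
    pred <- vapply(seq_len(nrow(st)), function(i)
      stage_survival_from_siler(p, st$start_age[i], st$end_age[i]),
      numeric(1))
    val <- sum((pred - st$survival)^2)
    if (!is.null(data$maturity_age))
      val <- val + weight_maturity *
        (age_at_min_hazard(p) - data$maturity_age)^2
    val
  }
  fit <- fit_siler_ls(objective)
  pred <- vapply(seq_len(nrow(st)), function(i)
    stage_survival_from_siler(fit, st$start_age[i], st$end_age[i]),
    numeric(1))
  attr(fit, "residuals") <- st$survival - pred
  fit
}

#' Fit a Siler model to cumulative-survival points
#'
#' Plain least squares of the Siler survival function against digitized or
#' tabulated cumulative-survival points (age, lx).
#'
#' @param points Data frame with columns `age` and `lx` (non-increasing
#'   cumulative survival, at least 5 points).
#' @return Fitted `siler_params` with attributes `residuals`, `objective`
#'   and `convergence`.
#' @export
fit_cumulative_survival <- function(points) {
  if (!all(c("age", "lx") %in% names(points)))
    stop("points must have columns age and lx")
  points <- points[order(points$age), , drop = FALSE]
  if (nrow(points) < 5) stop("need at least 5 cumulative-survival points")
  dup <- duplicated(points$age)
  if (any(dup)) {
    for (a in unique(points$age[dup]))
      if (length(unique(points$lx[points$age == a])) > 1)
        stop("duplicated age ", a, " with inconsistent survival values")
    points <- points[!dup, , drop = FALSE]
  }
  if (any(diff(points$lx) > 1e-9))
    stop("cumulative survival must be non-increasing in age")
  objective <- function(p)
    sum((siler_survival(p, points$age) - points$lx)^2)
  fit <- fit_siler_ls(objective)
  attr(fit, "residuals") <- points$lx - siler_survival(fit, points$age)
  fit
}

#' Cross-check a Siler fit against a raw life table
#'
#' Compares continuous life expectancies from the fitted model (ages 0 and
#' 1) with the discrete approximation computed from the raw life-table
#' survival, reporting both and their differences. Large differences signal
#' an implausible fit; nothing is silently passed.
#'
#' @param p Fitted Siler parameters.
#' @param lt A `life_table` (or data frame with `age`, `lx`).
#' @return Data frame with columns `age`, `e_continuous`, `e_discrete`,
#'   `difference`.
#' @export
verify_against_lifetable <- function(p, lt) {
  p <- as_siler_params(p)
  ages <- intersect(c(0, 1), lt$age[lt$lx > 0])
  if (length(ages) == 0)
    stop("life table has no usable overlap with ages 0-1")
  do.call(rbind, lapply(ages, function(a) {
    ec <- life_expectancy(p, a)
    ed <- discrete_life_expectancy(lt, a)
    data.frame(age = a, e_continuous = ec, e_discrete = ed,
               difference = ed - ec)
  }))
}

#' Read wild-population survival inputs from CSV
#'
#' `read_stage_csv()` expects columns `start_age`, `end_age`, `survival`
#' and optionally a `maturity_age` column (constant, first value used).
#' `read_cumulative_csv()` expects columns `age`, `lx`.
#'
#' @param path CSV path.
#' @return A [stage_survival_data()] object, or a data frame of
#'   cumulative-survival points.
#' @export
read_stage_csv <- function(path) {
  df <- utils::read.csv(path)
  mat <- if ("maturity_age" %in% names(df)) df$maturity_age[1] else NULL
  stage_survival_data(df[, c("start_age", "end_age", "survival")],
                      maturity_age = mat, label = basename(path))
}

#' @rdname read_stage_csv
#' @export
read_cumulative_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "lx") %in% names(df)))
    stop("cumulative survival CSV must have columns age, lx")
  df[, c("age", "lx")]
}
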