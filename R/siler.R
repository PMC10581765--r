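#' Construct a set of Siler mortality parameters
#'
#' The Siler model describes a "bathtub"-shaped hazard over age \eqn{x}
#' (in years),
#' \deqn{\mu(x) = \exp(a_0 - a_1 x) + c + \exp(b_0 + b_1 x),}
#' combining a declining juvenile hazard (\eqn{a_0}, \eqn{a_1}), a constant
#' age-independent hazard (\eqn{c}) and an exponentially increasing
#' Gompertz senescent hazard (\eqn{b_0}, \eqn{b_1}).
#'
#' @param a0 Real; log initial level of the juvenile hazard (yr\eqn{^{-1}}).
#' @param a1 Positive real; rate of decline of the juvenile hazard.
#' @param c Non-negative real; age-independent hazard. Zero is admitted as a
#'   degenerate boundary.
#' @param b0 Real; log level of the senescent hazard at age 0.
#' @param b1 Positive real; Gompertz rate of increase of the senescent hazard.
#'
#' @return An object of class `siler_params` (a named numeric vector).
#' @examples
#' p <- siler_params(a0 = 0, a1 = 1, c = 0.1, b0 = -2, b1 = 0.2)
#' siler_hazard(p, 0:5)
#' @export
siler_params <- function(a0, a1, c, b0, b1) {
  v <- c(a0 = a0, a1 = a1, c = c, b0 = b0, b1 = b1)
  validate_siler_params(v)
  structure(v, class = "siler_params")
}

validate_siler_params <- function(v) {
  if (length(v) != 5L || !is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    stop("siler_params requires five finite numeric values (a0, a1, c, b0, b1)")
  if (v[["a1"]] <= 0) stop("a1 must be > 0")
  if (v[["b1"]] <= 0) stop("b1 must be > 0")
  if (v[["c"]] < 0) stop("c must be >= 0")
  invisible(v)
}

#' Coerce to Siler parameters
#'
#' Accepts a `siler_params` object, a named or unnamed numeric vector of
#' length 5 (order a0, a1, c, b0, b1), or a named list.
#'
#' @param x Object to coerce.
#' @return A `siler_params` object.
#' @export
as_siler_params <- function(x) {
  if (inherits(x, "siler_params")) return(x)
  if (is.list(x)) x <- unlist(x)
  if (is.numeric(x) && length(x) == 5L) {
    if (is.null(names(x))) names(x) <- c("a0", "a1", "c", "b0", "b1")
    return(siler_params(x[["a0"]], x[["a1"]], x[["c"]], x[["b0"]], x[["b1"]]))
  }
  stop("cannot coerce to siler_params")
}

#' @export
print.siler_params <- function(x, ...) {
  cat("Siler mortality parameters:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Serialize Siler parameters to/from JSON
#'
#' @param p A `siler_params` object.
#' @return `siler_params_to_json()` returns a JSON string
#'   `{"a0": ..., "a1": ..., "c": ..., "b0": ..., "b1": ...}`;
#'   `siler_params_from_json()` parses one back.
#' @export
siler_params_to_json <- function(p) {
  p <- as_siler_params(p)
  jsonlite::toJSON(as.list(unclass(p)), auto_unbox = TRUE, digits = NA)
}

#' @rdname siler_params_to_json
#' @param json A JSON string or path to a JSON file.
#' @export
siler_params_from_json <- function(json) {
  as_siler_params(jsonlite::fromJSON(json))
}

check_age <- function(x) {
  if (!is.numeric(x) || anyNA(x)) stop("age must be numeric and non-missing")
  if (any(x < 0)) stop("age must be non-negative")
  invisible(x)
}

#' Siler hazard, cumulative hazard, survival and death density
#'
#' Closed-form quantities of the Siler model: the hazard
#' \eqn{\mu(x)}, the cumulative hazard
#' \eqn{U(x) = \int_0^x \mu(t)\,dt} evaluated analytically as
#' \eqn{(e^{a_0}/a_1)(1 - e^{-a_1 x}) + c x + (e^{b_0}/b_1)(e^{b_1 x} - 1)},
#' the survival function \eqn{S(x) = e^{-U(x)}} and the probability density
#' of ages at death \eqn{f(x) = \mu(x) S(x)}.
#'
#' @param p Siler parameters (anything accepted by [as_siler_params()]).
#' @param x Vector of non-negative ages in years.
#' @return Numeric vector of the same length as `x`.
#' @export
siler_hazard <- function(p, x) {
  p <- as_siler_params(p)
  check_age(x)
  exp(p[["a0"]] - p[["a1"]] * x) + p[["c"]] + exp(p[["b0"]] + p[["b1"]] * x)
}

#' @rdname siler_hazard
#' @export
siler_cumulative_hazard <- function(p, x) {
  p <- as_siler_params(p)
  check_age(x)
  exp(p[["a0"]]) / p[["a1"]] * (1 - exp(-p[["a1"]] * x)) +
    p[["c"]] * x +
    exp(p[["b0"]]) / p[["b1"]] * (exp(p[["b1"]] * x) - 1)
}

#' @rdname siler_hazard
#' @export
siler_survival <- function(p, x) {
  exp(-siler_cumulative_hazard(p, x))
}

#' @rdname siler_hazard
#' @export
siler_density <- function(p, x) {
  siler_hazard(p, x) * siler_survival(p, x)
}

#' First-year mortality probability
#'
#' The probability of dying before age 1, \eqn{q_1 = 1 - S(1)}.
#'
#' @inheritParams siler_hazard
#' @return A probability in (0, 1).
#' @export
first_year_mortality <- function(p) {
  1 - siler_survival(p, 1)
}

#' Age at which the Siler hazard is minimal
#'
#' Closed form \eqn{x^* = (a_0 - b_0 + \ln(a_1/b_1)) / (a_1 + b_1)}, clipped
#' at zero. Used as a proxy for the age at maturity when reconstructing wild
#' mortality schedules.
#'
#' @inheritParams siler_hazard
#' @return Non-negative age in years.
#' @export
age_at_min_hazard <- function(p) {
  p <- as_siler_params(p)
  xstar <- (p[["a0"]] - p[["b0"]] + log(p[["a1"]] / p[["b1"]])) /
    (p[["a1"]] + p[["b1"]])
  max(0, xstar)
}

# Smallest age (by doubling search) at which survival drops below `floor`.
# Siler survival has no finite support, so integrals are truncated here.
upper_age <- function(p, floor = 1e-12) {
  p <- as_siler_params(p)
  x <- 1
  for (i in 1:60) {
    if (siler_survival(p, x) < floor) return(x)
    x <- x * 2
  }
  stop("survival does not reach ", floor,
       " below age 2^60; parameters are pathological")
}

#' Sample ages at death from a Siler model
#'
#' Draws i.i.d. ages at death by inverting the survival function: for
#' \eqn{u \sim U(0,1)} the draw solves \eqn{U(x) = -\log u}. The monotone
#' cumulative hazard is inverted on a bracketing grid and polished with a few
#' Newton steps, giving draws accurate to well below any tolerance used in
#' the tests.
#'
#' @inheritParams siler_hazard
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG state is used.
#' @return Numeric vector of `n` non-negative ages.
#' @export
sample_ages_at_death <- function(p, n, seed = NULL) {
  p <- as_siler_params(p)
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  target <- -log(u)
  xmax <- upper_age(p, floor = 1e-14)
  grid <- seq(0, xmax, length.out = 4096L)
  Ug <- siler_cumulative_hazard(p, grid)
  if (any(diff(Ug) < 0)) stop("cumulative hazard failed to bracket draws")
  # initial inverse by interpolation, then Newton on U(x) = target
  x <- stats::approx(Ug, grid, xout = pmin(target, max(Ug)), rule = 2)$y
  for (i in 1:4) {
    x <- x - (siler_cumulative_hazard(p, x) - target) / siler_hazard(p, x)
    x <- pmin(pmax(x, 0), xmax)
  }
  resid <- siler_cumulative_hazard(p, x) - target
  if (max(abs(resid)) > 1e-6)
    stop("root-finding failed to invert the cumulative hazard; ",
         "parameters may be pathological")
  x
}
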