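#' Remaining life expectancy under a Siler model
#'
#' \deqn{e_x = \int_x^\infty S(t)\,dt \,/\, S(x).}
#' The improper integral is truncated at the smallest age (found by a
#' doubling search) where \eqn{S} falls below `1e-12`, and evaluated by
#' adaptive quadrature with absolute tolerance `1e-10`.
#'
#' @inheritParams siler_hazard
#' @param x Age (years) from which remaining life expectancy is computed.
#' @return Expected remaining years of life, a positive scalar.
#' @export
life_expectancy <- function(p, x = 0) {
  p <- as_siler_params(p)
  check_age(x)
  Sx <- siler_survival(p, x)
  if (Sx < 1e-12)
    stop("survival at age ", x, " is numerically zero; age beyond support")
  xmax <- max(upper_age(p), x + 1)
  stats::integrate(function(t) siler_survival(p, t), lower = x, upper = xmax,
                   rel.tol = 1e-10, abs.tol = 1e-10,
                   subdivisions = 500L)$value / Sx
}

#' Lifespan inequality and lifespan equality
#'
#' Lifespan inequality from age \eqn{x} is the survival-weighted average
#' accumulation of mortality after \eqn{x},
#' \deqn{H_x = \frac{\int_x^\infty S(t)/S(x)\,[U(t) - U(x)]\,dt}{e_x},}
#' which equals exactly 1 for a constant hazard, is large when deaths are
#' spread out and small when they concentrate at old ages. Lifespan equality
#' is \eqn{\varepsilon_x = -\ln H_x}.
#'
#' @inheritParams life_expectancy
#' @return `lifespan_inequality()` a positive scalar; `lifespan_equality()`
#'   a real scalar (0 for a constant hazard, positive when deaths concentrate
#'   at older ages).
#' @export
lifespan_inequality <- function(p, x = 0) {
  p <- as_siler_params(p)
  check_age(x)
  Sx <- siler_survival(p, x)
  if (Sx < 1e-12)
    stop("survival at age ", x, " is numerically zero; age beyond support")
  ex <- life_expectancy(p, x)
  Ux <- siler_cumulative_hazard(p, x)
  xmax <- max(upper_age(p), x + 1)
  num <- stats::integrate(
    function(t) siler_survival(p, t) / Sx *
      (siler_cumulative_hazard(p, t) - Ux),
    lower = x, upper = xmax, rel.tol = 1e-10, abs.tol = 1e-10,
    subdivisions = 500L)$value
  num / ex
}

#' @rdname lifespan_inequality
#' @export
lifespan_equality <- function(p, x = 0) {
  H <- lifespan_inequality(p, x)
  if (H <= 0) stop("lifespan inequality must be positive")
  -log(H)
}

#' Build a discrete life table by the product-limit estimator
#'
#' Kaplan-Meier survival evaluated on an integer-age grid (1-year age
#' classes, left-closed right-open). Censored records leave the risk set at
#' their censoring age; at tied ages deaths are processed before censorings
#' (the standard convention). Backed by [survival::survfit()].
#'
#' @param ages Non-negative event ages (years; death or censoring).
#' @param death Logical vector, `TRUE` for a death, `FALSE` for censoring.
#' @param max_age Optional upper age for the table; defaults to the largest
#'   observed event age (rounded up).
#' @return A `life_table` data frame with columns `age`, `nx` (number at
#'   risk at age x), `dx` (deaths in \[x, x+1)), `lx` (cumulative survival,
#'   `l0 = 1` unless deaths occur at exactly age 0), `qx` (1-year death
#'   probability).
#' @export
build_life_table <- function(ages, death, max_age = NULL) {
  if (length(ages) == 0) stop("empty input")
  check_age(ages)
  death <- as.logical(death)
  if (length(death) != length(ages)) stop("ages and death lengths differ")
  if (!any(death)) stop("life table requires at least one death")
  fit <- survival::survfit(survival::Surv(ages, death) ~ 1)
  if (is.null(max_age)) max_age <- ceiling(max(ages))
  grid <- 0:max_age
  sm <- summary(fit, times = grid, extend = TRUE)
  lx <- sm$surv
  nx <- vapply(grid, function(a) sum(ages >= a), integer(1))
  dx <- vapply(grid, function(a) sum(death & ages >= a & ages < a + 1),
               integer(1))
  qx <- ifelse(lx > 0, 1 - c(lx[-1], 0) / lx, NA_real_)
  qx <- pmin(pmax(qx, 0), 1)
  structure(data.frame(age = grid, nx = nx, dx = dx, lx = lx, qx = qx),
            class = c("life_table", "data.frame"))
}

#' Discrete life expectancy from a life table
#'
#' The raw life-table approximation
#' \deqn{e_x \approx \sum_{i=x}^{\omega} l_i / l_x,}
#' where \eqn{\omega} is the maximum age in the table. This left-Riemann
#' approximation of the continuous integral carries an upward bias of up to
#' one year (about half a year for smooth death-age distributions).
#'
#' @param lt A `life_table` from [build_life_table()] (or any data frame
#'   with columns `age` and `lx`).
#' @param x Integer age present in the table, with `lx > 0`.
#' @return Approximate remaining life expectancy in years.
#' @export
discrete_life_expectancy <- function(lt, x = 0) {
  if (!all(c("age", "lx") %in% names(lt))) stop("not a life table")
  row <- match(x, lt$age)
  if (is.na(row)) stop("age ", x, " not present in the life table")
  lx <- lt$lx[row]
  if (lx <= 0) stop("survival at age ", x, " is zero")
  sum(lt$lx[lt$age >= x]) / lx
}

#' Read or write a life table as CSV
#'
#' @param lt A `life_table`.
#' @param path File path.
#' @return `read_life_table()` returns a `life_table`; `write_life_table()`
#'   returns `path` invisibly.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt)[, c("age", "nx", "dx", "lx", "qx")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("age", "nx", "dx", "lx", "qx")
  if (!all(need %in% names(df))) stop("life table CSV must have columns ",
                                      paste(need, collapse = ", "))
  structure(df[, need], class = c("life_table", "data.frame"))
}
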