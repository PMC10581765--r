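date_to_year <- function(d) {
  y <- as.numeric(format(d, "%Y"))
  y + as.numeric(d - as.Date(paste0(format(d, "%Y"), "-01-01"))) /
    DAYS_PER_YEAR
}

#' Prepare census data for per-stratum analysis
#'
#' Applies the data-entry rules used for zoological census records:
#' excludes records with unknown sex, removes the 1% longest-lived
#' individuals (floor(0.01 n) records after the sex exclusion, observed
#' lifespan from the known birth date or the interval midpoint, ties broken
#' by earliest departure date), and assigns every remaining individual to
#' the period stratum containing its entry date. Individuals are not split
#' across periods.
#'
#' @param records Census data frame or path (see [read_census()]).
#' @param period_breaks Increasing calendar years delimiting the periods.
#' @param window_end Final calendar year used only for period labels.
#' @param min_per_stratum Floor below which a sex-by-period stratum is
#'   flagged in the audit (default 100).
#' @return A list with `records` (retained records plus a `period` column)
#'   and `audit` (counts: `input = retained + excluded_sex +
#'   excluded_lifespan`, per-stratum sizes, warnings).
#' @export
prepare_data <- function(records, period_breaks, window_end = NULL,
                         min_per_stratum = 100) {
  if (is.character(records)) records <- read_census(records)
  records <- as_census(as.data.frame(records))
  n_input <- nrow(records)
  keep_sex <- records$sex %in% c("F", "M")
  n_sex <- sum(!keep_sex)
  d <- records[keep_sex, , drop = FALSE]

  birth_num <- ifelse(!is.na(d$birth_date), as.numeric(d$birth_date),
                      (as.numeric(d$birth_min) +
                         pmin(as.numeric(d$birth_max),
                              as.numeric(d$entry_date))) / 2)
  lifespan <- (as.numeric(d$depart_date) - birth_num) / DAYS_PER_YEAR
  n_trim <- as.integer(floor(0.01 * nrow(d)))
  if (n_trim > 0) {
    ord <- order(-lifespan, d$depart_date)
    drop_idx <- ord[seq_len(n_trim)]
    d <- d[-drop_idx, , drop = FALSE]
  }

  labels <- period_labels(period_breaks, window_end)
  entry_y <- date_to_year(d$entry_date)
  per <- findInterval(entry_y, period_breaks) + 1
  d$period <- factor(labels[per], levels = labels)

  counts <- table(sex = d$sex, period = d$period)
  warnings <- character(0)
  for (s in rownames(counts)) for (pd in colnames(counts))
    if (counts[s, pd] < min_per_stratum)
      warnings <- c(warnings, paste0("stratum ", s, "/", pd, " has only ",
                                     counts[s, pd], " individuals (< ",
                                     min_per_stratum, ")"))
  audit <- list(input = n_input, excluded_sex = as.integer(n_sex),
                excluded_lifespan = n_trim,
                retained = nrow(d), stratum_counts = counts,
                warnings = warnings)
  stopifnot(audit$input ==
              audit$retained + audit$excluded_sex + audit$excluded_lifespan)
  list(records = d, audit = audit)
}

#' Quantile of a point value on a posterior sample
#'
#' The empirical CDF of the draws evaluated at `point`: the position of a
#' wild point estimate on a zoo posterior density.
#'
#' @param draws Posterior draws (at least 200 recommended).
#' @param point Point value.
#' @return Quantile in \[0, 1\].
#' @export
quantile_of_point <- function(draws, point) {
  if (length(draws) < 200)
    warning("fewer than 200 draws; quantile estimate will be coarse")
  mean(draws <= point)
}

#' Run the full demographic analysis pipeline
#'
#' Orchestrates the end-to-end analysis of a census: data preparation
#' (see [prepare_data()]), independent per-stratum (sex by period) MCMC
#' fits, posterior functionals (life expectancy and lifespan equality at
#' the requested ages, first-year mortality), calibrated Kullback-Leibler
#' comparisons of every earlier period against the reference (latest)
#' period and of the sexes within each period, and -- when wild survival
#' inputs are supplied -- Siler reconstruction of the wild schedules with
#' the quantile placement of their point estimates on the zoo posteriors.
#'
#' @param census Census data frame or CSV path.
#' @param period_breaks Increasing calendar years delimiting periods.
#' @param config An [mcmc_config()]; stratum `k` derives its chain seeds
#'   from `config$seed + 1000 k`, making the whole run reproducible.
#' @param maturity_age Optional age at maturity; adds `e`/`eps` at that age.
#' @param wild Optional named list of wild inputs, each either a
#'   [stage_survival_data()] or a data frame of cumulative-survival points
#'   (`age`, `lx`).
#' @param reference_period Period label used as KL reference; default the
#'   latest period.
#' @param window_end Final calendar year (labels only).
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `stratum_summary.csv`, `kl_periods.csv`, `kl_sexes.csv` and
#'   `wild_placement.csv`.
#' @param rhat_threshold Convergence flag threshold for max R-hat.
#' @return An `analysis_report` list.
#' @export
run_full_analysis <- function(census, period_breaks, config = mcmc_config(),
                              maturity_age = NULL, wild = NULL,
                              reference_period = NULL, window_end = NULL,
                              out_dir = NULL, rhat_threshold = 1.05) {
  prep <- prepare_data(census, period_breaks, window_end)
  d <- prep$records
  labels <- levels(d$period)
  if (is.null(reference_period)) reference_period <- labels[length(labels)]
  ages <- unique(c(0, 1, maturity_age))

  strata <- list()
  k <- 0
  for (sex in c("F", "M")) {
    for (pd in labels) {
      k <- k + 1
      sub <- d[d$sex == sex & d$period == pd, , drop = FALSE]
      key <- paste(sex, pd, sep = "/")
      if (nrow(sub) == 0) next
      cfg <- config
      cfg$seed <- config$seed + 1000 * k
      res <- tryCatch({
        ch <- suppressWarnings(run_mcmc(sub, cfg))
        rh <- psrf_all(ch)
        fn <- suppressWarnings(
          posterior_functionals(ch, ages, rhat_threshold))
        list(n = nrow(sub), rhat = rh,
             converged = max(rh) <= rhat_threshold,
             acceptance = colMeans(ch$acceptance),
             summary = fn$summary, draws = fn$draws,
             n_failed_draws = fn$n_failed, error = NULL)
      }, error = function(e)
        list(n = nrow(sub), rhat = NULL, converged = FALSE,
             summary = NULL, draws = NULL, error = conditionMessage(e)))
      strata[[key]] <- res
    }
  }

  kl_periods <- list()
  for (sex in c("F", "M")) {
    keys <- paste(sex, labels, sep = "/")
    ok <- keys[vapply(keys, function(k2)
      !is.null(strata[[k2]]) && !is.null(strata[[k2]]$draws), logical(1))]
    post <- lapply(strata[ok], function(s) s$draws)
    names(post) <- sub("^[FM]/", "", ok)
    if (length(post) >= 2 && reference_period %in% names(post)) {
      tb <- compare_groups(post, reference_period)
      tb$sex <- sex
      kl_periods[[sex]] <- tb
    }
  }
  kl_periods <- if (length(kl_periods)) do.call(rbind, kl_periods) else NULL

  kl_sexes <- list()
  for (pd in labels) {
    kf <- paste0("F/", pd); km <- paste0("M/", pd)
    if (!is.null(strata[[kf]]$draws) && !is.null(strata[[km]]$draws)) {
      tb <- compare_groups(list(F = strata[[kf]]$draws,
                                M = strata[[km]]$draws), "F")
      tb$period <- pd
      kl_sexes[[pd]] <- tb
    }
  }
  kl_sexes <- if (length(kl_sexes)) do.call(rbind, kl_sexes) else NULL

  wild_out <- NULL
  if (!is.null(wild)) {
    wild_out <- list()
    for (nm in names(wild)) {
      w <- wild[[nm]]
      fit <- if (inherits(w, "stage_survival_data")) fit_stage_data(w)
             else fit_cumulative_survival(w)
      e1 <- life_expectancy(fit, 1)
      eps1 <- lifespan_equality(fit, 1)
      for (sex in c("F", "M")) {
        key <- paste(sex, reference_period, sep = "/")
        if (is.null(strata[[key]]$draws)) next
        dr <- strata[[key]]$draws
        wild_out[[length(wild_out) + 1]] <- data.frame(
          wild_source = nm, sex = sex, reference = reference_period,
          e1_wild = e1, eps1_wild = eps1,
          e1_quantile = quantile_of_point(dr$e1, e1),
          eps1_quantile = quantile_of_point(dr$eps1, eps1))
      }
    }
    wild_out <- if (length(wild_out)) do.call(rbind, wild_out) else NULL
  }

  report <- structure(list(
    audit = prep$audit, strata = strata, kl_periods = kl_periods,
    kl_sexes = kl_sexes, wild = wild_out,
    settings = list(period_breaks = period_breaks, ages = ages,
                    reference_period = reference_period,
                    seed = config$seed)),
    class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Summarize an analysis report's strata as one data frame
#'
#' @param report An `analysis_report`.
#' @return Data frame: one row per stratum and functional with the posterior
#'   median and 95% credible interval.
#' @export
stratum_summary <- function(report) {
  rows <- list()
  for (key in names(report$strata)) {
    s <- report$strata[[key]]
    if (is.null(s$summary)) next
    parts <- strsplit(key, "/")[[1]]
    df <- s$summary
    df$sex <- parts[1]
    df$period <- parts[2]
    df$n <- s$n
    df$converged <- s$converged
    df$max_rhat <- if (!is.null(s$rhat)) max(s$rhat) else NA_real_
    rows[[key]] <- df
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Census demographic analysis report\n")
  cat("records: input", x$audit$input, "| retained", x$audit$retained,
      "| excluded (sex)", x$audit$excluded_sex,
      "| excluded (1% longest-lived)", x$audit$excluded_lifespan, "\n")
  failed <- names(Filter(function(s) !is.null(s$error), x$strata))
  if (length(failed))
    cat("strata with errors:", paste(failed, collapse = ", "), "\n")
  notconv <- names(Filter(function(s) is.null(s$error) && !s$converged,
                          x$strata))
  if (length(notconv))
    cat("strata flagged non-converged:", paste(notconv, collapse = ", "),
        "\n")
  sm <- stratum_summary(x)
  if (!is.null(sm)) {
    cat("\nposterior medians (95% CI):\n")
    print(sm[, c("sex", "period", "functional", "median", "lower",
                 "upper")], digits = 4, row.names = FALSE)
  }
  if (!is.null(x$kl_periods)) {
    cat("\ncalibrated K-L vs reference period:\n")
    print(x$kl_periods[, c("sex", "functional", "group", "reference",
                           "calibrated")], digits = 3, row.names = FALSE)
  }
  if (!is.null(x$wild)) {
    cat("\nwild point estimates on zoo posteriors:\n")
    print(x$wild, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

# Write the report as JSON plus CSV tables. Draws are omitted from the
# JSON (they are bulky and reproducible from the seed).
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sm <- stratum_summary(report)
  if (!is.null(sm))
    utils::write.csv(sm, file.path(out_dir, "stratum_summary.csv"),
                     row.names = FALSE)
  if (!is.null(report$kl_periods))
    utils::write.csv(report$kl_periods,
                     file.path(out_dir, "kl_periods.csv"), row.names = FALSE)
  if (!is.null(report$kl_sexes))
    utils::write.csv(report$kl_sexes, file.path(out_dir, "kl_sexes.csv"),
                     row.names = FALSE)
  if (!is.null(report$wild))
    utils::write.csv(report$wild,
                     file.path(out_dir, "wild_placement.csv"),
                     row.names = FALSE)
  json <- list(
    audit = list(input = report$audit$input,
                 excluded_sex = report$audit$excluded_sex,
                 excluded_lifespan = report$audit$excluded_lifespan,
                 retained = report$audit$retained,
                 warnings = report$audit$warnings),
    settings = report$settings,
    strata = lapply(report$strata, function(s)
      list(n = s$n, converged = s$converged,
           rhat = as.list(s$rhat),
           error = s$error,
           summary = s$summary)),
    kl_periods = report$kl_periods,
    kl_sexes = report$kl_sexes,
    wild = report$wild)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
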