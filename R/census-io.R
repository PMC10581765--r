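#' Read and write census CSV files
#'
#' The census schema mirrors studbook-style records from zoological
#' institutions: one row per individual with columns
#' `id, sex, provenance, birth_date, birth_min, birth_max, entry_date,
#' depart_date, depart_type` (ISO-8601 dates). An empty `birth_date` means
#' the birth is known only to the interval `[birth_min, birth_max]`.
#' `depart_type` is `"death"` or `"censored"`; `sex` is `"F"`, `"M"` or
#' `"U"` (unknown, excluded during data preparation); `provenance` is
#' `"captive_born"`, `"wild_born"` or `"not_reported"`.
#'
#' @param path CSV file path.
#' @return `read_census()` returns a validated data frame of class `census`.
#' @export
read_census <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  as_census(df)
}

#' @rdname read_census
#' @param records A census data frame.
#' @export
write_census <- function(records, path) {
  out <- as.data.frame(records)
  for (col in c("birth_date", "birth_min", "birth_max", "entry_date",
                "depart_date"))
    out[[col]] <- as.character(out[[col]])
  out$birth_date[is.na(out$birth_date)] <- ""
  out$birth_min[is.na(out$birth_min)] <- ""
  out$birth_max[is.na(out$birth_max)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_census
#' @param df A data frame in the census schema.
#' @export
as_census <- function(df) {
  need <- c("id", "sex", "provenance", "birth_date", "birth_min",
            "birth_max", "entry_date", "depart_date", "depart_type")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("census is missing columns: ", paste(miss, collapse = ", "))
  parse_d <- function(v) {
    v <- as.character(v)
    v[!nzchar(v) | is.na(v)] <- NA
    as.Date(v)
  }
  for (col in c("birth_date", "birth_min", "birth_max", "entry_date",
                "depart_date"))
    df[[col]] <- parse_d(df[[col]])
  if (anyNA(df$entry_date) || anyNA(df$depart_date))
    stop("entry_date and depart_date are required for every record")
  if (!all(df$depart_type %in% c("death", "censored")))
    stop("depart_type must be 'death' or 'censored'")
  no_birth <- is.na(df$birth_date)
  if (any(no_birth & (is.na(df$birth_min) | is.na(df$birth_max))))
    stop("records without birth_date require birth_min and birth_max")
  bmax <- as.numeric(ifelse(no_birth, df$birth_max, df$birth_date))
  bmin_n <- as.numeric(ifelse(no_birth, df$birth_min, df$birth_date))
  if (any(bmax < bmin_n)) stop("birth_max before birth_min")
  if (any(as.numeric(df$entry_date) < bmin_n))
    stop("entry_date before (earliest possible) birth date")
  if (any(df$depart_date < df$entry_date))
    stop("depart_date before entry_date")
  class(df) <- c("census", "data.frame")
  df
}

DAYS_PER_YEAR <- 365.25
HALF_DAY_YR <- 0.5 / 365

# Convert census records to the internal age/time representation used by the
# samplers: times in years since the earliest relevant date. Records with
# interval-valued births carry [bmin, bmax] (bmax clipped at entry);
# same-day entry/exit gets a half-day offset so no interval has zero length.
census_times <- function(records) {
  records <- as_census(as.data.frame(records))
  origin <- min(c(records$birth_date, records$birth_min, records$entry_date),
                na.rm = TRUE)
  yr <- function(d) as.numeric(d - origin) / DAYS_PER_YEAR
  known <- !is.na(records$birth_date)
  birth <- ifelse(known, yr(records$birth_date),
                  (yr(records$birth_min) + pmin(yr(records$birth_max),
                                                yr(records$entry_date))) / 2)
  entry <- yr(records$entry_date)
  depart <- yr(records$depart_date)
  depart[depart <= entry] <- entry[depart <= entry] + HALF_DAY_YR
  bmin <- ifelse(known, birth, yr(records$birth_min))
  bmax <- ifelse(known, birth, pmin(yr(records$birth_max), entry))
  bmin <- pmin(bmin, bmax)
  list(id = records$id, entry_t = entry, depart_t = depart, birth = birth,
       bmin = bmin, bmax = bmax, known = known,
       death = records$depart_type == "death",
       sex = records$sex, provenance = records$provenance, origin = origin)
}
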