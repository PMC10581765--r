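test_that("scenario specification validates its invariants", {
  p <- p_baseline
  expect_error(scenario_spec(list(F = p, M = p), period_breaks = c(2005, 1990)),
               "increasing")
  expect_error(scenario_spec(list(F = p, M = p), window = c(1995, 2021),
                             period_breaks = c(1990, 2005)), "span")
  expect_error(scenario_spec(list(F = p, M = p), frac_wild = 1.4),
               "fractions")
  expect_error(scenario_spec(list(F = p, M = p),
                             true_params = list(F = list(p, p), M = p),
                             period_breaks = c(1990, 2005)),
               "parameter sets")
  s <- scenario_spec(list(F = p, M = p))
  expect_length(s$true_params$F, 3)  # recycled across periods
})

test_that("uncensored untruncated death ages follow the generating model", {
  sim <- simulate_cohort(p_baseline, 2e4, censor_frac = 0, trunc_frac = 0,
                         seed = 61)
  expect_true(all(sim$records$death))
  se <- sd(sim$records$x) / sqrt(nrow(sim$records))
  expect_lt(abs(mean(sim$records$x) - life_expectancy(p_baseline, 0)),
            3 * se)
  ks <- suppressWarnings(stats::ks.test(
    sim$records$x[1:1e4],
    function(q) 1 - siler_survival(p_baseline, pmax(q, 0))))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("the a-priori censoring calibration hits its target", {
  sim <- simulate_cohort(p_baseline, 5000, censor_frac = 0.2,
                         trunc_frac = 0.15, seed = 62)
  obs <- mean(!sim$records$death)
  half <- 2.576 * sqrt(0.2 * 0.8 / 5000)  # binomial 99% bounds
  expect_lt(abs(obs - 0.2), half + 0.01)
  expect_lt(abs(mean(sim$records$xt > 0) - 0.15),
            3 * sqrt(0.15 * 0.85 / 5000))
})

test_that("generated censuses are byte-identical under a fixed seed", {
  spec <- preset_scenarios()$short_lived_high_juvenile
  spec$n_per_period <- 40  # keep the determinism check quick
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_census(generate_census(spec)$records, f1)
  write_census(generate_census(spec)$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("presets satisfy the stated modeling floor and structure", {
  presets <- preset_scenarios()
  expect_named(presets, c("short_lived_high_juvenile",
                          "long_lived_low_mortality",
                          "period_improvements", "worst_case"))
  for (nm in names(presets)) {
    s <- presets[[nm]]
    expect_s3_class(s, "scenario_spec")
    expect_gte(s$n_per_period, 100)
  }
  # four- and three-period layouts both present
  expect_length(presets$long_lived_low_mortality$period_breaks, 3)
  expect_length(presets$period_improvements$period_breaks, 2)
  # worst case: 30% interval births, heavy truncation
  expect_equal(presets$worst_case$frac_unknown_birth, 0.3)
  expect_gte(max(presets$worst_case$frac_wild), 0.6)
  # every sex/period stratum of a generated preset meets the floor of 100
  sim <- generate_census(presets$period_improvements)
  counts <- table(sim$truth$sex, sim$truth$period)
  expect_true(all(counts >= 100))
  # period improvements: true e1 strictly increases across periods
  tr <- scenario_truth(presets$period_improvements)
  for (sx in c("F", "M"))
    expect_true(all(diff(tr$e1[tr$sex == sx]) > 0))
})

test_that("generated records carry the stated truncation/censoring anatomy", {
  spec <- preset_scenarios()$worst_case
  spec$n_per_period <- 120
  sim <- generate_census(spec)
  rec <- sim$records
  expect_s3_class(rec, "census")
  # wild-born individuals are left-truncated (entry after birth)
  tms <- zoodemog:::census_times(rec)
  wild <- rec$provenance == "wild_born"
  known_wild <- wild & !is.na(rec$birth_date)
  expect_true(all((tms$entry_t - tms$birth)[known_wild] > 0.4))
  # captive-born known-birth individuals enter at birth
  cap <- rec$provenance == "captive_born" & !is.na(rec$birth_date)
  expect_true(all(abs((tms$entry_t - tms$birth)[cap]) < 0.01))
  # requested fraction of interval births
  expect_equal(mean(is.na(rec$birth_date)), 0.3, tolerance = 0.02)
  # intervals contain the true birth
  unk <- is.na(rec$birth_date)
  tr <- sim$truth[match(rec$id[unk], sim$truth$id), ]
  expect_true(all(rec$birth_min[unk] <= tr$true_birth + 1))
  expect_true(all(pmin(rec$birth_max[unk], rec$entry_date[unk]) >=
                    tr$true_birth - 1))
  # audit identity: truth rows match record rows one-to-one
  expect_setequal(rec$id, sim$truth$id)
})

test_that("census files round-trip through write/read", {
  spec <- preset_scenarios()$worst_case
  spec$n_per_period <- 25
  sim <- suppressWarnings(generate_census(spec))
  f <- tempfile(fileext = ".csv")
  write_census(sim$records, f)
  back <- read_census(f)
  expect_equal(nrow(back), nrow(sim$records))
  expect_identical(back$depart_type, sim$records$depart_type)
  expect_equal(back$entry_date, sim$records$entry_date)
  expect_equal(back$birth_min, sim$records$birth_min)
  unlink(f)
})

test_that("census validation rejects malformed schemas", {
  spec <- preset_scenarios()$short_lived_high_juvenile
  spec$n_per_period <- 20
  rec <- as.data.frame(generate_census(spec)$records)
  expect_error(as_census(rec[, -1]), "missing columns")
  bad <- rec
  bad$depart_type[1] <- "transferred"
  expect_error(as_census(bad), "depart_type")
  bad2 <- rec
  bad2$depart_date[1] <- as.Date(bad2$entry_date[1]) - 10
  expect_error(as_census(bad2), "depart_date before")
})
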