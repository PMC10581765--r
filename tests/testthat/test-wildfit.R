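# Siler params engineered so that S(1) = 0.8 and S(2) = 0.72 (juvenile term
# only: a1 = -log(U2/U1 - 1), senescent term suppressed).
p_tailored <- local({
  a1 <- -log(0.32850407 / 0.22314355 - 1)
  A <- 0.22314355 / (1 - exp(-a1))
  siler_params(log(A * a1), a1, 0, -30, 0.1)
})

test_that("stage survival is the survival-weighted mean of yearly survivals", {
  # constant hazard: every yearly survival is exp(-c)
  pc <- p_const(0.3)
  for (st in list(c(0, 1), c(1, 3), c(2, 7)))
    expect_equal(stage_survival_from_siler(pc, st[1], st[2]), exp(-0.3),
                 tolerance = 1e-6)
  # hand computation: l1 = 0.8, l2 = 0.72, stage [1,3)
  expect_equal(siler_survival(p_tailored, 1:2), c(0.8, 0.72),
               tolerance = 1e-6)
  expect_equal(stage_survival_from_siler(p_tailored, 1, 3),
               (0.8 * 0.8 + 0.9 * 0.72) / (0.8 + 0.72), tolerance = 1e-5)
  # one-year stage [x, x+1) reduces to the single ratio l_x / l_{x-1}
  for (p in random_params(10, seed = 51)) {
    for (x in c(1, 4, 9))
      expect_equal(stage_survival_from_siler(p, x, x + 1),
                   siler_survival(p, x) / siler_survival(p, x - 1),
                   tolerance = 1e-12)
  }
  # stage far beyond support errors rather than returning 0/0
  expect_error(stage_survival_from_siler(p_mixed, 500, 510), "support")
})

test_that("stage data constructor validates its invariants", {
  st <- data.frame(start_age = c(0, 1, 5), end_age = c(1, 5, 10),
                   survival = c(0.7, 0.9, 0.85))
  expect_s3_class(stage_survival_data(st, maturity_age = 4),
                  "stage_survival_data")
  bad <- st; bad$survival[2] <- 1.2
  expect_error(stage_survival_data(bad), "survival")
  overlap <- data.frame(start_age = c(0, 2), end_age = c(3, 5),
                        survival = c(0.8, 0.9))
  expect_error(stage_survival_data(overlap), "non-overlapping")
})

test_that("stage-data fit recovers the generating model", {
  p_true <- p_baseline
  stages <- data.frame(start_age = c(0, 1, 3, 6, 10),
                       end_age = c(1, 3, 6, 10, 16))
  stages$survival <- vapply(seq_len(nrow(stages)), function(i)
    stage_survival_from_siler(p_true, stages$start_age[i],
                              stages$end_age[i]), numeric(1))
  sd <- stage_survival_data(stages,
                            maturity_age = age_at_min_hazard(p_true))
  fit <- fit_stage_data(sd, weight_maturity = 1)
  # stage survivals reproduced
  pred <- vapply(seq_len(nrow(stages)), function(i)
    stage_survival_from_siler(fit, stages$start_age[i], stages$end_age[i]),
    numeric(1))
  expect_lt(max(abs(pred - stages$survival)), 1e-4)
  # derived life expectancy close to the truth
  expect_lt(abs(life_expectancy(fit, 1) - life_expectancy(p_true, 1)) /
              life_expectancy(p_true, 1), 0.02)
  # single stage, no maturity -> flagged under-determined
  one <- data.frame(start_age = 1, end_age = 5, survival = 0.9)
  expect_warning(fit_stage_data(stage_survival_data(one)),
                 "under-determined")
})

test_that("stage-data fit is stable under small observation noise", {
  p_true <- p_baseline
  stages <- data.frame(start_age = c(0, 1, 3, 6, 10),
                       end_age = c(1, 3, 6, 10, 16))
  stages$survival <- vapply(seq_len(nrow(stages)), function(i)
    stage_survival_from_siler(p_true, stages$start_age[i],
                              stages$end_age[i]), numeric(1))
  e1_clean <- life_expectancy(
    fit_stage_data(stage_survival_data(
      stages, maturity_age = age_at_min_hazard(p_true))), 1)
  set.seed(52)
  for (r in 1:3) {
    noisy <- stages
    noisy$survival <- pmin(pmax(
      noisy$survival + runif(nrow(noisy), -0.01, 0.01), 0.01), 1)
    fit_n <- fit_stage_data(stage_survival_data(
      noisy, maturity_age = age_at_min_hazard(p_true)))
    expect_lt(abs(life_expectancy(fit_n, 1) - e1_clean) / e1_clean, 0.2)
  }
})

test_that("cumulative-survival fit recovers exact and exponential inputs", {
  pts <- data.frame(age = 0:30, lx = siler_survival(p_baseline, 0:30))
  fit <- fit_cumulative_survival(pts)
  rms <- sqrt(mean((siler_survival(fit, pts$age) - pts$lx)^2))
  expect_lt(rms, 1e-6)
  # exponential points: e0 of the fit ~ 1/rate
  ptse <- data.frame(age = 0:30, lx = exp(-0.2 * (0:30)))
  fite <- fit_cumulative_survival(ptse)
  expect_equal(life_expectancy(fite, 0), 5, tolerance = 0.01)
  # validation
  expect_error(fit_cumulative_survival(pts[1:3, ]), "at least 5")
  inc <- data.frame(age = 0:5, lx = c(1, 0.9, 0.95, 0.8, 0.7, 0.6))
  expect_error(fit_cumulative_survival(inc), "non-increasing")
  dup <- data.frame(age = c(0, 1, 1, 2, 3, 4),
                    lx = c(1, 0.9, 0.85, 0.8, 0.7, 0.6))
  expect_error(fit_cumulative_survival(dup), "inconsistent")
})

test_that("life-table verification reports honest differences", {
  p <- p_baseline
  omega <- zoodemog:::upper_age(p)
  lt <- data.frame(age = 0:ceiling(omega), lx = siler_survival(p, 0:ceiling(omega)))
  rep1 <- verify_against_lifetable(p, lt)
  # report is internally consistent with the two estimators it compares
  for (i in seq_len(nrow(rep1))) {
    a <- rep1$age[i]
    expect_equal(rep1$e_continuous[i], life_expectancy(p, a))
    expect_equal(rep1$e_discrete[i], discrete_life_expectancy(lt, a))
    expect_equal(rep1$difference[i],
                 rep1$e_discrete[i] - rep1$e_continuous[i])
  }
  # the printed discrete estimator carries its known ~half-year upward bias
  expect_true(all(rep1$difference > 0.3 & rep1$difference < 0.7))
  # a grossly mismatched table yields a large reported difference
  lt_bad <- data.frame(age = 0:40, lx = exp(-0.02 * (0:40)))
  rep2 <- verify_against_lifetable(p, lt_bad)
  expect_gt(max(abs(rep2$difference)), 5)
  # no usable overlap
  expect_error(verify_against_lifetable(
    p, data.frame(age = 50:60, lx = rep(0, 11))), "overlap")
})

test_that("wild CSV readers parse stage and cumulative inputs", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(start_age = c(0, 1, 4), end_age = c(1, 4, 9),
                       survival = c(0.6, 0.85, 0.9), maturity_age = 4),
            f, row.names = FALSE)
  sd <- read_stage_csv(f)
  expect_s3_class(sd, "stage_survival_data")
  expect_equal(sd$maturity_age, 4)
  write.csv(data.frame(age = 0:10, lx = exp(-0.15 * (0:10))), f,
            row.names = FALSE)
  pts <- read_cumulative_csv(f)
  expect_equal(nrow(pts), 11)
  unlink(f)
})
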