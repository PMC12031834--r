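test_that("counting-process expansion carries covariates forward", {
  meas <- data.frame(patient_id = "A", day = c(-17, 1), value = c(0, 2))
  out <- data.frame(patient_id = "A", icans_day = 5, censor_day = 30)
  rows <- expand_counting_process(meas, out, name = "x")
  expect_equal(rows$start, c(0, 1))
  expect_equal(rows$stop, c(1, 5))
  expect_equal(rows$event, c(0L, 1L))
  expect_equal(rows$x, c(0, 2))
})

test_that("measurements on or after the onset day are excluded", {
  meas <- data.frame(patient_id = "A", day = c(-17, 1, 5, 7),
                     value = c(0, 1, 9, 9))
  out <- data.frame(patient_id = "A", icans_day = 5, censor_day = 30)
  rows <- expand_counting_process(meas, out, name = "x")
  expect_false(any(rows$x == 9))
  expect_equal(max(rows$stop), 5)
  expect_equal(sum(rows$event), 1L)
})

test_that("expansion conserves each patient's at-risk time", {
  spec <- cohort_sim_spec(n_patients = 150, seed = 21)
  co <- simulate_cohort(spec)
  rows <- expand_counting_process(cohort_measurements(co, "grade"),
                                  cohort_outcomes(co), name = "g")
  at_risk <- tapply(rows$stop - rows$start, rows$patient_id, sum)
  ends <- vapply(co, function(p)
    if (!is.na(p$icans_day)) p$icans_day else p$censor_day, numeric(1))
  names(ends) <- vapply(co, function(p) p$patient_id, character(1))
  common <- intersect(names(at_risk), names(ends))
  expect_gt(length(common), 100)
  expect_equal(as.numeric(at_risk[common]), as.numeric(ends[common]),
               tolerance = 1e-8)
})

test_that("structural violations of the long format are rejected", {
  bad <- data.frame(patient_id = "A", start = c(0, 0.5), stop = c(1, 2),
                    event = c(0, 1), x = c(1, 1))
  expect_error(validate_survival_rows(bad), "overlap")
  bad2 <- data.frame(patient_id = "A", start = 1, stop = 1, event = 1, x = 1)
  expect_error(validate_survival_rows(bad2), "start < stop")
  bad3 <- data.frame(patient_id = "A", start = c(0, 1), stop = c(1, 2),
                     event = c(1, 1), x = c(1, 2))
  expect_error(validate_survival_rows(bad3), "more than one event")
})

test_that("the Cox fit recovers a known hazard ratio", {
  spec <- cohort_sim_spec(n_patients = 1000, covariate = "binary",
                          beta = c(x = log(2)), baseline_hazard = 0.02,
                          risk_window = 30, censor_day = 30, seed = 22)
  co <- simulate_cohort(spec)
  rows <- expand_counting_process(cohort_measurements(co, "covariate"),
                                  cohort_outcomes(co), name = "x")
  res <- fit_cox(rows, "x")
  expect_gt(res$hr, 1.6)
  expect_lt(res$hr, 2.5)
  expect_lt(res$p_value, 0.01)
  expect_true(res$ci_low <= res$hr && res$hr <= res$ci_high)
})

test_that("the partial likelihood maximizer matches a brute-force oracle", {
  # tie-free continuous event times on a small cohort
  spec <- cohort_sim_spec(n_patients = 60, covariate = "binary",
                          beta = c(x = log(2)), baseline_hazard = 0.05,
                          risk_window = 30, censor_day = 30, seed = 23)
  co <- simulate_cohort(spec)
  rows <- expand_counting_process(cohort_measurements(co, "covariate"),
                                  cohort_outcomes(co), name = "x")
  fit <- attr(fit_cox(rows, "x"), "fit")
  b_oracle <- oracle_cox_coef(rows$start, rows$stop, rows$event, rows$x)
  expect_equal(unname(coef(fit)), b_oracle, tolerance = 1e-4)
})

test_that("a null covariate gives HR near 1 and uniform-ish p-values", {
  set.seed(24)
  ps <- numeric(40)
  for (r in 1:40) {
    spec <- cohort_sim_spec(n_patients = 150, covariate = "binary",
                            beta = c(x = 0), baseline_hazard = 0.03,
                            risk_window = 30, censor_day = 30, seed = 3000 + r)
    co <- simulate_cohort(spec)
    rows <- expand_counting_process(cohort_measurements(co, "covariate"),
                                    cohort_outcomes(co), name = "x")
    ps[r] <- fit_cox(rows, "x")$p_value
  }
  expect_gt(mean(ps > 0.05), 0.8)           # ~95% expected under the null
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("degenerate fits are refused with informative errors", {
  rows <- data.frame(patient_id = letters[1:10], start = 0, stop = 1:10,
                     event = c(rep(1, 6), rep(0, 4)), x = 5)
  expect_error(fit_cox(rows, "x"), "constant")
  rows$x <- rnorm(10); rows$event <- 0
  expect_error(fit_cox(rows, "x"), "no events")
  rows$event <- c(1, 1, rep(0, 8))
  expect_error(fit_cox(rows, "x"), "too few events")
})

test_that("time-dependent fit equals fixed fit for constant covariates", {
  spec <- cohort_sim_spec(n_patients = 400, covariate = "binary",
                          beta = c(x = log(2)), baseline_hazard = 0.02,
                          risk_window = 30, censor_day = 30, seed = 25)
  co <- simulate_cohort(spec)
  rows <- expand_counting_process(cohort_measurements(co, "covariate"),
                                  cohort_outcomes(co), name = "x")
  td <- fit_cox(rows, "x", model_type = "time_dependent")
  # collapse to one row per patient: covariate constant, so the classical
  # fixed-exposure fit applies
  ends <- tapply(rows$stop, rows$patient_id, max)
  ev <- tapply(rows$event, rows$patient_id, max)
  xv <- tapply(rows$x, rows$patient_id, function(v) v[1])
  fixed_rows <- data.frame(patient_id = names(ends), time = as.numeric(ends),
                           event = as.integer(ev), x = as.numeric(xv))
  fx <- fit_cox(fixed_rows, "x", model_type = "fixed")
  expect_equal(log(td$hr), log(fx$hr), tolerance = 1e-6)
  expect_equal(td$p_value, fx$p_value, tolerance = 1e-6)
})

test_that("stepwise selection keeps a strong covariate among nulls", {
  set.seed(26)
  hits <- 0
  for (r in 1:20) {
    spec <- cohort_sim_spec(n_patients = 300, covariate = "binary",
                            beta = c(x = log(3)), baseline_hazard = 0.02,
                            risk_window = 30, censor_day = 30, seed = 4000 + r)
    co <- simulate_cohort(spec)
    rows <- expand_counting_process(cohort_measurements(co, "covariate"),
                                    cohort_outcomes(co), name = "true_cov")
    for (j in 1:3) rows[[paste0("null", j)]] <- rnorm(nrow(rows))
    sel <- stepwise_select(rows, c("true_cov", paste0("null", 1:3)))
    if ("true_cov" %in% sel$selected) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("stepwise with a single strong candidate matches the univariable fit", {
  spec <- cohort_sim_spec(n_patients = 300, covariate = "binary",
                          beta = c(x = log(3)), baseline_hazard = 0.02,
                          risk_window = 30, censor_day = 30, seed = 27)
  co <- simulate_cohort(spec)
  rows <- expand_counting_process(cohort_measurements(co, "covariate"),
                                  cohort_outcomes(co), name = "x")
  sel <- stepwise_select(rows, "x")
  expect_identical(sel$selected, "x")
  expect_equal(sel$results$hr, fit_cox(rows, "x")$hr)
})

test_that("all-null candidates are mostly rejected", {
  set.seed(28)
  n_sel <- 0
  for (r in 1:15) {
    spec <- cohort_sim_spec(n_patients = 200, covariate = "binary",
                            beta = c(x = 0), baseline_hazard = 0.03,
                            risk_window = 30, censor_day = 30, seed = 5000 + r)
    co <- simulate_cohort(spec)
    rows <- expand_counting_process(cohort_measurements(co, "covariate"),
                                    cohort_outcomes(co), name = "x")
    for (j in 1:3) rows[[paste0("null", j)]] <- rnorm(nrow(rows))
    sel <- stepwise_select(rows, paste0("null", 1:3))
    n_sel <- n_sel + length(sel$selected)
  }
  # expected false entries: about alpha per candidate
  expect_lte(n_sel, 8)
})

test_that("tertile cutoffs follow the interpolation convention", {
  rows <- data.frame(patient_id = letters[1:9], start = 0,
                     stop = c(5, 3, 8, 1, 9, 2, 7, 4, 6),
                     event = rep(1, 9), f = 1:9)
  expect_warning(ta <- tertile_analysis(rows, "f"), NA)
  expect_equal(ta$cutoffs, c(11 / 3, 19 / 3), tolerance = 1e-12)

  rows$f <- rep(5, 9)
  expect_warning(ta2 <- tertile_analysis(rows, "f"), "degenerate")
  expect_true(ta2$degenerate)
  expect_error(tertile_analysis(rows[1:5, ], "f"), "at least 9")
})

test_that("hazard doubling above the upper tertile is detected", {
  # continuous covariate whose top tertile carries the excess hazard
  spec <- cohort_sim_spec(n_patients = 1000, beta = c(slowing = log(2)),
                          baseline_hazard = 0.01, risk_window = 30,
                          censor_day = 30, seed = 29)
  co <- simulate_cohort(spec)
  rows <- expand_counting_process(cohort_measurements(co, "covariate"),
                                  cohort_outcomes(co), name = "sev")
  ta <- tertile_analysis(rows, "sev")
  expect_gt(ta$results$hr, 1)
  expect_lt(ta$results$p_value, 0.05)
})

test_that("two-group comparisons match their classical statistics", {
  # complete separation: U statistic at its extreme, p very small
  g1 <- 1:20; g2 <- 101:120
  gc <- group_compare(c(g1, g2), rep(c("a", "b"), each = 20), "continuous")
  expect_true(gc$statistic %in% c(0, 400))
  expect_lt(gc$p_value, 0.001)

  # 2x2 table [[10, 0], [0, 10]]: chi-square 20 without continuity correction
  vals <- rep(c("pos", "neg"), each = 10)
  grp <- rep(c("a", "b"), each = 10)
  suppressWarnings(cc <- group_compare(vals, grp, "categorical"))
  expect_equal(unname(cc$statistic), 20)

  expect_error(group_compare(1:9, rep(c("a", "b", "c"), each = 3),
                             "continuous"), "two groups")
})

test_that("permuted group labels give uniform p-values", {
  set.seed(30)
  ps <- replicate(200, {
    x <- rnorm(40)
    group_compare(x, sample(rep(c("a", "b"), 20)), "continuous")$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
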