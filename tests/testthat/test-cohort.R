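# Synthetic cohort generator, missingness and imputation.

test_that("generation is deterministic given the seed", {
  sp <- cohort_spec(n = 500, seed = 99)
  expect_identical(generate_cohort(sp), generate_cohort(sp))
  sp2 <- cohort_spec(n = 500, seed = 100)
  expect_false(identical(generate_cohort(sp)$mrs_90d,
                         generate_cohort(sp2)$mrs_90d))
})

test_that("a null treatment effect makes the potential outcomes coincide", {
  tm <- true_model("original")
  tm$coefficients[grep("evt", names(tm$coefficients))] <- 0
  co <- generate_cohort(cohort_spec(n = 2000, truth = tm, seed = 21))
  expect_identical(co$po_mrs_control, co$po_mrs_treated)
})

test_that("observed outcome equals the assigned arm's potential outcome", {
  co <- small_cohort(n = 3000, seed = 22)
  expect_identical(co$mrs_90d,
                   ifelse(co$evt == 1, co$po_mrs_treated, co$po_mrs_control))
  expect_equal(sum(co$evt), 1500)  # 1:1 randomization
  reg <- generate_cohort(cohort_spec(n = 3000, design = "registry", seed = 23))
  expect_true(all(reg$evt == 1))
  expect_identical(reg$mrs_90d, ifelse(reg$etici_success == 1,
                                       reg$po_mrs_treated, reg$po_mrs_control))
})

test_that("empirical good-outcome rates match the model-implied averages", {
  tm <- true_model("original")
  co <- generate_cohort(cohort_spec(n = 20000, truth = tm, seed = 24))
  fit <- toy_fit(tm$cutpoints, tm$coefficients, tm$spec)
  for (arm in 0:1) {
    sel <- co$evt == arm
    implied <- mean(predict(fit, co[sel, ], type = "good", evt_override = arm))
    emp <- mean(co$mrs_90d[sel] <= 2)
    se <- sqrt(implied * (1 - implied) / sum(sel))
    expect_lt(abs(emp - implied), 2.5 * se)
  }
  # full outcome distribution against implied category probabilities (control)
  sel <- co$evt == 0
  pr <- colMeans(predict(fit, co[sel, ], type = "probs", evt_override = 0))
  emp <- as.numeric(table(factor(co$mrs_90d[sel], levels = 0:6))) / sum(sel)
  se <- sqrt(pr * (1 - pr) / sum(sel))
  expect_true(all(abs(emp - pr) < 3 * se + 1e-12))
})

test_that("registry reperfusion hits its target rate", {
  reg <- generate_cohort(cohort_spec(n = 20000, design = "registry",
                                     p_reperf = 0.7, seed = 25))
  expect_equal(mean(reg$etici_success), 0.7, tolerance = 0.02)
})

test_that("copula correlation induces the requested dependence", {
  R <- matrix(c(1, 0.8, 0.8, 1), 2, 2,
              dimnames = list(c("aspects", "collateral_grade"),
                              c("aspects", "collateral_grade")))
  co <- generate_cohort(cohort_spec(n = 10000, copula_cor = R, seed = 26))
  expect_gt(cor(co$aspects, co$collateral_grade, method = "spearman"), 0.5)
  co0 <- generate_cohort(cohort_spec(n = 10000, seed = 26))
  expect_lt(abs(cor(co0$aspects, co0$collateral_grade)), 0.05)
})

test_that("MCAR injection blanks at the configured rate, reproducibly", {
  co <- small_cohort(n = 10000, seed = 27)
  m1 <- inject_missingness(co, c(collateral_grade = 0.33), seed = 5)
  frac <- mean(is.na(m1$collateral_grade))
  se <- sqrt(0.33 * 0.67 / 10000)
  expect_lt(abs(frac - 0.33), 2 * se)
  expect_false(anyNA(m1$mrs_90d))
  expect_identical(m1, inject_missingness(co, c(collateral_grade = 0.33), seed = 5))
  expect_identical(inject_missingness(co, c(age = 0, nihss = 0), seed = 1), co)
  expect_error(inject_missingness(co, c(age = 1.2), seed = 1), "\\[0, 1\\]")
})

test_that("mean and mode imputation fill sparse gaps", {
  d <- data.frame(age = c(60, 70, 80, NA), diabetes = c(1, 1, 1, 0),
                  iv_alteplase = c(1, 1, 0, 1), mrs_90d = c(0, 2, 4, 6))
  d$diabetes[2] <- NA
  out <- impute_cohort(d, policy = "mean_mode")
  expect_equal(out$age[4], 70)
  expect_equal(out$diabetes[2], 1)
  expect_false(anyNA(out))
  dd <- data.frame(age = c(NA_real_, NA_real_), mrs_90d = c(1, 2))
  expect_error(impute_cohort(dd), "no observed values")
  d$mrs_90d[1] <- NA
  expect_error(impute_cohort(d), "outcome")
})

test_that("regression imputation outperforms the mode on correlated data", {
  R <- matrix(c(1, 0.8, 0.8, 1), 2, 2,
              dimnames = list(c("aspects", "collateral_grade"),
                              c("aspects", "collateral_grade")))
  co <- generate_cohort(cohort_spec(n = 4000, copula_cor = R, seed = 28))
  truth <- co$collateral_grade
  masked <- inject_missingness(co, c(collateral_grade = 0.33), seed = 6)
  idx <- is.na(masked$collateral_grade)
  reg <- impute_cohort(masked, policy = "single_regression", threshold = 0.05)
  mm <- impute_cohort(masked, policy = "mean_mode")
  acc_reg <- mean(reg$collateral_grade[idx] == truth[idx])
  acc_mode <- mean(mm$collateral_grade[idx] == truth[idx])
  expect_gt(acc_reg, acc_mode)
  expect_false(anyNA(reg$collateral_grade))
})

test_that("end-to-end: fitting a generated cohort recovers the generator", {
  tm <- true_model("updated")
  co <- generate_cohort(cohort_spec(n = 8000, truth = tm, seed = 29))
  fit <- fit_mrs_model(co, tm$spec)
  est <- c(fit$cutpoints, fit$coefficients)
  tru <- c(tm$cutpoints, tm$coefficients)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(est - tru) <= 3 * se))
})
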