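# Likelihood-ratio tests, intercept recalibration, cohort-adjusted refit.

test_that("identical models give statistic 0 and p = 1", {
  co <- small_cohort(n = 400, seed = 12)
  sp <- model_spec(main = c("age", "nihss"))
  fit <- fit_mrs_model(co, sp)
  out <- lr_test(fit, fit)
  expect_equal(unname(out$statistic), 0)
  expect_equal(out$p.value, 1)
})

test_that("LR statistic equals twice the independently computed loglik gap", {
  set.seed(23)
  full_sp <- model_spec(main = c("age", "nihss", "collateral_grade"))
  red_sp <- model_spec(main = c("age", "nihss"))
  for (rep in 1:20) {
    co <- small_cohort(n = 150, seed = 1000 + rep)
    full <- fit_mrs_model(co, full_sp)
    red <- fit_mrs_model(co, red_sp)
    Xf <- build_design(co, full_sp)
    Xr <- build_design(co, red_sp)
    gap <- 2 * (direct_loglik(full$cutpoints, full$coefficients, Xf, co$mrs_90d) -
                  direct_loglik(red$cutpoints, red$coefficients, Xr, co$mrs_90d))
    out <- lr_test(full, red)
    expect_equal(unname(out$statistic), gap, tolerance = 1e-8)
    expect_gte(unname(out$statistic), 0)
    expect_equal(unname(out$parameter), 1)
  }
})

test_that("non-nested or mismatched fits are refused", {
  co <- small_cohort(n = 300, seed = 13)
  f1 <- fit_mrs_model(co, model_spec(main = c("age", "nihss")))
  f2 <- fit_mrs_model(co, model_spec(main = c("age", "sbp")))
  expect_error(lr_test(f1, f2), "nested")
  f3 <- fit_mrs_model(co[1:250, ], model_spec(main = "age"))
  expect_error(lr_test(f1, f3), "observation")
})

test_that("recalibration recovers an intercept shift with coefficients untouched", {
  tm <- true_model("original")
  co <- generate_cohort(cohort_spec(n = 10000, truth = tm, seed = 31))
  fit <- fit_mrs_model(co, tm$spec)
  # external cohort from the same process: delta ~ 0
  ext_same <- generate_cohort(cohort_spec(n = 10000, truth = tm, seed = 32))
  r1 <- recalibrate_intercepts(fit, ext_same)
  expect_lt(abs(r1$recalibration$delta), 0.05)
  # external cohort generated with all true cutpoints shifted by +0.5:
  # the recalibrated offset must reproduce that shift (|delta| = 0.5; its
  # sign follows this package's convention cutpoints_new = cutpoints + delta)
  tm_shift <- tm
  tm_shift$cutpoints <- tm$cutpoints + 0.5
  ext_shift <- generate_cohort(cohort_spec(n = 10000, truth = tm_shift, seed = 33))
  r2 <- recalibrate_intercepts(fit, ext_shift)
  expect_equal(r2$recalibration$delta, 0.5, tolerance = 0.05)
  expect_identical(r2$coefficients, fit$coefficients)
  expect_equal(unname(r2$cutpoints - fit$cutpoints),
               rep(r2$recalibration$delta, 6), tolerance = 1e-12)
  # calibration-in-the-large after recalibration ~ 0
  cal <- calibration_intercept_slope(predict(r2, ext_shift, type = "good"),
                                     as.numeric(ext_shift$mrs_90d <= 2))
  expect_lt(abs(cal$intercept), 0.06)
  expect_error(recalibrate_intercepts(fit, ext_same[0, ]), "empty")
})

test_that("cohort-adjusted refit recovers a null and a real cohort offset", {
  tm <- true_model("original")
  a <- generate_cohort(cohort_spec(n = 3000, truth = tm, label = "A", seed = 41))
  b <- generate_cohort(cohort_spec(n = 3000, truth = tm, label = "B", seed = 42))
  fit0 <- refit_with_cohort_adjustment(rbind(a, b), spec_original())
  off <- fit0$coefficients["cohortB"]
  se <- sqrt(diag(fit0$vcov))["cohortB"]
  expect_lt(abs(off), 3 * se)
  # shift cohort B's outcome level by +0.4 on the linear-predictor scale
  tm_s <- tm; tm_s$cutpoints <- tm$cutpoints + 0.4
  b2 <- generate_cohort(cohort_spec(n = 3000, truth = tm_s, label = "B", seed = 43))
  fit1 <- refit_with_cohort_adjustment(rbind(a, b2), spec_original())
  off1 <- fit1$coefficients["cohortB"]
  se1 <- sqrt(diag(fit1$vcov))["cohortB"]
  expect_lt(abs(off1 - 0.4), 3 * se1)
  # shared predictor coefficients stay near the pooled truth
  shared <- setdiff(names(fit1$coefficients), "cohortB")
  se_sh <- sqrt(diag(fit1$vcov))[shared]
  expect_true(all(abs(fit1$coefficients[shared] - tm$coefficients[shared])
                  <= 3 * se_sh))
  expect_error(refit_with_cohort_adjustment(a, spec_original()), "one cohort")
})
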