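# Category probabilities, cumulative monotonicity, and predicted benefit.

test_that("uniform construction gives equal category probabilities", {
  sp <- model_spec(main = "age")
  fit <- toy_fit(qlogis((1:6) / 7), c(age = 0, evt = 0), sp)
  pr <- predict(fit, toy_profile(), type = "probs")
  expect_equal(unname(pr[1, ]), rep(1 / 7, 7), tolerance = 1e-12)
})

test_that("link saturation sends all mass to mRS 0", {
  sp <- model_spec(main = "age")
  fit <- toy_fit(qlogis((1:6) / 7), c(age = 1, evt = 0), sp)
  pr <- predict(fit, toy_profile(age = 60), type = "probs")  # eta = 60
  expect_equal(unname(pr[1, 1]), 1, tolerance = 1e-12)
  expect_equal(sum(pr[1, -1]), 0, tolerance = 1e-12)
})

test_that("probabilities match an independent re-implementation on random models", {
  set.seed(41)
  sp <- toy_spec(c("onset_to_groin", "collateral_grade"))
  cols <- design_colnames(sp)
  for (rep in 1:20) {
    alpha <- sort(rnorm(6, 0, 2))
    fit <- toy_fit(alpha, setNames(rnorm(length(cols), 0, 0.02), cols), sp)
    prof <- toy_profile(age = runif(1, 40, 90), evt = rbinom(1, 1, 0.5),
                        onset_to_groin = runif(1, 60, 390),
                        collateral_grade = sample(0:3, 1))
    X <- build_design(prof, sp)
    eta <- sum(X[1, ] * fit$coefficients)
    expect_equal(unname(predict(fit, prof, type = "probs")[1, ]),
                 direct_category_probs(alpha, eta), tolerance = 1e-12)
  }
})

test_that("category probabilities are a simplex and cumulatives are monotone", {
  set.seed(7)
  co <- small_cohort(n = 300, seed = 5)
  fit <- fit_mrs_model(co, spec_original())
  pr <- predict(fit, co, type = "probs")
  expect_true(all(pr >= 0))
  expect_equal(unname(rowSums(pr)), rep(1, nrow(co)), tolerance = 1e-12)
  cum <- predict(fit, co, type = "cumulative")
  expect_true(all(diff(t(cum)) >= 0))
})

test_that("non-monotone cutpoints are an invalid model", {
  sp <- model_spec(main = "age")
  fit <- toy_fit(c(0, 1, 0.5, 2, 3, 4), c(age = 0, evt = 0), sp)
  expect_error(predict(fit, toy_profile(), type = "probs"),
               "strictly increasing")
})

test_that("predicted benefit is zero without treatment terms in play", {
  sp <- model_spec(main = "age")
  fit <- toy_fit(sort(rnorm(6)), c(age = -0.02, evt = 0), sp)
  b <- predicted_benefit(fit, toy_profile(age = c(50)))
  expect_identical(b$benefit, 0)
})

test_that("benefit is modified by baseline risk through the logistic link", {
  sp <- model_spec(main = "age")
  beta_evt <- 0.6
  fit <- toy_fit(c(-1, 0, 1, 2, 3, 4), c(age = -0.1, evt = beta_evt), sp)
  # choose ages so control P(good) ~ 0.01 and ~ 0.50: alpha_3 = 1
  age_mid <- 1 / 0.1                      # eta = -1 -> P(good) = 0.5
  age_low <- (1 - qlogis(0.01)) / 0.1     # P(good) = 0.01
  b <- predicted_benefit(fit, data.frame(age = c(age_low, age_mid), evt = 0))
  expect_equal(b$p_good_control[1], 0.01, tolerance = 1e-10)
  expect_equal(b$p_good_control[2], 0.50, tolerance = 1e-10)
  expect_gt(b$benefit[2], b$benefit[1])
  expect_true(all(b$benefit > 0))
})

test_that("a negative treatment-by-time coefficient shrinks benefit over time", {
  sp <- toy_spec("onset_to_groin")
  fit <- toy_fit(c(-1, 0, 1, 2, 3, 4),
                 setNames(c(-0.02, -0.001, 0.9, -0.002), design_colnames(sp)),
                 sp)
  b <- predicted_benefit(fit, toy_profile(onset_to_groin = c(120, 360), n = 2))
  expect_gt(b$benefit[1], b$benefit[2])
})

test_that("predicted benefit ignores the profile's recorded treatment value", {
  co <- small_cohort(n = 200, seed = 11)
  fit <- fit_mrs_model(co, spec_original())
  b1 <- predicted_benefit(fit, transform(co, evt = 0))
  b2 <- predicted_benefit(fit, transform(co, evt = 1))
  expect_identical(b1, b2)
})

test_that("benefit vanishes at degenerate baseline risk and is positive between", {
  sp <- model_spec(main = "age")
  fit <- toy_fit(c(-1, 0, 1, 2, 3, 4), c(age = -0.1, evt = 0.8), sp)
  grid <- data.frame(age = seq(-400, 600, by = 25), evt = 0)
  grid$age <- pmax(grid$age, 0.1)  # keep ages positive but spanning the link
  b <- predicted_benefit(fit, grid)
  expect_true(all(b$benefit >= 0))
  expect_true(all(b$benefit <= 1))
  # extremes of baseline risk: benefit ~ 0
  extreme <- b$p_good_control < 1e-6 | b$p_good_control > 1 - 1e-6
  expect_true(all(b$benefit[extreme] < 1e-5))
  mid <- b$p_good_control > 0.2 & b$p_good_control < 0.8
  expect_true(all(b$benefit[mid] > 0.05))
})

test_that("benefit requires a treatment term in the spec", {
  sp <- model_spec(main = "age")
  fit <- toy_fit(sort(rnorm(6)), c(age = 0.1), sp)
  fit$coefficients <- c(age = 0.1)  # no evt coefficient
  expect_error(predicted_benefit(fit, toy_profile()), "evt")
})
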