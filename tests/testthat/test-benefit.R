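# Matched pairs, c-for-benefit, benefit-group calibration.

test_that("rank matching pairs every retained patient exactly once", {
  b <- c(0.05, 0.10, 0.20, 0.01, 0.15, 0.08, 0.12, 0.03)
  arm <- c(1, 1, 1, 0, 0, 0, 0, 0)          # 3 treated, 5 controls
  good <- c(1, 0, 1, 0, 1, 0, 0, 1)
  pr <- match_benefit_pairs(b, arm, good, seed = 4)
  expect_equal(nrow(pr), 3)
  expect_equal(length(unique(pr$treated_id)), 3)
  expect_equal(length(unique(pr$control_id)), 3)
  expect_true(all(pr$treated_id %in% which(arm == 1)))
  expect_true(all(pr$control_id %in% which(arm == 0)))
  expect_true(all(pr$pair_observed %in% c(-1, 0, 1)))
  # rank alignment: both sides sorted by predicted benefit
  expect_true(all(diff(pr$benefit_treated) >= 0))
  expect_true(all(diff(pr$benefit_control) >= 0))
  expect_error(match_benefit_pairs(b, rep(1, 8), good, seed = 1), "nonempty")
})

test_that("equal per-rank benefits make the pair benefit that shared value", {
  b <- c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3)
  arm <- c(1, 1, 1, 0, 0, 0)
  pr <- match_benefit_pairs(b, arm, rep(0, 6), seed = 1)
  expect_equal(pr$pair_predicted, c(0.1, 0.2, 0.3))
  expect_equal(pr$benefit_treated, pr$benefit_control)
})

test_that("rank matching beats random pairing on within-pair benefit distance", {
  set.seed(61)
  for (rep in 1:20) {
    n <- 60
    b <- runif(n, 0, 0.3)
    arm <- rep_len(c(1, 0), n)
    pr <- match_benefit_pairs(b, arm, rbinom(n, 1, 0.4), seed = rep)
    rank_d <- mean(abs(pr$benefit_treated - pr$benefit_control))
    sh <- sample(which(arm == 0))
    rand_d <- mean(abs(b[arm == 1] - b[sh]))
    expect_lte(rank_d, rand_d + 1e-12)
  }
})

test_that("c-for-benefit matches its examples and the exhaustive oracle", {
  expect_equal(c_for_benefit(c(0.20, 0.05), c(1, -1)), 1.0)
  expect_equal(c_for_benefit(rep(0.07, 6), c(1, 0, -1, 1, 0, -1)), 0.5)
  expect_error(c_for_benefit(c(0.1, 0.2, 0.3), c(0, 0, 0)), "undefined")
  expect_error(c_for_benefit(0.1, 1), "at least 2")
  set.seed(62)
  for (rep in 1:10) {
    m <- 100
    pred <- round(runif(m, -0.05, 0.25), 2)
    obs <- sample(c(-1, 0, 1), m, replace = TRUE)
    expect_identical(c_for_benefit(pred, obs), brute_c_for_benefit(pred, obs))
  }
})

test_that("c-for-benefit is invariant under increasing benefit transforms", {
  set.seed(63)
  pred <- runif(80)
  obs <- sample(c(-1, 0, 1), 80, replace = TRUE)
  expect_equal(c_for_benefit(pred, obs), c_for_benefit(pred^3 + 2, obs))
})

test_that("perfect ordering of observed by predicted benefit gives 1", {
  pred <- sort(runif(30))
  obs <- rep(c(-1, 0, 1), each = 10)    # higher predicted <-> higher observed
  expect_equal(c_for_benefit(pred, obs), 1.0)
})

test_that("benefit classes use the 1% and 10% cut points", {
  b <- c(0.005, 0.02, 0.5, 0.15, 0.0, 0.09)
  tab <- benefit_group_table(b, rep_len(c(1, 0), 6), rbinom(6, 1, 0.5),
                             grouping = "classes")
  expect_equal(tab$group, c("low (<1%)", "moderate (1-10%)", "high (>10%)"))
  expect_equal(tab$upper[1], 0.01)
  expect_equal(tab$lower[2], 0.01)
  expect_equal(tab$upper[2], 0.10)
  expect_equal(tab$lower[3], 0.10)
  expect_equal(sum(tab$n_treated) + sum(tab$n_control), 6)
})

test_that("weighted per-group observed benefits reproduce the cohort contrast", {
  set.seed(64)
  m <- 300
  bvals <- runif(m, -0.02, 0.25)
  b <- rep(bvals, each = 2)             # one treated + one control per value
  arm <- rep_len(c(1, 0), 2 * m)
  good <- rbinom(2 * m, 1, 0.3 + pmax(b, 0) * arm)
  tab <- benefit_group_table(b, arm, good, grouping = "quintiles")
  expect_equal(sum(tab$n_treated), m)
  expect_equal(sum(tab$n_control), m)
  expect_true(all(tab$n_treated == tab$n_control))
  w <- (tab$n_treated + tab$n_control) / (2 * m)
  overall <- mean(good[arm == 1]) - mean(good[arm == 0])
  expect_equal(sum(w * tab$observed), overall, tolerance = 1e-12)
})

test_that("degenerate constant benefits collapse quintiles without error", {
  tab <- benefit_group_table(rep(0.1, 40), rep_len(c(1, 0), 40),
                             rbinom(40, 1, 0.5), grouping = "quintiles")
  expect_equal(nrow(tab), 1)
  expect_false(tab$flagged[1])
})

test_that("groups lacking an arm are flagged with undefined observed benefit", {
  b <- c(0.001, 0.002, 0.2, 0.3)
  tab <- benefit_group_table(b, c(1, 1, 1, 0), c(1, 0, 1, 0), "classes")
  expect_true(tab$flagged[1])           # low class has treated only
  expect_true(is.na(tab$observed[1]))
})

test_that("the registry surrogate contrast is guarded and labelled", {
  tm <- true_model("original")
  reg <- generate_cohort(cohort_spec(n = 2000, design = "registry",
                                     truth = tm, seed = 65))
  fit <- toy_fit(tm$cutpoints, tm$coefficients, tm$spec)
  tab <- registry_surrogate_benefit(fit, reg, grouping = "classes")
  expect_true(attr(tab, "surrogate"))
  rct <- generate_cohort(cohort_spec(n = 100, truth = tm, seed = 66))
  expect_error(registry_surrogate_benefit(fit, rct), "all-treated")
  reg2 <- reg; reg2$etici_success <- NULL
  expect_error(registry_surrogate_benefit(fit, reg2), "etici_success")
})

test_that("reperfusion tied to outcome shows surrogate benefit where predicted", {
  tm <- true_model("original")
  reg <- generate_cohort(cohort_spec(n = 20000, design = "registry",
                                     truth = tm, p_reperf = 0.7, seed = 67))
  fit <- toy_fit(tm$cutpoints, tm$coefficients, tm$spec)
  tab <- registry_surrogate_benefit(fit, reg, grouping = "classes")
  hi <- tab[tab$group == "high (>10%)", ]
  expect_gt(hi$observed, 0)
})

test_that("a null treatment effect yields zero surrogate benefit", {
  tm <- true_model("original")
  tm$coefficients[c("evt", "evt:onset_to_groin", "evt:collateral_grade",
                    "evt:prior_stroke")] <- 0
  reg <- generate_cohort(cohort_spec(n = 20000, design = "registry",
                                     truth = tm, reperf_coef = c(age = 0),
                                     p_reperf = 0.6, seed = 68))
  # reperfusion independent of covariates and outcome: contrast ~ 0
  d <- mean(reg$mrs_90d[reg$etici_success == 1] <= 2) -
       mean(reg$mrs_90d[reg$etici_success == 0] <= 2)
  se <- sqrt(sum(1 / table(reg$etici_success)) * 0.25)
  expect_lt(abs(d), 2 * se)
})
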