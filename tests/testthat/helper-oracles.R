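# Independent oracles, deliberately written with plain loops and direct
# formulas, never calling the implementation paths they check.

# Exhaustive pairwise concordance.  Convention: over all pairs with
# different outcome, count 1 when the member with the higher outcome has
# the strictly higher score, 0.5 on score ties.
brute_concordance <- function(score, outcome) {
  num <- 0; den <- 0
  n <- length(score)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (outcome[i] == outcome[j]) next
    den <- den + 1
    hi <- if (outcome[i] > outcome[j]) i else j
    lo <- if (outcome[i] > outcome[j]) j else i
    if (score[hi] > score[lo]) num <- num + 1
    else if (score[hi] == score[lo]) num <- num + 0.5
  }
  num / den
}
brute_c_binary <- function(pred, y) brute_concordance(pred, y)
brute_c_ordinal <- function(score, mrs) brute_concordance(score, -mrs)
brute_c_for_benefit <- function(pred, obs) brute_concordance(pred, obs)

# Direct evaluation of the restricted (natural) cubic spline in
# truncated-power form, scalar x, normalized by the squared boundary span.
direct_rcs_term <- function(x, knots, j) {
  k <- length(knots)
  tp <- function(u) if (u > 0) u^3 else 0
  t1 <- knots[1]; tkm1 <- knots[k - 1]; tk <- knots[k]
  (tp(x - knots[j]) -
     tp(x - tkm1) * (tk - knots[j]) / (tk - tkm1) +
     tp(x - tk) * (tkm1 - knots[j]) / (tk - tkm1)) / (tk - t1)^2
}

# Direct category probabilities of the cumulative-logit model for one
# profile: successive differences of inverse-logits.
direct_category_probs <- function(alpha, eta) {
  cum <- 1 / (1 + exp(-(unname(alpha) + eta)))
  diff(c(0, cum, 1))
}

# Direct log-likelihood from first principles (per-observation loop).
direct_loglik <- function(cutpoints, beta, X, y) {
  s <- 0
  for (i in seq_along(y)) {
    eta <- sum(unname(X[i, ]) * unname(beta))
    p <- direct_category_probs(cutpoints, eta)[y[i] + 1]
    s <- s + log(p)
  }
  unname(s)
}

# Minimal hand-built fitted-model object for prediction-level tests.
toy_fit <- function(cutpoints, coefficients, spec) {
  structure(list(cutpoints = setNames(cutpoints, paste0("mrs<=", 0:5)),
                 coefficients = coefficients,
                 vcov = diag(length(cutpoints) + length(coefficients)),
                 logLik = NA_real_, n = NA_integer_, converged = TRUE,
                 grad_norm = 0, iterations = 0L, spec = spec,
                 cohort_levels = NULL, call = NULL),
            class = "mrs_fit")
}

# Tiny one-covariate spec and profile maker used across prediction tests.
toy_spec <- function(interactions = character())
  model_spec(main = unique(c("age", interactions)), interactions = interactions)

toy_profile <- function(age = 70, evt = 0, onset_to_groin = 200,
                        collateral_grade = 2, n = 1) {
  data.frame(age = rep(age, n), evt = rep(evt, n),
             onset_to_groin = rep(onset_to_groin, n),
             collateral_grade = rep(collateral_grade, n))
}

# Small simulated trial cohort via the package generator (shared fixture).
small_cohort <- function(n = 500, seed = 1, preset = "original", ...)
  generate_cohort(cohort_spec(n = n, truth = true_model(preset), seed = seed, ...))
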