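# Synthetic cohort generation.  All defaults are synthetic study conditions
# chosen to give plausible large-vessel-occlusion stroke marginals; they are
# fully configurable and none is an estimate from patient data.

law <- function(dist, ...) structure(list(dist = dist, ...), class = "cov_law")

# quantile transform of one law: u in (0,1) -> value
law_quantile <- function(l, u) {
  switch(l$dist,
    truncnorm = {
      plo <- pnorm(l$lower, l$mean, l$sd); phi <- pnorm(l$upper, l$mean, l$sd)
      x <- qnorm(plo + u * (phi - plo), l$mean, l$sd)
      if (isTRUE(l$integer)) x <- round(x)
      pmin(pmax(x, l$lower), l$upper)
    },
    lognormal = exp(qnorm(u, l$meanlog, l$sdlog)),
    uniform = l$min + u * (l$max - l$min),
    bernoulli = as.numeric(u > 1 - l$p),
    categorical = {
      cum <- cumsum(l$probs)
      idx <- findInterval(u, c(0, cum), left.open = TRUE, rightmost.closed = TRUE)
      idx <- pmin(pmax(idx, 1L), length(l$values))
      l$values[idx]
    },
    stop("unknown covariate law: ", l$dist))
}

#' Default covariate laws for synthetic stroke cohorts
#'
#' Marginal distributions emulating a large-vessel-occlusion EVT
#' population: age truncated normal around 68 y; NIHSS integer truncated
#' normal around 16; SBP around 145 mmHg; glucose log-normal with median
#' 120 mg/dL; IV alteplase in ~85%; diabetes ~15%; prestroke mRS mostly 0;
#' ASPECTS skewed toward 8--10; occlusion mostly M1; collateral grades
#' mostly 2--3; onset-to-groin uniform between 60 and 390 minutes (within
#' the 6.5-hour treatment window); prior stroke ~10%.  Every law can be
#' replaced, or substituted by a function `function(n)` returning draws.
#'
#' @return named list of covariate laws.
#' @export
default_covariate_laws <- function() {
  list(
    age = law("truncnorm", mean = 68, sd = 13, lower = 18, upper = 100),
    nihss = law("truncnorm", mean = 16, sd = 5, lower = 2, upper = 42, integer = TRUE),
    sbp = law("truncnorm", mean = 145, sd = 24, lower = 80, upper = 230),
    glucose = law("lognormal", meanlog = log(120), sdlog = 0.22),
    iv_alteplase = law("bernoulli", p = 0.85),
    diabetes = law("bernoulli", p = 0.15),
    prestroke_mrs = law("categorical", values = 0:5,
                        probs = c(0.75, 0.12, 0.06, 0.04, 0.02, 0.01)),
    aspects = law("categorical", values = 0:10,
                  probs = c(0.002, 0.003, 0.005, 0.01, 0.02, 0.04,
                            0.07, 0.13, 0.22, 0.27, 0.23)),
    occlusion_location = law("categorical", values = c("ICA/ICA-T", "M1", "M2"),
                             probs = c(0.25, 0.60, 0.15)),
    collateral_grade = law("categorical", values = 0:3,
                           probs = c(0.07, 0.25, 0.40, 0.28)),
    onset_to_groin = law("uniform", min = 60, max = 390),
    prior_stroke = law("bernoulli", p = 0.10)
  )
}

#' Default true generating models
#'
#' Named coefficient sets (on the cumulative-logit scale, positive = better
#' outcome) and cutpoints used by the generator's defaults.  The
#' `"original"` truth matches the original model configuration (prior
#' stroke in, no glucose effect); the `"updated"` truth adds a
#' piecewise-linear glucose effect with slopes corresponding to common odds
#' ratios of about 0.97 per 10 mg/dL below 120 and 0.98 above, and drops
#' the prior-stroke terms.  Cutpoints were fixed once so that, at the
#' default covariate laws, the control-arm probability of functional
#' independence is about 0.25 and the treated-arm about 0.38.
#'
#' @param preset `"original"` or `"updated"`.
#' @return list with `spec` (an `mrs_spec`), `cutpoints` (6) and
#'   `coefficients` named by design column.
#' @export
true_model <- function(preset = c("original", "updated")) {
  preset <- match.arg(preset)
  base <- c(age = -0.035, nihss = -0.09, sbp = -0.006,
            iv_alteplase = 0.30, diabetes = -0.30, prestroke_mrs = -0.45,
            aspects = 0.12, occlusion_ICA = -0.45, occlusion_M2 = 0.20,
            collateral_grade = 0.30, onset_to_groin = -0.0015)
  if (preset == "original") {
    spec <- spec_original()
    beta <- c(base, prior_stroke = 0,
              evt = 0.77, `evt:onset_to_groin` = -0.002,
              `evt:collateral_grade` = 0.15, `evt:prior_stroke` = 0)
  } else {
    spec <- spec_updated()
    beta <- c(base, glucose = -0.003, glucose_hinge = 0.001,
              evt = 0.77, `evt:onset_to_groin` = -0.002,
              `evt:collateral_grade` = 0.15)
  }
  beta <- beta[design_colnames(spec)]
  cut <- switch(preset,
    original = c(0.288, 1.396, 2.286, 3.132, 3.987, 5.108),
    updated  = c(0.643, 1.751, 2.642, 3.488, 4.344, 5.466))
  list(spec = spec, cutpoints = setNames(cut, paste0("mrs<=", 0:5)),
       coefficients = beta)
}

#' Cohort generation scenario
#'
#' Bundles everything needed to draw one synthetic cohort: size, design
#' (1:1 randomized trial, or all-treated registry with a reperfusion
#' surrogate), covariate laws, the true outcome model, optional
#' Gaussian-copula correlation between covariates, per-field MCAR
#' missingness rates, and the seed.
#'
#' @param n number of patients (> 0).
#' @param design `"rct"` (1:1 randomization) or `"registry"` (all treated).
#' @param covariate_laws named list of laws or `function(n)` generators;
#'   see [default_covariate_laws()].
#' @param truth a [true_model()] list (spec + cutpoints + coefficients).
#' @param p_reperf registry only: marginal probability of successful
#'   reperfusion (eTICI >= 2b); the generator solves the logistic intercept
#'   so the realized covariate mix attains it.
#' @param reperf_coef registry only: named logistic coefficients linking
#'   covariates to reperfusion success (default: collateral grade helps).
#' @param copula_cor optional correlation matrix (named rows/cols a subset
#'   of the law names) inducing Gaussian-copula dependence between those
#'   covariates; laws given as functions cannot be correlated.
#' @param missingness named per-field MCAR rates in `[0, 1]`.
#' @param label cohort label written to the `cohort` column.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, design = c("rct", "registry"),
                        covariate_laws = default_covariate_laws(),
                        truth = true_model("original"),
                        p_reperf = 0.7,
                        reperf_coef = c(collateral_grade = 0.3),
                        copula_cor = NULL,
                        missingness = NULL,
                        label = "synthetic",
                        seed = 1) {
  design <- match.arg(design)
  stopifnot(n > 0)
  if (!is.null(missingness)) {
    if (any(missingness < 0 | missingness > 1))
      stop("missingness rates must lie in [0, 1]")
    bad <- setdiff(names(missingness), names(covariate_laws))
    if (length(bad)) stop("missingness rates for unknown fields: ",
                          paste(bad, collapse = ", "))
  }
  for (nm in names(covariate_laws)) {
    l <- covariate_laws[[nm]]
    if (inherits(l, "cov_law") && l$dist %in% c("categorical")) {
      if (abs(sum(l$probs) - 1) > 1e-8)
        stop("law probabilities for '", nm, "' must sum to 1")
    }
  }
  if (design == "registry") {
    stopifnot(is.numeric(p_reperf), p_reperf > 0, p_reperf < 1)
  }
  structure(list(n = as.integer(n), design = design,
                 covariate_laws = covariate_laws, truth = truth,
                 p_reperf = p_reperf, reperf_coef = reperf_coef,
                 copula_cor = copula_cor, missingness = missingness,
                 label = label, seed = seed),
            class = "cohort_spec")
}

draw_covariates <- function(spec) {
  laws <- spec$covariate_laws
  n <- spec$n
  u <- matrix(runif(n * length(laws)), n, length(laws),
              dimnames = list(NULL, names(laws)))
  if (!is.null(spec$copula_cor)) {
    R <- spec$copula_cor
    nm <- rownames(R)
    if (any(vapply(laws[nm], is.function, logical(1))))
      stop("copula correlation cannot apply to function-valued laws")
    L <- chol(R)
    Z <- matrix(rnorm(n * length(nm)), n, length(nm)) %*% L
    u[, nm] <- pnorm(Z)
  }
  out <- list()
  for (nm in names(laws)) {
    l <- laws[[nm]]
    out[[nm]] <- if (is.function(l)) l(n) else law_quantile(l, u[, nm])
  }
  as.data.frame(out, check.names = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws covariates from the scenario's laws, then draws each patient's two
#' potential mRS outcomes (under control and under treatment) from the true
#' model's category probabilities using one shared uniform draw per patient
#' (comonotone coupling), so individual-level benefit is well defined in
#' fixtures while every marginal statistic matches the model.  The observed
#' outcome is the potential outcome of the assigned arm.  Registry cohorts
#' are all-treated; reperfusion success follows a logistic model on
#' covariates with its intercept solved so the realized marginal equals
#' `p_reperf`, and a non-reperfused patient's outcome is drawn under the
#' control arm — an explicit simplification standing in for procedure
#' failure.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with the predictor columns, `evt`, `etici_success`
#'   (registry), `mrs_90d`, `cohort`, and latent potential outcomes
#'   `po_mrs_control` / `po_mrs_treated` kept for oracle checks.  The
#'   scenario is attached as attribute `"cohort_spec"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    dat <- draw_covariates(spec)
    n <- spec$n
    tm <- spec$truth
    dat$evt <- 0  # placeholder for design build
    X0 <- build_design(dat, tm$spec, evt_override = 0, validate = FALSE)
    X1 <- build_design(dat, tm$spec, evt_override = 1, validate = FALSE)
    beta <- tm$coefficients
    cum0 <- mrs_cumprob(tm$cutpoints, drop(X0 %*% beta))
    cum1 <- mrs_cumprob(tm$cutpoints, drop(X1 %*% beta))
    u <- runif(n)
    y0 <- as.integer(rowSums(u > cum0))
    y1 <- as.integer(rowSums(u > cum1))
    if (spec$design == "rct") {
      dat$evt <- sample(rep_len(c(0L, 1L), n))
      dat$mrs_90d <- ifelse(dat$evt == 1, y1, y0)
    } else {
      dat$evt <- 1L
      rc <- spec$reperf_coef
      lin <- numeric(n)
      for (nm in names(rc)) lin <- lin + rc[[nm]] * as.numeric(dat[[nm]])
      a0 <- stats::uniroot(function(a) mean(plogis(a + lin)) - spec$p_reperf,
                           interval = c(-30, 30))$root
      dat$etici_success <- rbinom(n, 1, plogis(a0 + lin))
      dat$mrs_90d <- ifelse(dat$etici_success == 1, y1, y0)
    }
    dat$po_mrs_control <- y0
    dat$po_mrs_treated <- y1
    dat$cohort <- spec$label
  })
  attr(dat, "cohort_spec") <- spec
  dat
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort scenario: n = ", x$n, ", design = ", x$design,
      ", label = ", x$label, ", seed = ", x$seed, "\n", sep = "")
  if (x$design == "registry")
    cat("  reperfusion target p = ", x$p_reperf, "\n", sep = "")
  if (!is.null(x$missingness))
    cat("  MCAR rates: ",
        paste(names(x$missingness), signif(x$missingness, 3),
              sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
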