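# Orchestration of the full derive / validate / update / re-validate
# workflow at synthetic scale.

# Deterministic fan-out of the master seed into independent per-stage seeds.
# Each stage owns a fixed named offset, so inserting a new stage never
# perturbs the draws of existing ones.
.stage_offsets <- c(derivation = 11, validation = 22, registry = 33,
                    missing_validation = 44, missing_registry = 55,
                    boot_validation = 66, pairs_validation = 77,
                    boot_registry = 88, pairs_registry = 99)

stage_seed <- function(master, stage) {
  off <- .stage_offsets[[stage]]
  as.integer((as.numeric(master) * 1009 + off) %% 2147483647)
}

#' Study configuration
#'
#' Everything [run_study()] needs: the three cohort scenarios (derivation
#' trial, validation trial, all-treated registry), the model presets, the
#' bootstrap size, the benefit groupings, and the master seed from which
#' every stage seed is derived.
#'
#' @param n_derivation,n_validation,n_registry cohort sizes.
#' @param truth the generating [true_model()] shared by all cohorts (the
#'   registry may shift cutpoints via `registry_shift`).
#' @param registry_shift additive shift applied to the registry generator's
#'   cutpoints (a different baseline outcome level in routine practice).
#' @param missingness optional named MCAR rates applied to the validation
#'   and registry cohorts before imputation.
#' @param original_spec,updated_spec model configurations fitted before and
#'   after updating.
#' @param B bootstrap replications for every validation (>= 40).
#' @param recalibrate also recalibrate the updated model's intercept on the
#'   registry and report the offset.
#' @param seed master seed.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_derivation = 2000, n_validation = 2000,
                         n_registry = 2000,
                         truth = true_model("original"),
                         registry_shift = 0,
                         missingness = NULL,
                         original_spec = spec_original(),
                         updated_spec = spec_updated(),
                         B = 200, recalibrate = TRUE, seed = 1) {
  if (B < 40) stop("B must be at least 40")
  structure(list(n_derivation = n_derivation, n_validation = n_validation,
                 n_registry = n_registry, truth = truth,
                 registry_shift = registry_shift, missingness = missingness,
                 original_spec = original_spec, updated_spec = updated_spec,
                 B = B, recalibrate = recalibrate, seed = seed),
            class = "study_config")
}

#' Run the full modelling study
#'
#' Executes, in order: (1) generate the derivation trial and fit the
#' original model configuration; (2) generate the validation trial and
#' compute its validation report, benefit-quintile calibration and
#' c-for-benefit; (3) on the combined trials, likelihood-ratio tests for
#' adding the glucose term and for dropping prior stroke; (4) refit the
#' updated configuration on the combined trials with a
#' derivation-vs-validation cohort adjustment; (5) generate the registry,
#' validate the updated model there (predictions use the validation
#' cohort's baseline level), tabulate the three-class reperfusion-surrogate
#' benefit contrast and its c-for-benefit, and optionally recalibrate the
#' intercept.  Cohorts with configured missingness pass through MCAR
#' injection and imputation first.  Every stage seed derives from the
#' master seed; rerunning with the same config is bit-identical.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, all artifacts (cohort
#'   CSVs, model JSONs, validation CSV/JSONs, benefit tables, pair tables,
#'   and a `study.json` bundle) are written there.
#' @return object of class `mrs_study`: list of all stage results.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  ms <- config$seed
  prep <- function(data, stage) {
    if (!is.null(config$missingness)) {
      data <- inject_missingness(data, config$missingness,
                                 seed = stage_seed(ms, stage))
      data <- impute_cohort(data)
    }
    data
  }

  # stage 1: derivation fit
  deriv <- generate_cohort(cohort_spec(
    n = config$n_derivation, design = "rct", truth = config$truth,
    label = "derivation", seed = stage_seed(ms, "derivation")))
  fit_orig <- fit_mrs_model(deriv, config$original_spec)

  # stage 2: first external validation
  valid <- generate_cohort(cohort_spec(
    n = config$n_validation, design = "rct", truth = config$truth,
    label = "validation", seed = stage_seed(ms, "validation")))
  valid <- prep(valid, "missing_validation")
  val1 <- validate_model(fit_orig, valid, B = config$B,
                         seed = stage_seed(ms, "boot_validation"))
  ben1 <- predicted_benefit(fit_orig, valid)$benefit
  quint1 <- benefit_group_table(ben1, valid$evt,
                                as.numeric(valid$mrs_90d <= 2), "quintiles")
  pairs1 <- match_benefit_pairs(ben1, valid$evt,
                                as.numeric(valid$mrs_90d <= 2),
                                seed = stage_seed(ms, "pairs_validation"))
  cfb1 <- c_for_benefit(pairs1)

  # stage 3: model updating on the combined trials
  combined <- rbind(deriv[names(valid)], valid)
  upd_no_cohort <- config$updated_spec
  upd_no_cohort$cohort_adjustment <- FALSE
  reduced_spec <- upd_no_cohort
  reduced_spec$glucose <- NULL
  fit_reduced <- fit_mrs_model(combined, reduced_spec)
  fit_glucose <- fit_mrs_model(combined, upd_no_cohort)
  lr_glucose <- lr_test(fit_glucose, fit_reduced)

  with_ps <- config$original_spec
  with_ps$cohort_adjustment <- FALSE
  fit_with_ps <- fit_mrs_model(combined, with_ps)
  no_ps_spec <- model_spec(main = setdiff(with_ps$main, "prior_stroke"),
                           glucose = with_ps$glucose,
                           interactions = setdiff(with_ps$interactions, "prior_stroke"))
  fit_no_ps <- fit_mrs_model(combined, no_ps_spec)
  lr_prior_stroke <- lr_test(fit_with_ps, fit_no_ps)

  # stage 4: cohort-adjusted refit of the updated configuration
  fit_updated <- refit_with_cohort_adjustment(combined, config$updated_spec)

  # stage 5: registry validation of the updated model
  reg_truth <- config$truth
  reg_truth$cutpoints <- reg_truth$cutpoints + config$registry_shift
  registry <- generate_cohort(cohort_spec(
    n = config$n_registry, design = "registry", truth = reg_truth,
    label = "registry", seed = stage_seed(ms, "registry")))
  registry <- prep(registry, "missing_registry")
  # predictions in the registry use the validation cohort's baseline level
  registry$cohort <- "validation"
  val2 <- validate_model(fit_updated, registry, B = config$B,
                         seed = stage_seed(ms, "boot_registry"))
  ben2 <- predicted_benefit(fit_updated, registry)$benefit
  classes2 <- benefit_group_table(ben2, registry$etici_success,
                                  as.numeric(registry$mrs_90d <= 2),
                                  "classes", surrogate = TRUE)
  pairs2 <- match_benefit_pairs(ben2, registry$etici_success,
                                as.numeric(registry$mrs_90d <= 2),
                                seed = stage_seed(ms, "pairs_registry"))
  cfb2 <- c_for_benefit(pairs2)
  recal <- if (config$recalibrate) recalibrate_intercepts(fit_updated, registry)

  out <- structure(list(
    config = config,
    fit_original = fit_orig,
    validation_trial = val1,
    benefit_quintiles_trial = quint1,
    c_for_benefit_trial = cfb1,
    pairs_trial = pairs1,
    lr_glucose = lr_glucose,
    lr_prior_stroke = lr_prior_stroke,
    fit_updated = fit_updated,
    validation_registry = val2,
    benefit_classes_registry = classes2,
    c_for_benefit_registry = cfb2,
    pairs_registry = pairs2,
    median_benefit_registry = median(ben2),
    recalibration = if (config$recalibrate) recal$recalibration,
    cohorts = list(derivation = deriv, validation = valid, registry = registry)
  ), class = "mrs_study")
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

#' @export
print.mrs_study <- function(x, digits = 3, ...) {
  cat("== Derivation fit (original configuration) ==\n")
  print(x$fit_original, digits = digits)
  cat("\n== First external validation (trial cohort) ==\n")
  print(x$validation_trial, digits = digits)
  cat("  c-for-benefit:", round(x$c_for_benefit_trial, digits), "\n")
  cat("\n== Model updating ==\n")
  cat("  LR test, adding glucose:    X2 =",
      round(x$lr_glucose$statistic, 2), " p =",
      signif(x$lr_glucose$p.value, 3), "\n")
  cat("  LR test, dropping prior stroke: X2 =",
      round(x$lr_prior_stroke$statistic, 2), " p =",
      signif(x$lr_prior_stroke$p.value, 3), "\n")
  cat("\n== Second validation (registry, reperfusion surrogate) ==\n")
  print(x$validation_registry, digits = digits)
  cat("  c-for-benefit (surrogate):", round(x$c_for_benefit_registry, digits), "\n")
  cat("  median predicted benefit:",
      sprintf("%.1f%%", 100 * x$median_benefit_registry), "\n")
  if (!is.null(x$recalibration))
    cat("  intercept recalibration delta:",
        round(x$recalibration$delta, digits), "\n")
  invisible(x)
}

#' Write all study artifacts to a directory
#'
#' @param study an `mrs_study`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  for (nm in names(study$cohorts))
    write_cohort(study$cohorts[[nm]], p(paste0("cohort_", nm, ".csv")))
  write_model(study$fit_original, p("model_original.json"))
  write_model(study$fit_updated, p("model_updated.json"))
  write_validation_csv(study$validation_trial, p("validation_trial.csv"))
  write_validation_json(study$validation_trial, p("validation_trial.json"))
  write_validation_csv(study$validation_registry, p("validation_registry.csv"))
  write_validation_json(study$validation_registry, p("validation_registry.json"))
  write.csv(as.data.frame(study$benefit_quintiles_trial),
            p("benefit_quintiles_trial.csv"), row.names = FALSE)
  write.csv(as.data.frame(study$benefit_classes_registry),
            p("benefit_classes_registry.csv"), row.names = FALSE)
  write.csv(study$pairs_trial, p("pairs_trial.csv"), row.names = FALSE)
  write.csv(study$pairs_registry, p("pairs_registry.csv"), row.names = FALSE)
  summ <- list(
    seed = study$config$seed,
    n = list(derivation = study$config$n_derivation,
             validation = study$config$n_validation,
             registry = study$config$n_registry),
    B = study$config$B,
    lr_glucose = list(statistic = unname(study$lr_glucose$statistic),
                      df = unname(study$lr_glucose$parameter),
                      p = study$lr_glucose$p.value),
    lr_prior_stroke = list(statistic = unname(study$lr_prior_stroke$statistic),
                           df = unname(study$lr_prior_stroke$parameter),
                           p = study$lr_prior_stroke$p.value),
    c_for_benefit_trial = study$c_for_benefit_trial,
    c_for_benefit_registry = study$c_for_benefit_registry,
    median_benefit_registry = study$median_benefit_registry,
    recalibration_delta = if (!is.null(study$recalibration))
      study$recalibration$delta
  )
  jsonlite::write_json(summ, p("study.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}
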