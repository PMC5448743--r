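# End-to-end pipeline: QC -> reference selection -> quantification ->
# marker discovery -> (validation) -> risk model -> incremental value.

#' Pipeline configuration
#'
#' Collects the tunable thresholds of the full analysis. Defaults follow the
#' study protocol the package implements: hemolysis absorbance cutoff 0.2 at
#' 415 nm, 40-cycle detection limit, reference fold-change window 0.9--1.1,
#' marker fold-change window outside 0.5--2.0, and 0.05 significance levels
#' for the reference t-test, marker t-test, discriminant entry and logistic
#' entry.
#'
#' @param hemolysis_threshold absorbance cutoff at 415 nm.
#' @param max_cycles detection limit / undetermined replacement value.
#' @param ref_fold_bounds closed fold-change interval for reference
#'   candidates.
#' @param ref_alpha reference-candidate t-test level (candidates need
#'   p > `ref_alpha`).
#' @param marker_fold_bounds excluded central fold-change interval for
#'   differential candidates.
#' @param marker_alpha differential t-test level.
#' @param alpha_discriminant stepwise discriminant entry level.
#' @param alpha_logistic forward logistic entry level.
#' @param class_threshold classification probability threshold.
#' @param max_pair_candidates cap on the number of top single candidates
#'   whose pairs are scored for stability (bounds the pair search).
#' @param clinical_covariates clinical covariate names offered to the
#'   forward logistic model.
#' @param seed RNG seed recorded in the run report.
#' @param out_dir optional output directory for per-stage artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(hemolysis_threshold = 0.2, max_cycles = 40,
                            ref_fold_bounds = c(0.9, 1.1), ref_alpha = 0.05,
                            marker_fold_bounds = c(0.5, 2),
                            marker_alpha = 0.05,
                            alpha_discriminant = 0.05, alpha_logistic = 0.05,
                            class_threshold = 0.5, max_pair_candidates = 20,
                            clinical_covariates = c(
                              "age", "bmi", "hypertension", "hba1c",
                              "fasting_glucose", "triglyceride",
                              "total_cholesterol", "hdl_c", "ldl_c",
                              "apolipoprotein_a", "apolipoprotein_b",
                              "lipoprotein_a", "hs_crp", "homocysteine"),
                            seed = 1, out_dir = NULL) {
  alphas <- c(ref_alpha, marker_alpha, alpha_discriminant, alpha_logistic)
  if (any(alphas <= 0 | alphas >= 1))
    stop("all alpha levels must lie in (0, 1)", call. = FALSE)
  if (!(marker_fold_bounds[1L] > 0 && marker_fold_bounds[1L] < 1 &&
        marker_fold_bounds[2L] > 1))
    stop("marker fold bounds must satisfy 0 < lower < 1 < upper",
         call. = FALSE)
  structure(list(hemolysis_threshold = hemolysis_threshold,
                 max_cycles = max_cycles,
                 ref_fold_bounds = ref_fold_bounds, ref_alpha = ref_alpha,
                 marker_fold_bounds = marker_fold_bounds,
                 marker_alpha = marker_alpha,
                 alpha_discriminant = alpha_discriminant,
                 alpha_logistic = alpha_logistic,
                 class_threshold = class_threshold,
                 max_pair_candidates = max_pair_candidates,
                 clinical_covariates = clinical_covariates,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

quantify_cohort <- function(panel, cohort, reference_ids, config) {
  cohort <- hemolysis_filter(cohort, config$hemolysis_threshold)
  panel <- subset_ct_panel(panel, samples = cohort$sample_id)
  panel <- impute_undetermined(panel, config$max_cycles)
  list(panel = panel, cohort = cohort,
       expr = if (!is.null(reference_ids)) delta_ct(panel, reference_ids))
}

#' Run the full discovery-to-incremental-value pipeline
#'
#' Executes, in order: hemolysis QC and Ct imputation; reference-candidate
#' filtering and NormFinder-type stability selection of the best single or
#' pair; delta-Ct relative quantification; fold-change/t-test marker
#' filtering and forward stepwise discriminant reduction; optional
#' validation of the discriminant-selected markers in an independent cohort;
#' forward logistic risk modelling over clinical covariates plus marker
#' relative quantities; leave-one-out cross-validation; and incremental
#' value of the marker(s) over the clinical-only model (accuracy metrics,
#' paired AUC comparison, continuous NRI and IDI).
#'
#' The risk-model stages run on the validation cohort when one is given,
#' otherwise on the discovery cohort. The "base" model re-fits the selected
#' clinical covariates only; the "full" model additionally includes the
#' selected marker column(s).
#'
#' @param panel discovery [ct_panel()].
#' @param cohort discovery cohort data frame (`sample_id`, `group`,
#'   `absorbance_415`, clinical covariates).
#' @param config a [pipeline_config()].
#' @param validation_panel,validation_cohort optional independent validation
#'   study measured on (at least) the marker and reference miRNAs.
#' @return Object of class `pipeline_report` (nested list of per-stage
#'   results); written to `config$out_dir` as JSON/CSV when set.
#' @export
run_pipeline <- function(panel, cohort, config = pipeline_config(),
                         validation_panel = NULL, validation_cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("sample_id", "group", "absorbance_415", config$clinical_covariates)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  qc <- pipeline_stage("qc", quantify_cohort(panel, cohort, NULL, config))
  panel_i <- qc$panel
  cohort_f <- qc$cohort
  labels <- cohort_f$group

  candidates <- pipeline_stage("reference_candidates",
    candidate_reference_filter(panel_i, labels, config$ref_fold_bounds,
                               config$ref_alpha))
  if (length(candidates) < 3L)
    stop("pipeline stage 'reference_candidates' failed: fewer than 3 ",
         "reference candidates pass the criteria", call. = FALSE)
  stab <- pipeline_stage("reference_stability", {
    x <- -panel_i$ct[candidates, , drop = FALSE]
    if (length(candidates) > config$max_pair_candidates) {
      singles <- normfinder_stability(x, labels, pairs = FALSE)
      top <- head(singles$sets$set, config$max_pair_candidates)
      normfinder_stability(x[top, , drop = FALSE], labels, pairs = TRUE)
    } else normfinder_stability(x, labels, pairs = TRUE)
  })
  reference_ids <- best_reference(stab)

  expr <- pipeline_stage("quantification", delta_ct(panel_i, reference_ids))
  markers <- pipeline_stage("marker_filter",
    differential_candidates(expr, labels, config$marker_fold_bounds,
                            config$marker_alpha))
  passed <- markers$mirna[markers$passed_filter]
  disc <- if (length(passed)) pipeline_stage("discriminant",
    stepwise_discriminant(t(expr$q_rel[passed, , drop = FALSE]), labels,
                          config$alpha_discriminant))
  else list(selected = character(0), steps = NULL)
  putative <- disc$selected

  validation <- NULL
  model_cohort <- cohort_f
  model_expr <- expr
  if (!is.null(validation_panel)) {
    if (is.null(validation_cohort))
      stop("a validation panel requires a validation cohort", call. = FALSE)
    vq <- pipeline_stage("validation_quantification",
      quantify_cohort(validation_panel, validation_cohort, reference_ids,
                      config))
    validation <- if (length(putative)) pipeline_stage("validation",
      validate_marker(vq$expr, vq$cohort$group, putative))
    model_cohort <- vq$cohort
    model_expr <- vq$expr
  }
  validated <- if (!is.null(validation))
    validation$mirna[validation$p < config$marker_alpha]
  else putative

  univariate <- pipeline_stage("univariate",
    univariate_tables(model_cohort,
                      covariates = intersect(names(model_cohort),
                                             c(config$clinical_covariates,
                                               "sex_male", "hypertension",
                                               "diabetes", "smoking",
                                               "alcohol"))))

  incremental <- NULL
  fit <- NULL
  loocv <- NULL
  if (length(validated)) {
    mdata <- pipeline_stage("model_data",
      assemble_model_data(model_cohort, model_expr, validated))
    marker_cols <- attr(mdata, "marker_cols")
    fit <- pipeline_stage("forward_logistic",
      forward_logistic(mdata, "group",
                       c(config$clinical_covariates, marker_cols),
                       config$alpha_logistic))
    base_cov <- setdiff(fit$selected, marker_cols)
    mirna_cov <- intersect(fit$selected, marker_cols)
    if (length(base_cov) && length(mirna_cov)) {
      base_fit <- logistic_model(mdata, "group", base_cov)
      full_fit <- logistic_model(mdata, "group", fit$selected)
      y <- mdata$group
      loocv <- list(
        base = loocv_accuracy(mdata, "group", base_cov,
                              config$class_threshold),
        full = loocv_accuracy(mdata, "group", fit$selected,
                              config$class_threshold))
      incremental <- pipeline_stage("incremental_value", list(
        metrics_base = classification_metrics(base_fit$fitted, y,
                                              config$class_threshold),
        metrics_full = classification_metrics(full_fit$fitted, y,
                                              config$class_threshold),
        auc = compare_auc(base_fit$fitted, full_fit$fitted, y),
        reclassification = reclassification_report(
          base_fit$fitted, full_fit$fitted, y, config$class_threshold)))
    }
  }

  report <- structure(list(
    config = config,
    qc = list(n_input = nrow(cohort), n_retained = nrow(cohort_f),
              excluded = attr(cohort_f, "excluded")),
    reference = list(n_candidates = length(candidates),
                     candidates = as.character(candidates),
                     stability = stab$sets,
                     reference_ids = reference_ids),
    markers = list(report = markers, passed_filter = passed,
                   discriminant = disc$steps, putative = putative),
    validation = validation,
    validated = validated,
    univariate = univariate,
    fit = fit,
    loocv = loocv,
    incremental = incremental),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) write_pipeline_report(report, config$out_dir)
  report
}

# Flatten the report into JSON-serialisable pieces with a stable key order.
report_as_json_list <- function(report) {
  cfg <- report$config
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  inc <- report$incremental
  list(
    config = cfg,
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("seromir")),
    qc = report$qc[c("n_input", "n_retained")],
    reference = list(n_candidates = report$reference$n_candidates,
                     reference_ids = report$reference$reference_ids,
                     best_stability = report$reference$stability$stability[1L]),
    markers = list(passed_filter = report$markers$passed_filter,
                   putative = report$markers$putative),
    validated = report$validated,
    model = if (!is.null(report$fit))
      list(selected = report$fit$selected,
           coefficients = report$fit$coefficients),
    loocv = if (!is.null(report$loocv))
      list(base_accuracy = report$loocv$base$accuracy,
           full_accuracy = report$loocv$full$accuracy),
    incremental = if (!is.null(inc))
      list(metrics_base = inc$metrics_base,
           metrics_full = inc$metrics_full,
           auc_base = inc$auc$auc_old, auc_full = inc$auc$auc_new,
           auc_p = inc$auc$p.value,
           nri = inc$reclassification$nri$nri,
           nri_p = inc$reclassification$nri$p.value,
           idi = inc$reclassification$idi$idi,
           idi_p = inc$reclassification$idi$p.value,
           counts = inc$reclassification$counts))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write pipeline artifacts
#'
#' Writes `report.json` (stable key order, including the configuration hash
#' and package version) plus per-stage CSV tables.
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_as_json_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  write.csv(report$markers$report, file.path(out_dir, "marker_report.csv"),
            row.names = FALSE)
  write.csv(report$reference$stability,
            file.path(out_dir, "reference_stability.csv"), row.names = FALSE)
  write.csv(report$univariate, file.path(out_dir, "univariate.csv"),
            row.names = FALSE)
  if (!is.null(report$fit))
    write.csv(report$fit$coefficients,
              file.path(out_dir, "model_coefficients.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat("  QC: ", x$qc$n_retained, "/", x$qc$n_input, " samples retained\n",
      sep = "")
  cat("  reference: ", paste(x$reference$reference_ids, collapse = "/"),
      " (", x$reference$n_candidates, " candidates)\n", sep = "")
  cat("  markers past filter: ", length(x$markers$passed_filter),
      "; discriminant-selected: ", length(x$markers$putative), "\n", sep = "")
  if (!is.null(x$loocv))
    cat(sprintf("  LOOCV accuracy: base %.1f%%, +marker %.1f%%\n",
                x$loocv$base$accuracy, x$loocv$full$accuracy))
  if (!is.null(x$incremental))
    cat(sprintf("  AUC %.4f -> %.4f; NRI %.4f, IDI %.4f\n",
                x$incremental$auc$auc_old, x$incremental$auc$auc_new,
                x$incremental$reclassification$nri$nri,
                x$incremental$reclassification$idi$idi))
  invisible(x)
}
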