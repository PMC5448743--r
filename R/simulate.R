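# Synthetic two-panel serum miRNA study generator with known ground truth.

#' Default clinical covariate specification
#'
#' Group means/SDs for the continuous covariates and group proportions for
#' the categorical ones, matching the characteristics of an elderly ischemic
#' stroke cohort stratified into non-atherosclerotic and atherosclerotic
#' patients (e.g. HbA1c 5.7 +/- 0.7 vs 6.4 +/- 1.1 %, lipoprotein(a)
#' 14.5 +/- 10.4 vs 21.9 +/- 15.7 mg/dl).
#'
#' @return List with elements `continuous` (data frame: `name`, `mean_non`,
#'   `sd_non`, `mean_ath`, `sd_ath`, `lower` truncation bound),
#'   `binary` (data frame: `name`, `p_non`, `p_ath` event-group prevalence)
#'   and `previous_infarction` (per-group category probabilities).
#' @export
default_clinical_spec <- function() {
  continuous <- data.frame(
    name = c("age", "height", "weight", "bmi", "nihss_er", "nihss_discharge",
             "hba1c", "fasting_glucose", "triglyceride", "total_cholesterol",
             "hdl_c", "ldl_c", "apolipoprotein_a", "apolipoprotein_b",
             "lipoprotein_a", "hs_crp", "homocysteine"),
    mean_non = c(69.3, 161.2, 62.8, 24.1, 1.3, 0.7,
                 5.7, 107.5, 120.3, 165.5, 45.1, 102.9, 108.8, 83.8,
                 14.5, 1.0, 9.9),
    sd_non = c(4.9, 9.3, 9.7, 2.2, 1.7, 1.3,
               0.7, 27.5, 55.2, 34.2, 9.0, 32.0, 20.0, 23.1,
               10.4, 1.0, 4.1),
    mean_ath = c(71.4, 160.2, 62.1, 24.1, 1.1, 0.8,
                 6.4, 133.8, 124.9, 162.5, 40.3, 101.2, 101.9, 89.2,
                 21.9, 2.1, 13.2),
    sd_ath = c(5.8, 9.1, 10.2, 3.4, 1.7, 1.3,
               1.1, 54.6, 65.7, 46.8, 12.3, 40.1, 26.1, 29.5,
               15.7, 2.8, 8.9),
    lower = c(40, 120, 30, 14, 0, 0,
              3.5, 40, 20, 60, 10, 20, 30, 20,
              0.1, 0.01, 1),
    stringsAsFactors = FALSE)
  binary <- data.frame(
    name = c("sex_male", "hypertension", "diabetes", "smoking", "alcohol"),
    p_non = c(19 / 33, 15 / 33, 5 / 33, 8 / 33, 3 / 33),
    p_ath = c(19 / 32, 24 / 32, 18 / 32, 6 / 32, 3 / 32),
    stringsAsFactors = FALSE)
  list(continuous = continuous, binary = binary,
       diagnosis_p_tia = c(non = 13 / 33, ath = 11 / 32),
       previous_infarction = list(
         non = c(no = 20 / 33, small = 11 / 33, branch = 2 / 33),
         ath = c(no = 9 / 32, small = 16 / 32, branch = 7 / 32)))
}

#' Simulation parameters for a synthetic serum miRNA study
#'
#' Ct is treated as a negative log2 abundance plus a per-sample offset, so a
#' planted log2 fold change of `f` appears as an additive Ct shift of `-f`
#' in the event group and yields `Q_rel` fold changes of exactly `2^f` in
#' expectation. Planted reference miRNAs have no group effect and low
#' variance; planted differential miRNAs carry `effect_log2fc`; the rest are
#' noise. Wells whose simulated Ct exceeds `dropout_ct` are emitted as
#' undetermined (before imputation).
#'
#' @param n_per_group samples per group (default 8, the scale of a discovery
#'   profiling run).
#' @param n_mirnas total miRNAs across the two panels (default 754).
#' @param n_reference planted stable miRNAs (default 10).
#' @param n_differential planted group-shifted miRNAs (default 14).
#' @param effect_log2fc per-planted-miRNA log2 fold change (event over
#'   non-event; recycled to `n_differential`). Default alternates +2/-2,
#'   i.e. 4-fold up/down shifts.
#' @param ct_base_mean,ct_sd baseline Ct level and within-group Ct SD in
#'   cycles (defaults 30 and 1).
#' @param between_mirna_sd SD of per-miRNA baseline Ct around
#'   `ct_base_mean` (default 3.5 cycles).
#' @param reference_sd within-group Ct SD of planted reference miRNAs
#'   (default 0.2 cycles).
#' @param sample_offset_sd SD of the per-sample global extraction/loading
#'   offset (default 0.5 cycles).
#' @param dropout_ct detection limit; simulated Ct above it becomes
#'   undetermined (default 40).
#' @param clinical_spec covariate group means/SDs and proportions
#'   (default [default_clinical_spec()]).
#' @param hemolysis_fraction fraction of samples drawn above the 0.2
#'   absorbance cutoff at 415 nm (default 0: a pre-screened cohort).
#' @param seed integer RNG seed.
#' @return Object of class `simulation_params`.
#' @export
simulation_params <- function(n_per_group = 8, n_mirnas = 754,
                              n_reference = 10, n_differential = 14,
                              effect_log2fc = NULL,
                              ct_base_mean = 30, ct_sd = 1,
                              between_mirna_sd = 3.5, reference_sd = 0.2,
                              sample_offset_sd = 0.5, dropout_ct = 40,
                              clinical_spec = default_clinical_spec(),
                              hemolysis_fraction = 0, seed = 1) {
  if (n_per_group < 2) stop("`n_per_group` must be >= 2", call. = FALSE)
  if (n_reference + n_differential > n_mirnas)
    stop("n_reference + n_differential must not exceed n_mirnas",
         call. = FALSE)
  if (ct_sd <= 0 || reference_sd <= 0 || between_mirna_sd <= 0 ||
      sample_offset_sd < 0)
    stop("all SDs must be positive", call. = FALSE)
  if (dropout_ct > 40) stop("`dropout_ct` must be <= 40", call. = FALSE)
  if (any(clinical_spec$continuous$sd_non <= 0) ||
      any(clinical_spec$continuous$sd_ath <= 0))
    stop("clinical covariate SDs must be positive", call. = FALSE)
  if (hemolysis_fraction < 0 || hemolysis_fraction >= 1)
    stop("`hemolysis_fraction` must be in [0, 1)", call. = FALSE)
  effect_log2fc <- effect_log2fc %||% rep(c(2, -2), length.out = n_differential)
  effect_log2fc <- rep(effect_log2fc, length.out = n_differential)
  structure(list(n_per_group = as.integer(n_per_group),
                 n_mirnas = as.integer(n_mirnas),
                 n_reference = as.integer(n_reference),
                 n_differential = as.integer(n_differential),
                 effect_log2fc = effect_log2fc,
                 ct_base_mean = ct_base_mean, ct_sd = ct_sd,
                 between_mirna_sd = between_mirna_sd,
                 reference_sd = reference_sd,
                 sample_offset_sd = sample_offset_sd,
                 dropout_ct = dropout_ct,
                 clinical_spec = clinical_spec,
                 hemolysis_fraction = hemolysis_fraction,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

rnorm_trunc <- function(n, mean, sd, lower) pmax(rnorm(n, mean, sd), lower)

#' Simulate a two-panel serum miRNA study with known ground truth
#'
#' Generates a miRNA-by-sample Ct panel (with planted stable reference
#' miRNAs, planted differential miRNAs, noise miRNAs, per-sample offsets and
#' dropout above the detection limit), a per-patient clinical table drawn
#' from the covariate specification, and the planted truth. Deterministic
#' given `params$seed`; the caller's RNG state is preserved.
#'
#' @param params a [simulation_params()] object.
#' @return List with elements `panel` (a [ct_panel()], undetermined wells as
#'   `NA`), `cohort` (data frame with `sample_id`, `group`,
#'   `absorbance_415` and the clinical covariates) and `truth` (list:
#'   `reference_ids`, `differential_ids`, `log2fc` named per differential
#'   miRNA, `clinical_effects` = true event-minus-nonevent mean differences).
#' @examples
#' sim <- simulate_cohort(simulation_params(n_per_group = 4, n_mirnas = 50,
#'                                          seed = 7))
#' dim(sim$panel$ct)  # 50 x 8
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  with_preserved_seed(params$seed, {
    n_g <- params$n_per_group
    n <- 2L * n_g
    m <- params$n_mirnas
    mirna_ids <- sprintf("miR-sim-%04d", seq_len(m))
    sample_ids <- sprintf("P%03d", seq_len(n))
    group <- factor(rep(c("non_atherosclerotic", "atherosclerotic"),
                        each = n_g),
                    levels = c("non_atherosclerotic", "atherosclerotic"))
    ref_idx <- seq_len(params$n_reference)
    diff_idx <- params$n_reference + seq_len(params$n_differential)

    mu <- rnorm(m, params$ct_base_mean, params$between_mirna_sd)
    # keep planted miRNAs comfortably inside the detection range
    mu[ref_idx] <- runif(length(ref_idx),
                         params$ct_base_mean - 6, params$ct_base_mean)
    mu[diff_idx] <- runif(length(diff_idx),
                          params$ct_base_mean - 4, params$ct_base_mean + 2)
    sds <- rep(params$ct_sd, m)
    sds[ref_idx] <- params$reference_sd
    shift <- numeric(m)
    shift[diff_idx] <- -params$effect_log2fc  # Ct shift in the event group
    offsets <- rnorm(n, 0, params$sample_offset_sd)

    ct <- mu + matrix(rnorm(m * n), m, n) * sds
    ct <- ct + outer(shift, as.numeric(group == "atherosclerotic"))
    ct <- sweep(ct, 2, offsets, "+")
    ct <- pmax(ct, 5)
    ct[ct > params$dropout_ct] <- NA  # undetermined wells
    dimnames(ct) <- list(mirna_ids, sample_ids)
    panel <- ct_panel(ct)

    spec <- params$clinical_spec
    cohort <- data.frame(sample_id = sample_ids, group = group,
                         stringsAsFactors = FALSE)
    is_ath <- group == "atherosclerotic"
    n_hem <- round(params$hemolysis_fraction * n)
    absorbance <- runif(n, 0.02, 0.18)
    if (n_hem > 0) {
      hem <- sample(n, n_hem)
      absorbance[hem] <- runif(n_hem, 0.20, 0.60)
    }
    cohort$absorbance_415 <- absorbance
    for (i in seq_len(nrow(spec$binary))) {
      b <- spec$binary[i, ]
      cohort[[b$name]] <- factor(
        ifelse(rbinom(n, 1, ifelse(is_ath, b$p_ath, b$p_non)) == 1,
               "yes", "no"),
        levels = c("no", "yes"))
    }
    cohort$diagnosis <- factor(
      ifelse(rbinom(n, 1, ifelse(is_ath, spec$diagnosis_p_tia["ath"],
                                 spec$diagnosis_p_tia["non"])) == 1,
             "tia", "lacune_small"),
      levels = c("tia", "lacune_small"))
    cats <- names(spec$previous_infarction$non)
    prev <- character(n)
    prev[!is_ath] <- sample(cats, sum(!is_ath), replace = TRUE,
                            prob = spec$previous_infarction$non)
    prev[is_ath] <- sample(cats, sum(is_ath), replace = TRUE,
                           prob = spec$previous_infarction$ath)
    cohort$previous_infarction <- factor(prev, levels = cats)
    for (i in seq_len(nrow(spec$continuous))) {
      cc <- spec$continuous[i, ]
      cohort[[cc$name]] <- ifelse(
        is_ath,
        rnorm_trunc(n, cc$mean_ath, cc$sd_ath, cc$lower),
        rnorm_trunc(n, cc$mean_non, cc$sd_non, cc$lower))
    }

    truth <- list(
      reference_ids = mirna_ids[ref_idx],
      differential_ids = mirna_ids[diff_idx],
      log2fc = setNames(params$effect_log2fc, mirna_ids[diff_idx]),
      clinical_effects = setNames(
        spec$continuous$mean_ath - spec$continuous$mean_non,
        spec$continuous$name))
    stopifnot(!anyDuplicated(c(truth$reference_ids, truth$differential_ids)))
    list(panel = panel, cohort = cohort, truth = truth)
  })
}

#' Write a simulated study to disk
#'
#' Writes the Ct panel as a wide CSV (`ct_panel.csv`, undetermined wells as
#' `"Undetermined"`), the cohort table as `cohort.csv` and the planted truth
#' as `truth.json`.
#'
#' @param sim a [simulate_cohort()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ct_wide(sim$panel, file.path(out_dir, "ct_panel.csv"))
  write.csv(sim$cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
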