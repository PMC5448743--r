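# Cohort-level univariate statistics, forward logistic regression and LOOCV.

summarise_continuous <- function(x) {
  sprintf("%.1f ± %.1f", mean(x), sd(x))
}

#' Univariate group comparisons of clinical covariates
#'
#' Categorical covariates (factor, character or logical columns) are compared
#' with a chi-squared test on the contingency table; continuous covariates
#' with a two-sided equal-variance Student's t-test. Chi-squared results with
#' an expected cell count below 5 or a zero table margin are flagged as
#' unreliable.
#'
#' @param cohort data frame with a `group` column (two levels) and the
#'   covariates in `covariates`.
#' @param covariates column names to compare; defaults to every column except
#'   `sample_id`, `group` and `absorbance_415`.
#' @param group_col name of the group column.
#' @return Data frame with one row per covariate: `type`, group summaries
#'   (mean +/- SD or counts), `statistic`, `p` and `note`.
#' @export
univariate_tables <- function(cohort, covariates = NULL, group_col = "group") {
  if (!group_col %in% names(cohort))
    stop("cohort is missing the `", group_col, "` column", call. = FALSE)
  g <- as_two_groups(cohort[[group_col]])
  covariates <- covariates %||%
    setdiff(names(cohort), c("sample_id", group_col, "absorbance_415"))
  miss <- setdiff(covariates, names(cohort))
  if (length(miss))
    stop("cohort is missing covariate column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  rows <- lapply(covariates, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      ht <- t.test(x ~ g, var.equal = TRUE)
      data.frame(variable = v, type = "continuous",
                 nonevent = summarise_continuous(x[g == levels(g)[1L]]),
                 event = summarise_continuous(x[g == levels(g)[2L]]),
                 statistic = unname(ht$statistic), p = ht$p.value,
                 note = "", stringsAsFactors = FALSE)
    } else {
      tab <- table(x, g)
      note <- ""
      if (nrow(tab) < 2L || ncol(tab) < 2L ||
          any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        note <- "unreliable: zero margin"
        stat <- NA_real_; p <- NA_real_
      } else {
        ht <- suppressWarnings(chisq.test(tab))
        stat <- unname(ht$statistic); p <- ht$p.value
        if (any(ht$expected < 5)) note <- "unreliable: expected count < 5"
      }
      cnt <- apply(tab, 2, paste, collapse = ":")
      data.frame(variable = v, type = "categorical",
                 nonevent = cnt[1L], event = cnt[2L],
                 statistic = stat, p = p, note = note,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Expand one covariate to model-matrix columns (dropping the intercept).
covariate_block <- function(data, v) {
  x <- data[[v]]
  if (is.character(x) || is.logical(x)) x <- factor(x)
  mm <- model.matrix(~x, data.frame(x = x))[, -1L, drop = FALSE]
  colnames(mm) <- sub("^x", v, colnames(mm))
  mm
}

fit_logistic <- function(X, y) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  sep <- !fit$converged || any(abs(fit$coefficients) > 15) ||
    all(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  list(fit = fit, separation = sep)
}

#' Forward logistic regression over candidate covariates
#'
#' Forward selection for a binary outcome: at each step, every excluded
#' covariate is tested for addition with a likelihood-ratio test against the
#' current model; the most significant enters if its p-value is below
#' `alpha_enter` (default 0.05), and selection stops when none qualifies. The
#' final model is refit by maximum likelihood and reported with odds ratios
#' `Exp(B)` and Wald 95% confidence intervals `exp(B +/- 1.96 SE)`.
#'
#' Complete separation is flagged (`flags$separation`) and the affected
#' coefficients reported as non-convergent; numerically collinear covariates
#' are skipped with a warning.
#'
#' @param data data frame holding the outcome and candidate covariates.
#' @param outcome name of the binary outcome column (0/1, logical, or a
#'   two-level factor whose second level is the event).
#' @param candidates candidate covariate column names.
#' @param alpha_enter entry significance level for the likelihood-ratio test.
#' @param event_level optional event level of a factor outcome.
#' @return Object of class `risk_model_fit`: `selected` (entry order),
#'   `steps` (per-entry LR chi-squared and p), `coefficients` (data frame
#'   with `B`, `se`, `exp_B`, `ci_lower`, `ci_upper`, `p`), `fitted`
#'   (per-patient probabilities, named by `sample_id` when present),
#'   `deviance`, `null_deviance` and `flags`.
#' @export
forward_logistic <- function(data, outcome, candidates, alpha_enter = 0.05,
                             event_level = NULL) {
  if (!length(candidates)) stop("no candidate covariates", call. = FALSE)
  miss <- setdiff(c(outcome, candidates), names(data))
  if (length(miss))
    stop("data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  y <- event_indicator(data[[outcome]], event_level)
  n <- length(y)
  blocks <- lapply(candidates, covariate_block, data = data)
  names(blocks) <- candidates
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  cur <- fit_logistic(X, y)
  selected <- character(0)
  steps <- data.frame(variable = character(0), lr_chisq = numeric(0),
                      df = integer(0), p_enter = numeric(0),
                      stringsAsFactors = FALSE)
  skipped <- character(0)
  remaining <- candidates
  separation <- FALSE
  while (length(remaining)) {
    trials <- lapply(remaining, function(v) {
      Xv <- cbind(X, blocks[[v]])
      if (qr(Xv)$rank < ncol(Xv)) return(NULL)  # collinear with current model
      fit_logistic(Xv, y)
    })
    ok <- !vapply(trials, is.null, logical(1L))
    if (any(!ok)) {
      warning("skipping collinear covariate(s): ",
              paste(remaining[!ok], collapse = ", "), call. = FALSE)
      skipped <- c(skipped, remaining[!ok])
      remaining <- remaining[ok]
      trials <- trials[ok]
      if (!length(remaining)) break
    }
    lr <- vapply(trials, function(tr) cur$fit$deviance - tr$fit$deviance,
                 numeric(1L))
    dfs <- vapply(remaining, function(v) ncol(blocks[[v]]), integer(1L))
    ps <- pchisq(pmax(lr, 0), dfs, lower.tail = FALSE)
    best <- which.min(ps)
    if (ps[best] >= alpha_enter) break
    v <- remaining[best]
    X <- cbind(X, blocks[[v]])
    cur <- trials[[best]]
    separation <- separation || cur$separation
    selected <- c(selected, v)
    steps <- rbind(steps, data.frame(variable = v,
                                     lr_chisq = max(lr[best], 0),
                                     df = dfs[best],
                                     p_enter = ps[best],
                                     stringsAsFactors = FALSE))
    remaining <- remaining[-best]
  }
  if (cur$separation)
    warning("complete or quasi-complete separation detected; ",
            "coefficients are non-convergent", call. = FALSE)
  ctab <- wald_table(cur$fit)
  fitted <- cur$fit$fitted.values
  if ("sample_id" %in% names(data)) names(fitted) <- data$sample_id
  structure(list(selected = selected, steps = steps, coefficients = ctab,
                 fitted = fitted, deviance = cur$fit$deviance,
                 null_deviance = cur$fit$null.deviance,
                 outcome = outcome, data = data,
                 flags = list(separation = separation, skipped = skipped)),
            class = "risk_model_fit")
}

# Wald coefficient table from a glm.fit object.
wald_table <- function(fit) {
  p <- fit$rank
  Qr <- fit$qr
  covmat <- chol2inv(Qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(covmat))
  b <- fit$coefficients[Qr$pivot[seq_len(p)]]
  z <- b / se
  data.frame(term = names(b), B = unname(b), se = se,
             exp_B = exp(unname(b)),
             ci_lower = exp(unname(b) - qnorm(0.975) * se),
             ci_upper = exp(unname(b) + qnorm(0.975) * se),
             p = 2 * pnorm(-abs(z)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.risk_model_fit <- function(x, ...) {
  cat("forward logistic regression: ",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(no covariate entered)", "\n", sep = "")
  tab <- x$coefficients
  tab$exp_B <- signif(tab$exp_B, 4)
  print(tab, row.names = FALSE)
  if (x$flags$separation) cat("  [flag] separation detected\n")
  invisible(x)
}

#' Fit a plain maximum-likelihood logistic model on a fixed covariate set
#'
#' @inheritParams forward_logistic
#' @param covariates covariate column names (no selection is performed).
#' @return A `risk_model_fit` (with empty `steps`).
#' @export
logistic_model <- function(data, outcome, covariates, event_level = NULL) {
  forward_logistic(data, outcome, covariates, alpha_enter = 1 + 1e-9,
                   event_level = event_level)
}

#' Leave-one-out cross-validated classification accuracy
#'
#' For each patient, the logistic coefficients of a fixed covariate set are
#' re-estimated on the remaining n - 1 patients, the held-out probability is
#' predicted, and the patient is classified at `threshold`. The covariate
#' set is not re-selected per fold. Non-convergent folds are flagged with a
#' warning and the last-iterate coefficients are used for prediction.
#'
#' @inheritParams forward_logistic
#' @param covariates fixed covariate column names.
#' @param threshold classification probability threshold (default 0.5).
#' @return List of class `loocv_result`: `accuracy` (percent correct),
#'   `prob` (held-out probabilities), `predicted` (0/1), `y` (observed) and
#'   `n_nonconverged`.
#' @export
loocv_accuracy <- function(data, outcome, covariates, threshold = 0.5,
                           event_level = NULL) {
  y <- event_indicator(data[[outcome]], event_level)
  n <- length(y)
  blocks <- lapply(covariates, covariate_block, data = data)
  X <- cbind("(Intercept)" = rep(1, n), do.call(cbind, blocks))
  prob <- numeric(n)
  bad <- 0L
  for (i in seq_len(n)) {
    fit <- suppressWarnings(glm.fit(X[-i, , drop = FALSE], y[-i],
                                    family = binomial()))
    if (!fit$converged) bad <- bad + 1L
    eta <- drop(X[i, , drop = FALSE] %*% fit$coefficients)
    prob[i] <- 1 / (1 + exp(-eta))
  }
  if (bad > 0L)
    warning(bad, " fold(s) did not converge; last-iterate predictions used",
            call. = FALSE)
  predicted <- as.integer(prob >= threshold)
  structure(list(accuracy = 100 * mean(predicted == y), prob = prob,
                 predicted = predicted, y = y, n_nonconverged = bad),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV accuracy: %.1f%% (n = %d)\n", x$accuracy, length(x$y)))
  invisible(x)
}

#' Join marker relative quantities onto a cohort table
#'
#' Adds one `qrel_<miRNA>` column per marker, matched by `sample_id`.
#'
#' @param cohort data frame with a `sample_id` column.
#' @param expr an [delta_ct()] result covering the cohort's samples.
#' @param marker_ids miRNA ids to pull from `expr$q_rel`.
#' @return `cohort` with the marker columns appended; the new column names
#'   are returned in the `"marker_cols"` attribute.
#' @export
assemble_model_data <- function(cohort, expr, marker_ids) {
  miss <- setdiff(marker_ids, rownames(expr$q_rel))
  if (length(miss))
    stop("marker(s) absent from expression matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  idx <- match(cohort$sample_id, colnames(expr$q_rel))
  if (anyNA(idx))
    stop("expression matrix is missing sample(s): ",
         paste(cohort$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
  cols <- character(0)
  for (m in marker_ids) {
    cn <- paste0("qrel_", gsub("[^A-Za-z0-9]+", "_", m))
    cohort[[cn]] <- expr$q_rel[m, idx]
    cols <- c(cols, cn)
  }
  attr(cohort, "marker_cols") <- cols
  cohort
}
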