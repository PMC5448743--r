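#' Differential candidate miRNAs by fold-change and t-test filtering
#'
#' Per miRNA, compares the relative quantity `Q_rel` between the two groups
#' with a two-sided equal-variance Student's t-test and computes the fold
#' change (event-group mean over non-event-group mean). A miRNA passes the
#' filter when its fold change lies outside `[fold_bounds[1], fold_bounds[2]]`
#' (default outside 0.5--2.0) and its p-value is below `alpha`. miRNAs whose
#' non-event group mean is zero have an undefined fold change and are
#' excluded with a warning.
#'
#' @param expr an [delta_ct()] result (or a list with a `q_rel` matrix,
#'   miRNAs in rows).
#' @param labels two-level group label per sample; the second level (or
#'   `event_level`) is the event (atherosclerotic) group.
#' @param fold_bounds the excluded central fold-change interval.
#' @param alpha t-test significance threshold.
#' @param event_level optional name of the event group level.
#' @return A `marker_report` data frame: per-miRNA group means and SDs of
#'   `Q_rel`, `fold`, `p`, and `passed_filter`.
#' @export
differential_candidates <- function(expr, labels, fold_bounds = c(0.5, 2),
                                    alpha = 0.05, event_level = NULL) {
  q <- expr$q_rel
  if (is.null(q)) stop("`expr` must carry a `q_rel` matrix", call. = FALSE)
  g <- as_two_groups(labels, event_level)
  tt <- row_t_test(q, g)
  fold <- tt$mean2 / tt$mean1
  undef <- tt$mean1 == 0
  if (any(undef)) {
    warning("fold change undefined (zero non-event mean) for: ",
            paste(rownames(q)[undef], collapse = ", "), call. = FALSE)
    fold[undef] <- NA_real_
  }
  passed <- !is.na(fold) &
    (fold < fold_bounds[1L] | fold > fold_bounds[2L]) & tt$p < alpha
  out <- data.frame(mirna = rownames(q),
                    mean_nonevent = tt$mean1, sd_nonevent = tt$sd1,
                    mean_event = tt$mean2, sd_event = tt$sd2,
                    fold = fold, t = tt$t, p = tt$p,
                    passed_filter = passed,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("marker_report", "data.frame")
  out
}

# Wilks' lambda for the variable set `cols` of centred data. Returns NA when
# the total scatter matrix is numerically singular.
wilks_lambda <- function(xw, xt, cols) {
  W <- crossprod(xw[, cols, drop = FALSE])
  Tm <- crossprod(xt[, cols, drop = FALSE])
  dt <- determinant(Tm, logarithm = TRUE)
  if (!is.finite(dt$modulus) ||
      rcond_est(Tm) < 1e-12) return(NA_real_)
  dw <- determinant(W, logarithm = TRUE)
  exp(as.numeric(dw$modulus - dt$modulus))
}

rcond_est <- function(m) {
  if (nrow(m) == 1L) return(if (m[1L] > 0) 1 else 0)
  ev <- tryCatch(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (is.null(ev) || any(!is.finite(ev))) return(0)
  if (max(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' Forward stepwise linear discriminant analysis
#'
#' Selects variables that discriminate two groups by forward inclusion on the
#' partial Wilks' lambda F statistic. At each step, every excluded variable's
#' F-to-enter given the already-entered set is computed,
#' `F = (n - g - p) / (g - 1) * (lambda_p / lambda_(p+1) - 1)` with `g = 2`
#' groups and `p` entered variables, tested against `F(g - 1, n - g - p)`.
#' The largest-F variable enters if its p-value is below `alpha_enter`;
#' selection stops when none qualifies. For the first entered variable, F
#' equals the squared two-sample t statistic.
#'
#' @param x numeric matrix, samples in rows, candidate variables in columns.
#' @param labels two-level group label per sample.
#' @param alpha_enter entry significance level (default 0.05).
#' @return List of class `stepwise_lda`: `selected` (ids in entry order),
#'   `steps` (data frame with `F_enter`, `p_enter` per entered variable) and
#'   `skipped` (variables dropped as numerically collinear).
#' @export
stepwise_discriminant <- function(x, labels, alpha_enter = 0.05) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  if (!ncol(x)) stop("candidate set is empty", call. = FALSE)
  g <- as_two_groups(labels)
  n <- nrow(x)
  if (length(labels) != n)
    stop("`labels` must have one entry per row of `x`", call. = FALSE)
  # centred data for total (grand mean) and within (group means) scatter
  xt <- scale(x, scale = FALSE)
  xw <- x
  for (l in levels(g)) {
    ii <- g == l
    xw[ii, ] <- scale(x[ii, , drop = FALSE], scale = FALSE)
  }
  selected <- character(0)
  steps <- data.frame(variable = character(0), step = integer(0),
                      F_enter = numeric(0), p_enter = numeric(0),
                      stringsAsFactors = FALSE)
  skipped <- character(0)
  remaining <- colnames(x)
  lambda_cur <- 1
  repeat {
    p <- length(selected)
    df2 <- n - 2L - p
    if (!length(remaining) || df2 < 1L) break
    Fs <- vapply(remaining, function(v) {
      lam <- wilks_lambda(xw, xt, c(selected, v))
      if (is.na(lam) || lam <= 0) return(NA_real_)
      df2 * (lambda_cur / lam - 1)
    }, numeric(1L))
    bad <- is.na(Fs)
    if (any(bad)) {
      skipped <- c(skipped, remaining[bad])
      if (length(remaining[bad]))
        warning("skipping numerically collinear variable(s): ",
                paste(remaining[bad], collapse = ", "), call. = FALSE)
      remaining <- remaining[!bad]
      Fs <- Fs[!bad]
      if (!length(remaining)) break
    }
    best <- which.max(Fs)
    p_best <- pf(Fs[best], 1, df2, lower.tail = FALSE)
    if (p_best >= alpha_enter) break
    v <- remaining[best]
    lambda_cur <- wilks_lambda(xw, xt, c(selected, v))
    selected <- c(selected, v)
    steps <- rbind(steps, data.frame(variable = v, step = p + 1L,
                                     F_enter = as.numeric(Fs[best]),
                                     p_enter = as.numeric(p_best),
                                     stringsAsFactors = FALSE))
    remaining <- remaining[-best]
  }
  structure(list(selected = selected, steps = steps, skipped = skipped),
            class = "stepwise_lda")
}

#' @export
print.stepwise_lda <- function(x, ...) {
  cat("stepwise discriminant analysis: ", length(x$selected),
      " variable(s) entered\n", sep = "")
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Validate putative marker miRNAs in an independent cohort
#'
#' Per marker, compares `Q_rel` between the two groups of the validation
#' cohort with a two-sided equal-variance Student's t-test.
#'
#' @param expr an [delta_ct()] result for the validation cohort.
#' @param labels two-level group label per validation sample.
#' @param marker_ids miRNA ids to validate; all must be present in `expr`.
#' @param event_level optional name of the event group level.
#' @return Data frame with per-marker group means and SDs of `Q_rel` and the
#'   t-test p-value.
#' @export
validate_marker <- function(expr, labels, marker_ids, event_level = NULL) {
  q <- expr$q_rel
  miss <- setdiff(marker_ids, rownames(q))
  if (length(miss))
    stop("marker(s) absent from validation matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  g <- as_two_groups(labels, event_level)
  tt <- row_t_test(q[marker_ids, , drop = FALSE], g)
  data.frame(mirna = marker_ids,
             mean_nonevent = tt$mean1, sd_nonevent = tt$sd1,
             mean_event = tt$mean2, sd_event = tt$sd2,
             t = tt$t, p = tt$p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare marker expression across clinical subgroups
#'
#' Two categories are compared with a two-sided equal-variance Student's
#' t-test; three or more with a one-way ANOVA.
#'
#' @param values numeric vector of per-sample expression (e.g. one miRNA's
#'   `Q_rel`).
#' @param categories category label per sample; every category needs at least
#'   2 samples.
#' @return List with `method`, `statistic` (t or F), `df`, `p.value`, and
#'   per-category `means`.
#' @export
subgroup_comparison <- function(values, categories) {
  f <- factor(categories)
  if (nlevels(f) < 2L) stop("need at least 2 categories", call. = FALSE)
  cnt <- table(f)
  if (any(cnt < 2L))
    stop("category with fewer than 2 samples: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "), call. = FALSE)
  means <- tapply(values, f, mean)
  if (nlevels(f) == 2L) {
    ht <- t.test(values ~ f, var.equal = TRUE)
    list(method = "t", statistic = unname(ht$statistic),
         df = unname(ht$parameter), p.value = ht$p.value, means = means)
  } else {
    fit <- anova(lm(values ~ f))
    list(method = "anova", statistic = fit$`F value`[1L],
         df = fit$Df, p.value = fit$`Pr(>F)`[1L], means = means)
  }
}
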