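# Discrimination and reclassification metrics for nested risk models.

#' Confusion-matrix metrics at a probability threshold
#'
#' Classifies each patient as an event when the predicted probability is at
#' least `threshold` and reports sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and accuracy `(TP+TN)/n`, each in percent.
#'
#' @param probs predicted event probabilities in `[0, 1]`.
#' @param labels event indicator (0/1, logical, or a two-level factor whose
#'   second level is the event).
#' @param threshold classification threshold (default 0.5).
#' @param event_level optional event level of a factor `labels`.
#' @return One-row data frame: `sensitivity`, `specificity`, `accuracy`
#'   (percent), and the counts `tp`, `fp`, `tn`, `fn`.
#' @export
classification_metrics <- function(probs, labels, threshold = 0.5,
                                   event_level = NULL) {
  y <- event_indicator(labels, event_level)
  if (length(probs) != length(y))
    stop("`probs` and `labels` lengths differ", call. = FALSE)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (all(y == 1L) || all(y == 0L))
    stop("both classes must be present", call. = FALSE)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & y == 1L); fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L); fp <- sum(pred == 1L & y == 0L)
  data.frame(sensitivity = 100 * tp / (tp + fn),
             specificity = 100 * tn / (tn + fp),
             accuracy = 100 * (tp + tn) / length(y),
             tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic, the probability that a randomly
#' chosen event outscores a randomly chosen nonevent, counting ties as one
#' half; this equals the trapezoidal area under the empirical ROC curve.
#'
#' @inheritParams classification_metrics
#' @param scores numeric risk scores (higher = more event-like).
#' @return AUC in `[0, 1]`. Constant scores give 0.5 with a warning.
#' @export
roc_auc <- function(scores, labels, event_level = NULL) {
  y <- event_indicator(labels, event_level)
  if (length(scores) != length(y))
    stop("`scores` and `labels` lengths differ", call. = FALSE)
  if (all(y == 1L) || all(y == 0L))
    stop("both classes must be present", call. = FALSE)
  if (length(unique(scores)) == 1L) {
    warning("constant scores: AUC is degenerate (0.5)", call. = FALSE)
    return(0.5)
  }
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: for each event, the fraction of nonevents it
# outscores (ties = 1/2), and vice versa.
delong_placements <- function(scores, y) {
  xs <- scores[y == 1L]
  ys <- scores[y == 0L]
  v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), numeric(1L))
  v01 <- vapply(ys, function(x) mean((xs > x) + 0.5 * (xs == x)), numeric(1L))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired comparison of two AUCs (DeLong test)
#'
#' Compares the AUCs of two risk scores measured on the same patients using
#' the DeLong covariance estimate for paired ROC curves; two-sided p from the
#' asymptotic normal distribution of the AUC difference.
#'
#' @inheritParams classification_metrics
#' @param scores_old,scores_new the two paired score vectors.
#' @return List: `auc_old`, `auc_new`, `diff` (`new - old`), `se`, `z`,
#'   `p.value`.
#' @export
compare_auc <- function(scores_old, scores_new, labels, event_level = NULL) {
  y <- event_indicator(labels, event_level)
  if (length(scores_old) != length(y) || length(scores_new) != length(y))
    stop("score vectors and labels must have equal length", call. = FALSE)
  if (all(y == 1L) || all(y == 0L))
    stop("both classes must be present", call. = FALSE)
  p1 <- delong_placements(scores_old, y)
  p2 <- delong_placements(scores_new, y)
  m <- sum(y == 1L); n <- sum(y == 0L)
  s10 <- var(cbind(p1$v10, p2$v10))
  s01 <- var(cbind(p1$v01, p2$v01))
  v <- (s10[1L, 1L] + s10[2L, 2L] - 2 * s10[1L, 2L]) / m +
       (s01[1L, 1L] + s01[2L, 2L] - 2 * s01[1L, 2L]) / n
  d <- p2$auc - p1$auc
  if (v <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else z <- d / sqrt(v)
  list(auc_old = p1$auc, auc_new = p2$auc, diff = d,
       se = sqrt(max(v, 0)), z = z,
       p.value = if (d == 0) 1 else 2 * pnorm(-abs(z)))
}

check_paired_probs <- function(probs_old, probs_new, labels, event_level) {
  y <- event_indicator(labels, event_level)
  if (length(probs_old) != length(y) || length(probs_new) != length(y))
    stop("probability vectors and labels must have equal length",
         call. = FALSE)
  if (!sum(y == 1L) || !sum(y == 0L))
    stop("need at least one event and one nonevent", call. = FALSE)
  y
}

#' Continuous (category-free) net reclassification improvement
#'
#' Each patient's movement under the new model is scored +1 for any increase
#' in predicted probability, -1 for any decrease and 0 for no change. The
#' NRI is the mean movement among events minus the mean movement among
#' nonevents, giving a value in `[-2, 2]`. Significance uses the asymptotic
#' z statistic `NRI / sqrt((up_e + down_e)/N_e^2 + (up_ne + down_ne)/N_ne^2)`.
#'
#' @inheritParams classification_metrics
#' @param probs_old,probs_new paired predicted probabilities per patient
#'   under the old and new model.
#' @return List: `nri`, `se`, `z`, `p.value` and `components` (movement
#'   counts per class).
#' @export
nri <- function(probs_old, probs_new, labels, event_level = NULL) {
  y <- check_paired_probs(probs_old, probs_new, labels, event_level)
  mv <- sign(probs_new - probs_old)
  ne <- sum(y == 1L); nn <- sum(y == 0L)
  up_e <- sum(mv == 1 & y == 1L); down_e <- sum(mv == -1 & y == 1L)
  up_n <- sum(mv == 1 & y == 0L); down_n <- sum(mv == -1 & y == 0L)
  est <- (up_e - down_e) / ne - (up_n - down_n) / nn
  se <- sqrt((up_e + down_e) / ne^2 + (up_n + down_n) / nn^2)
  z <- if (se == 0) 0 else est / se
  list(nri = est, se = se, z = z,
       p.value = if (est == 0) 1 else 2 * pnorm(-abs(z)),
       components = list(up_events = up_e, down_events = down_e,
                         up_nonevents = up_n, down_nonevents = down_n,
                         n_events = ne, n_nonevents = nn))
}

#' Integrated discrimination improvement
#'
#' The IDI is the change in discrimination slope between the models:
#' `(mean new-model probability among events - among nonevents)` minus the
#' same gap for the old model. Significance uses the asymptotic z statistic
#' with standard errors of the per-class mean probability changes.
#'
#' @inheritParams nri
#' @return List: `idi`, `se`, `z`, `p.value` and `components` (the four mean
#'   predicted probabilities).
#' @export
idi <- function(probs_old, probs_new, labels, event_level = NULL) {
  y <- check_paired_probs(probs_old, probs_new, labels, event_level)
  d <- probs_new - probs_old
  de <- d[y == 1L]; dn <- d[y == 0L]
  est <- mean(de) - mean(dn)
  se_e <- if (length(de) > 1L) sd(de) / sqrt(length(de)) else 0
  se_n <- if (length(dn) > 1L) sd(dn) / sqrt(length(dn)) else 0
  se <- sqrt(se_e^2 + se_n^2)
  z <- if (se == 0) 0 else est / se
  list(idi = est, se = se, z = z,
       p.value = if (est == 0) 1 else 2 * pnorm(-abs(z)),
       components = list(
         mean_new_events = mean(probs_new[y == 1L]),
         mean_old_events = mean(probs_old[y == 1L]),
         mean_new_nonevents = mean(probs_new[y == 0L]),
         mean_old_nonevents = mean(probs_old[y == 0L])))
}

#' Threshold-based reclassification counts
#'
#' Cross-tabulates, per class, how patients misclassified or correctly
#' classified by the old model (at `threshold`) are classified by the new
#' model. These counts describe threshold reclassification and are reported
#' separately from the continuous NRI.
#'
#' @inheritParams nri
#' @param threshold classification threshold (default 0.5).
#' @return List with per-class counts of corrected and newly introduced
#'   misclassifications.
#' @export
reclassification_counts <- function(probs_old, probs_new, labels,
                                    threshold = 0.5, event_level = NULL) {
  y <- check_paired_probs(probs_old, probs_new, labels, event_level)
  old_ok <- as.integer(probs_old >= threshold) == y
  new_ok <- as.integer(probs_new >= threshold) == y
  cnt <- function(cls, was_ok, now_ok)
    sum(y == cls & old_ok == was_ok & new_ok == now_ok)
  list(events_corrected = cnt(1L, FALSE, TRUE),
       events_still_misclassified = cnt(1L, FALSE, FALSE),
       events_newly_misclassified = cnt(1L, TRUE, FALSE),
       nonevents_corrected = cnt(0L, FALSE, TRUE),
       nonevents_still_misclassified = cnt(0L, FALSE, FALSE),
       nonevents_newly_misclassified = cnt(0L, TRUE, FALSE))
}

#' Combined reclassification report (NRI, IDI, counts)
#'
#' @inheritParams reclassification_counts
#' @param n_boot if positive, adds seeded bootstrap percentile confidence
#'   intervals for NRI and IDI as a cross-check of the asymptotic tests.
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `reclassification_report` combining [nri()],
#'   [idi()] and [reclassification_counts()].
#' @export
reclassification_report <- function(probs_old, probs_new, labels,
                                    threshold = 0.5, event_level = NULL,
                                    n_boot = 0, seed = 1) {
  out <- list(nri = nri(probs_old, probs_new, labels, event_level),
              idi = idi(probs_old, probs_new, labels, event_level),
              counts = reclassification_counts(probs_old, probs_new, labels,
                                               threshold, event_level))
  if (n_boot > 0) {
    y <- event_indicator(labels, event_level)
    out$bootstrap <- with_preserved_seed(seed, {
      stats <- vapply(seq_len(n_boot), function(b) {
        idx <- c(sample(which(y == 1L), replace = TRUE),
                 sample(which(y == 0L), replace = TRUE))
        c(nri(probs_old[idx], probs_new[idx], y[idx])$nri,
          idi(probs_old[idx], probs_new[idx], y[idx])$idi)
      }, numeric(2L))
      list(n_boot = n_boot,
           nri_ci = unname(stats::quantile(stats[1L, ], c(0.025, 0.975))),
           idi_ci = unname(stats::quantile(stats[2L, ], c(0.025, 0.975))))
    })
  }
  class(out) <- "reclassification_report"
  out
}

#' @export
print.reclassification_report <- function(x, ...) {
  cat(sprintf("NRI = %.4f (p = %.3g), IDI = %.4f (p = %.3g)\n",
              x$nri$nri, x$nri$p.value, x$idi$idi, x$idi$p.value))
  invisible(x)
}
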