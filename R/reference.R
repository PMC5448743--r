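#' Candidate reference miRNAs by detection, fold-change and t-test criteria
#'
#' A miRNA qualifies as a reference candidate when it is (1) detected in every
#' sample, (2) shows a mean expression fold change between the two groups
#' within `fold_bounds` (0.9--1.1 by default), and (3) shows no significant
#' group difference (two-sided equal-variance t-test on the log scale,
#' p > `alpha`).
#'
#' Fold changes are computed on globally normalised expression: each sample's
#' Ct is centred on its across-miRNA mean (removing extraction/loading
#' offsets), expression is `2^(-centred Ct)` and the fold change is the ratio
#' of group means (second group over first). A pre-computed per-miRNA fold
#' change can be supplied via `q_fold` instead.
#'
#' @param panel an imputed [ct_panel()].
#' @param labels two-level group label per sample.
#' @param fold_bounds closed interval of acceptable mean fold changes.
#' @param alpha significance level below which a miRNA is rejected
#'   (criterion 3 requires p > `alpha`).
#' @param q_fold optional named per-miRNA mean fold change overriding the
#'   internally computed one.
#' @return Character vector of candidate ids, with a `"report"` attribute: a
#'   data frame of per-miRNA `detected_all`, `fold`, `p` and `candidate`.
#' @export
candidate_reference_filter <- function(panel, labels,
                                       fold_bounds = c(0.9, 1.1),
                                       alpha = 0.05, q_fold = NULL) {
  stopifnot(inherits(panel, "ct_panel"))
  if (anyNA(panel$ct))
    stop("panel contains undetermined wells; run impute_undetermined() first",
         call. = FALSE)
  g <- as_two_groups(labels)
  if (length(labels) != length(panel$sample_ids))
    stop("`labels` must have one entry per sample", call. = FALSE)
  detected_all <- rowSums(panel$detected) == ncol(panel$ct)
  # global-mean normalised log2 expression (negative centred Ct)
  z <- -sweep(panel$ct, 2, colMeans(panel$ct), "-")
  if (is.null(q_fold)) {
    e <- 2^z
    m1 <- rowMeans(e[, g == levels(g)[1L], drop = FALSE])
    m2 <- rowMeans(e[, g == levels(g)[2L], drop = FALSE])
    fold <- m2 / m1
  } else {
    fold <- q_fold[panel$mirna_ids]
  }
  tt <- row_t_test(z, g)
  candidate <- detected_all &
    fold >= fold_bounds[1L] & fold <= fold_bounds[2L] &
    tt$p > alpha
  report <- data.frame(mirna = panel$mirna_ids,
                       detected_all = detected_all,
                       fold = as.numeric(fold),
                       p = tt$p,
                       candidate = candidate,
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(panel$mirna_ids[candidate], report = report)
}

# Bias-corrected within-group variances for sample-centred data: solves
# E[s2_ig] = sigma2_ig (1 - 2/k) + (1/k^2) sum_i' sigma2_i'g for each group,
# clamping negative estimates at zero.
normfinder_correct_var <- function(s2, k) {
  tot <- sum(s2) / (1 - 1 / k)
  pmax(0, (s2 - tot / k^2) / (1 - 2 / k))
}

#' Model-based (NormFinder-type) reference stability over singles and pairs
#'
#' Implements the two-group model-based stability estimator for reference
#' gene selection. Input values must be on a log scale on which expression is
#' additive (for qPCR data, negative Ct). The model decomposes each value
#' into gene, sample and gene-by-group effects; a gene's stability combines
#' the magnitude of its (variance-shrunk) gene-by-group bias `d` with its
#' within-group standard error: `mean over groups of |d| + sqrt(var/n)`.
#' Lower is more stable.
#'
#' Steps: (1) centre each sample across the k candidate genes; (2) compute
#' per gene-by-group means and within-group variances; (3) bias-correct the
#' variances for the centring; (4) shrink the group biases toward zero with
#' an empirical-Bayes factor `gamma^2 / (gamma^2 + var/n)` where `gamma^2` is
#' the between-gene variance of the biases in excess of sampling noise;
#' (5) score each gene, and optionally every unordered candidate pair as a
#' pseudo-gene formed by averaging the two members' centred values.
#'
#' @param x numeric matrix, candidate genes in rows (log scale), samples in
#'   columns; needs at least 3 rows.
#' @param labels two-level group label per sample (at least 2 per group).
#' @param pairs score all unordered pairs as well (default `TRUE`).
#' @return An object of class `stability_report`: list with `candidates`,
#'   `singles` (per-gene data frame with `stability`, bias and variance
#'   components), `sets` (all scored sets, sorted by stability) and
#'   `best_set` (character vector of 1 or 2 ids; ties broken by set name).
#' @references Model-based variance estimation approach for real-time
#'   quantitative PCR normalisation (Andersen, Jensen & Orntoft 2004).
#' @export
normfinder_stability <- function(x, labels, pairs = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix (genes x samples)", call. = FALSE)
  k <- nrow(x)
  if (k < 3L)
    stop("need at least 3 candidate genes (sample-centring is degenerate)",
         call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("gene", seq_len(k))
  g <- as_two_groups(labels)
  n_g <- as.numeric(table(g))
  if (any(n_g < 2L))
    stop("need at least 2 samples per group", call. = FALSE)
  lev <- levels(g)

  z <- sweep(x, 2, colMeans(x))  # sample centring
  grp_idx <- lapply(lev, function(l) which(g == l))
  m <- vapply(grp_idx, function(ii) rowMeans(z[, ii, drop = FALSE]),
              numeric(k))
  s2 <- vapply(grp_idx, function(ii) {
    zz <- z[, ii, drop = FALSE]
    rowSums((zz - rowMeans(zz))^2) / (length(ii) - 1)
  }, numeric(k))
  sig2 <- vapply(seq_along(lev), function(j) normfinder_correct_var(s2[, j], k),
                 numeric(k))
  dhat <- m - rowMeans(m)  # gene-by-group interaction (gene effect removed)
  v <- sweep(sig2, 2, n_g, "/")  # sampling variance of dhat
  gamma2 <- pmax(0, apply(dhat, 2, var) - colMeans(v))
  shrink <- vapply(seq_along(lev), function(j) {
    if (gamma2[j] == 0) rep(0, k) else gamma2[j] / (gamma2[j] + v[, j])
  }, numeric(k))
  dtil <- dhat * shrink
  stab <- rowMeans(abs(dtil) + sqrt(v))

  singles <- data.frame(set = rownames(x),
                        stability = stab,
                        bias = rowMeans(abs(dtil)),
                        se = rowMeans(sqrt(v)),
                        row.names = NULL, stringsAsFactors = FALSE)

  sets <- data.frame(set = singles$set, size = 1L,
                     stability = singles$stability,
                     stringsAsFactors = FALSE)
  if (isTRUE(pairs) && k >= 2L) {
    pr <- utils::combn(rownames(x), 2L)
    pair_stab <- apply(pr, 2L, function(ab) {
      w <- (z[ab[1L], ] + z[ab[2L], ]) / 2
      mw <- vapply(grp_idx, function(ii) mean(w[ii]), numeric(1L))
      s2w <- vapply(grp_idx, function(ii) var(w[ii]), numeric(1L))
      tot <- colSums(s2) / (1 - 1 / k)
      sig2w <- pmax(0, (s2w - tot / k^2) / (1 - 2 / k))
      vw <- sig2w / n_g
      dw <- mw - mean(mw)
      sw <- ifelse(gamma2 == 0, 0, gamma2 / (gamma2 + vw)) * dw
      mean(abs(sw) + sqrt(vw))
    })
    sets <- rbind(sets,
                  data.frame(set = paste(pr[1L, ], pr[2L, ], sep = "/"),
                             size = 2L, stability = pair_stab,
                             stringsAsFactors = FALSE))
  }
  sets <- sets[order(sets$stability, sets$set), , drop = FALSE]
  rownames(sets) <- NULL
  structure(list(candidates = rownames(x), singles = singles, sets = sets,
                 best_set = strsplit(sets$set[1L], "/", fixed = TRUE)[[1L]]),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability_report: ", length(x$candidates), " candidates, ",
      nrow(x$sets), " scored sets\n", sep = "")
  cat("  best set: ", paste(x$best_set, collapse = "/"),
      " (stability ", signif(x$sets$stability[1L], 3), ")\n", sep = "")
  print(head(x$sets, 5))
  invisible(x)
}

#' Reference set with the lowest stability value
#'
#' @param report a [normfinder_stability()] result.
#' @return Character vector of the miRNA ids forming the most stable scored
#'   set (single or pair); ties are broken lexicographically by set name.
#' @export
best_reference <- function(report) {
  stopifnot(inherits(report, "stability_report"))
  if (!length(report$candidates) || !nrow(report$sets))
    stop("no candidate reference sets were scored", call. = FALSE)
  report$best_set
}
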