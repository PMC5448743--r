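#' Hemolysis quality control of serum samples
#'
#' Hemolysed serum is contaminated with red-cell miRNAs, so samples are
#' screened by free-oxyhemoglobin absorbance at 415 nm. Samples are retained
#' only when their absorbance is strictly below the threshold (0.2 by
#' default); samples at or above the threshold, or with a missing absorbance
#' measurement, are excluded.
#'
#' @param cohort data frame with one row per sample, containing at least
#'   `sample_id` and the absorbance column.
#' @param threshold absorbance cutoff at 415 nm (default 0.2); retention is
#'   strict (`absorbance < threshold`).
#' @param absorbance_col name of the absorbance column
#'   (default `"absorbance_415"`).
#' @return The retained rows of `cohort`, with an `"excluded"` attribute: a
#'   data frame of excluded `sample_id`s and the reason
#'   (`"hemolysis"` or `"missing absorbance"`).
#' @examples
#' coh <- data.frame(sample_id = c("a", "b", "c"),
#'                   absorbance_415 = c(0.19, 0.20, 0.25))
#' hemolysis_filter(coh)  # keeps only "a"
#' @export
hemolysis_filter <- function(cohort, threshold = 0.2,
                             absorbance_col = "absorbance_415") {
  if (!is.data.frame(cohort) || !"sample_id" %in% names(cohort))
    stop("`cohort` must be a data frame with a `sample_id` column",
         call. = FALSE)
  if (!absorbance_col %in% names(cohort))
    stop("cohort is missing the absorbance column `", absorbance_col, "`",
         call. = FALSE)
  a <- cohort[[absorbance_col]]
  keep <- !is.na(a) & a < threshold
  reason <- ifelse(is.na(a), "missing absorbance", "hemolysis")
  excluded <- data.frame(sample_id = cohort$sample_id[!keep],
                         absorbance = a[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
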