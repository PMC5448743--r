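#' Cycle-threshold panel
#'
#' Container for a miRNA-by-sample cycle-threshold (Ct) matrix as produced by
#' two-card TaqMan-style array panels. Undetermined wells (no amplification
#' within the run's cycle limit) are stored as `NA` until
#' [impute_undetermined()] replaces them with the maximal cycle number.
#'
#' @param ct numeric matrix of Ct values (rows = miRNAs, columns = samples);
#'   `NA` encodes an undetermined well. Row and column names are required.
#' @param detected optional logical matrix of the same shape; defaults to
#'   `!is.na(ct)`.
#' @param panel_of optional character vector over `c("A", "B")` naming the
#'   array card each miRNA sits on; defaults to an even split.
#'
#' @return An object of class `ct_panel`: a list with elements `ct`,
#'   `detected`, `panel_of`, `mirna_ids`, `sample_ids`.
#' @seealso [impute_undetermined()], [delta_ct()], [read_ct_wide()]
#' @export
ct_panel <- function(ct, detected = NULL, panel_of = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have miRNA row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(ct)))
    stop("duplicated miRNA ids in `ct`", call. = FALSE)
  if (any(ct <= 0, na.rm = TRUE))
    stop("Ct values must be positive cycles", call. = FALSE)
  if (is.null(detected)) detected <- !is.na(ct)
  if (!identical(dim(detected), dim(ct)))
    stop("`detected` must match the shape of `ct`", call. = FALSE)
  dimnames(detected) <- dimnames(ct)
  if (is.null(panel_of)) {
    half <- ceiling(nrow(ct) / 2)
    panel_of <- rep(c("A", "B"), c(half, nrow(ct) - half))
  }
  if (length(panel_of) != nrow(ct) || !all(panel_of %in% c("A", "B")))
    stop("`panel_of` must assign each miRNA to panel \"A\" or \"B\"", call. = FALSE)
  structure(
    list(ct = ct, detected = detected,
         panel_of = setNames(as.character(panel_of), rownames(ct)),
         mirna_ids = rownames(ct), sample_ids = colnames(ct)),
    class = "ct_panel")
}

#' @export
print.ct_panel <- function(x, ...) {
  cat("ct_panel: ", length(x$mirna_ids), " miRNAs x ", length(x$sample_ids),
      " samples (panel A: ", sum(x$panel_of == "A"),
      ", B: ", sum(x$panel_of == "B"), ")\n", sep = "")
  cat("  undetermined wells: ", sum(is.na(x$ct)),
      "; detected: ", sum(x$detected), "\n", sep = "")
  invisible(x)
}

#' Subset a Ct panel by sample and/or miRNA
#'
#' @param panel a [ct_panel()].
#' @param samples,mirnas character vectors of ids to keep (default: all).
#' @return A `ct_panel` restricted to the requested rows/columns.
#' @export
subset_ct_panel <- function(panel, samples = NULL, mirnas = NULL) {
  stopifnot(inherits(panel, "ct_panel"))
  samples <- samples %||% panel$sample_ids
  mirnas <- mirnas %||% panel$mirna_ids
  missing_s <- setdiff(samples, panel$sample_ids)
  missing_m <- setdiff(mirnas, panel$mirna_ids)
  if (length(missing_s)) stop("unknown sample id(s): ",
                              paste(missing_s, collapse = ", "), call. = FALSE)
  if (length(missing_m)) stop("unknown miRNA id(s): ",
                              paste(missing_m, collapse = ", "), call. = FALSE)
  ct_panel(panel$ct[mirnas, samples, drop = FALSE],
           panel$detected[mirnas, samples, drop = FALSE],
           panel$panel_of[mirnas])
}

#' Replace undetermined Ct values with the maximal cycle number
#'
#' Wells whose amplification never crossed the fluorescence threshold carry no
#' Ct; they are replaced by the run's maximal cycle number (40 for a standard
#' 40-cycle protocol) so that downstream delta-Ct arithmetic is defined. A
#' miRNA is considered detected in a sample only when its original Ct was
#' determined and strictly below `max_cycles`.
#'
#' @param panel a [ct_panel()] possibly containing `NA` (undetermined) wells.
#' @param max_cycles positive number of cycles used as the replacement value
#'   and detection limit (default 40).
#' @return A `ct_panel` with no missing entries and consistent `detected`
#'   flags (`detected == FALSE` exactly where the stored Ct equals
#'   `max_cycles`).
#' @export
impute_undetermined <- function(panel, max_cycles = 40) {
  stopifnot(inherits(panel, "ct_panel"))
  if (!is.numeric(max_cycles) || length(max_cycles) != 1L || max_cycles <= 0)
    stop("`max_cycles` must be a single positive number", call. = FALSE)
  ct <- panel$ct
  detected <- panel$detected & !is.na(ct) & (ct < max_cycles)
  ct[!detected] <- max_cycles
  ct_panel(ct, detected, panel$panel_of)
}

#' Relative quantification against a reference miRNA set
#'
#' Computes per-well expression differences relative to a reference set,
#' `delta Ct = Ct(miRNA) - Ct(reference)`, where the reference Ct of a sample
#' is the unweighted arithmetic mean of the reference members' Ct in that
#' sample (equivalent to geometric-mean normalisation on the expression
#' scale), and the relative quantity `Q_rel = 2^(-delta Ct)`.
#'
#' @param panel an imputed [ct_panel()] (no missing entries).
#' @param reference_ids character vector of reference miRNA ids; each must be
#'   detected in every sample.
#' @return An object of class `expression_matrix`: list with `delta_ct` and
#'   `q_rel` matrices (same shape as `panel$ct`), `reference_ids`,
#'   `mirna_ids`, `sample_ids`.
#' @examples
#' ct <- matrix(c(30, 28, 30, 30), 2, 2,
#'              dimnames = list(c("miR-a", "miR-ref"), c("s1", "s2")))
#' ex <- delta_ct(ct_panel(ct), "miR-ref")
#' ex$q_rel["miR-a", ]  # 1 (same Ct) and 1 (same Ct)
#' @export
delta_ct <- function(panel, reference_ids) {
  stopifnot(inherits(panel, "ct_panel"))
  if (anyNA(panel$ct))
    stop("panel contains undetermined wells; run impute_undetermined() first",
         call. = FALSE)
  if (!length(reference_ids))
    stop("`reference_ids` must name at least one miRNA", call. = FALSE)
  missing_ref <- setdiff(reference_ids, panel$mirna_ids)
  if (length(missing_ref))
    stop("reference miRNA(s) not in panel: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  und <- !panel$detected[reference_ids, , drop = FALSE]
  if (any(und)) {
    bad <- reference_ids[rowSums(und) > 0]
    stop("reference miRNA(s) undetected in some samples: ",
         paste(bad, collapse = ", "),
         " (violates the detection-in-all-samples criterion)", call. = FALSE)
  }
  ref_ct <- colMeans(panel$ct[reference_ids, , drop = FALSE])
  dct <- sweep(panel$ct, 2, ref_ct, "-")
  structure(
    list(delta_ct = dct, q_rel = 2^(-dct),
         reference_ids = reference_ids,
         mirna_ids = panel$mirna_ids, sample_ids = panel$sample_ids),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", length(x$mirna_ids), " miRNAs x ",
      length(x$sample_ids), " samples\n", sep = "")
  cat("  reference set: ", paste(x$reference_ids, collapse = " + "), "\n",
      sep = "")
  invisible(x)
}
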