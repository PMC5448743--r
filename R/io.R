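# CSV readers/writers for Ct panels and cohort tables.

parse_ct_token <- function(x) {
  # "Undetermined" (any case) and empty cells encode undetermined wells.
  x <- trimws(as.character(x))
  x[x == "" | tolower(x) == "undetermined" | tolower(x) == "na"] <- NA
  as.numeric(x)
}

#' Read a wide-format Ct matrix
#'
#' Expects a CSV whose first column holds miRNA ids and remaining columns one
#' sample each; undetermined wells may be encoded as empty cells or the token
#' `"Undetermined"` (case-insensitive). Several files (e.g. the two array
#' cards) are row-bound; a `panel_of` assignment can label the cards.
#'
#' @param paths one or more CSV paths, in panel order.
#' @param panel_of optional per-file panel labels (`"A"`/`"B"`, recycled to
#'   the rows of each file); default labels the first file A, the second B.
#' @return A [ct_panel()].
#' @export
read_ct_wide <- function(paths, panel_of = NULL) {
  mats <- lapply(paths, function(p) {
    df <- read.csv(p, check.names = FALSE, colClasses = "character")
    ids <- df[[1L]]
    m <- vapply(df[-1L], parse_ct_token, numeric(nrow(df)))
    m <- matrix(m, nrow = nrow(df),
                dimnames = list(ids, names(df)[-1L]))
    m
  })
  samp <- colnames(mats[[1L]])
  for (m in mats) if (!identical(colnames(m), samp))
    stop("all panel files must share the same sample columns", call. = FALSE)
  ct <- do.call(rbind, mats)
  if (is.null(panel_of)) {
    lab <- if (length(mats) == 2L) c("A", "B") else rep("A", length(mats))
    panel_of <- rep(lab, vapply(mats, nrow, 1L))
  }
  ct_panel(ct, panel_of = panel_of)
}

#' Read a long-format Ct table
#'
#' Expects columns `mirna`, `sample`, `ct` and optionally `panel`;
#' undetermined wells as empty cells or `"Undetermined"`.
#'
#' @param path CSV path.
#' @return A [ct_panel()].
#' @export
read_ct_long <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("mirna", "sample", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("long Ct table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  mirnas <- unique(df$mirna)
  samples <- unique(df$sample)
  ct <- matrix(NA_real_, length(mirnas), length(samples),
               dimnames = list(mirnas, samples))
  ct[cbind(match(df$mirna, mirnas), match(df$sample, samples))] <-
    parse_ct_token(df$ct)
  panel_of <- NULL
  if ("panel" %in% names(df))
    panel_of <- df$panel[match(mirnas, df$mirna)]
  ct_panel(ct, panel_of = panel_of)
}

#' Write a Ct panel as a wide CSV
#'
#' Undetermined wells are written as the token `"Undetermined"`.
#'
#' @param panel a [ct_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_wide <- function(panel, path) {
  stopifnot(inherits(panel, "ct_panel"))
  ch <- matrix(as.character(panel$ct), nrow = nrow(panel$ct),
               dimnames = dimnames(panel$ct))
  ch[is.na(panel$ct)] <- "Undetermined"
  df <- data.frame(mirna = rownames(ch), ch, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-patient cohort table
#'
#' @param path CSV path; must contain `sample_id` and `group` columns.
#' @param group_levels order of the group factor levels, non-event first
#'   (default `c("non_atherosclerotic", "atherosclerotic")`).
#' @return A data frame with `group` as a factor.
#' @export
read_cohort_csv <- function(path,
                            group_levels = c("non_atherosclerotic",
                                             "atherosclerotic")) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "group"), names(df))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (all(df$group %in% group_levels))
    df$group <- factor(df$group, levels = group_levels)
  else df$group <- factor(df$group)
  df
}

#' Read a per-patient cohort table from a spreadsheet
#'
#' Accepts a patient-level XLSX export (one row per patient, clinical and
#' expression columns); requires the `readxl` package.
#'
#' @inheritParams read_cohort_csv
#' @param sheet sheet name or index (default first).
#' @return A data frame with `group` as a factor.
#' @export
read_cohort_xlsx <- function(path, sheet = 1,
                             group_levels = c("non_atherosclerotic",
                                              "atherosclerotic")) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("reading XLSX cohort tables requires the `readxl` package",
         call. = FALSE)
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  miss <- setdiff(c("sample_id", "group"), names(df))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (all(df$group %in% group_levels))
    df$group <- factor(df$group, levels = group_levels)
  else df$group <- factor(df$group)
  df
}

#' Write an expression matrix (delta-Ct and relative quantity) as CSV
#'
#' Writes two wide tables, `<stem>_delta_ct.csv` and `<stem>_qrel.csv`.
#'
#' @param expr an [delta_ct()] result.
#' @param stem output path stem.
#' @return The two paths, invisibly.
#' @export
write_expression_csv <- function(expr, stem) {
  stopifnot(inherits(expr, "expression_matrix"))
  p1 <- paste0(stem, "_delta_ct.csv")
  p2 <- paste0(stem, "_qrel.csv")
  for (z in list(list(expr$delta_ct, p1), list(expr$q_rel, p2))) {
    df <- data.frame(mirna = rownames(z[[1L]]), z[[1L]], check.names = FALSE)
    write.csv(df, z[[2L]], row.names = FALSE, quote = FALSE)
  }
  invisible(c(p1, p2))
}
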