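# Readers/writers for the delimited ROI-measurement table shared by the
# simulator and the analysis pipeline.

ROI_REQUIRED_COLS <- c("roi_id", "condition", "environment",
                       "I_cfp_pre_1", "I_cfp_pre_2",
                       "I_cfp_post_1", "I_cfp_post_2",
                       "I_yfp_pre", "I_yfp_post")

ROI_TABLE_COLS <- c(ROI_REQUIRED_COLS, "ground_truth_E")

#' Write an ROI measurement table
#'
#' Comma-delimited with a header row; the optional `ground_truth_E` column is
#' written when present, with missing values as empty fields.
#'
#' @param rois ROI measurement table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(rois, path) {
  check_roi_table(rois)
  cols <- intersect(ROI_TABLE_COLS, names(rois))
  utils::write.csv(as.data.frame(rois)[, cols], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Read an ROI measurement table
#'
#' Validates the header against the documented schema and every row against
#' the basic invariants (intensities must be non-negative, finite numbers);
#' violations are reported with the offending row and column. An empty
#' `ground_truth_E` field marks externally measured data with no known truth.
#'
#' @param path Path to a comma-delimited ROI table.
#' @return A [tibble::tibble()] in the schema of [render_intensities()];
#'   zero rows for a file holding only the header.
#' @export
read_roi_table <- function(path) {
  if (!file.exists(path)) {
    stop("ROI table not found: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(ROI_REQUIRED_COLS, names(tab))
  if (length(missing)) {
    stop(sprintf("%s: header lacks required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  int_cols <- grep("^I_", ROI_REQUIRED_COLS, value = TRUE)
  for (cc in int_cols) {
    v <- tab[[cc]]
    if (nrow(tab) == 0L) {
      tab[[cc]] <- numeric(0)
      next
    }
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop(sprintf("%s: row %d, column %s: not a number (\"%s\")",
                   path, bad, cc, v[bad]), call. = FALSE)
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      stop(sprintf("%s: row %d, column %s: negative or missing intensity (%s)",
                   path, bad[1], cc, format(v[bad[1]])), call. = FALSE)
    }
  }
  if (!"ground_truth_E" %in% names(tab)) {
    tab$ground_truth_E <- rep(NA_real_, nrow(tab))
  } else {
    tab$ground_truth_E <- suppressWarnings(as.numeric(tab$ground_truth_E))
  }
  tibble::as_tibble(tab[, ROI_TABLE_COLS])
}
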