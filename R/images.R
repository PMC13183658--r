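# Optional rendering of synthetic two-channel pre/post-bleach images.

#' Render an ROI table as synthetic microscopy images
#'
#' Writes small 16-bit TIFF images visualizing an ROI measurement table:
#' one image per channel and timepoint (`cfp_pre`, `cfp_post`, `yfp_pre`,
#' `yfp_post`) in which each ROI appears as a square patch of its measured
#' mean intensity on a dark background, plus an ROI label mask
#' (pixel value = `roi_id`, 0-based pixel coordinates). The rendering is a
#' visual aid; quantification starts from the table, not from pixels.
#'
#' @param rois ROI measurement table.
#' @param dir Output directory (created if needed).
#' @param patch_px Side length of one ROI patch in pixels.
#' @return Invisible character vector of the files written.
#' @export
render_roi_images <- function(rois, dir, patch_px = 16L) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("render_roi_images() requires the `tiff` package", call. = FALSE)
  }
  check_roi_table(rois)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(rois)
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  h <- nrow_grid * (patch_px + 4L) + 4L
  w <- ncol_grid * (patch_px + 4L) + 4L
  channels <- list(
    cfp_pre  = (rois$I_cfp_pre_1 + rois$I_cfp_pre_2) / 2,
    cfp_post = (rois$I_cfp_post_1 + rois$I_cfp_post_2) / 2,
    yfp_pre  = rois$I_yfp_pre,
    yfp_post = rois$I_yfp_post
  )
  scale <- max(unlist(channels), 1)
  paint <- function(values) {
    img <- matrix(0, nrow = h, ncol = w)
    for (i in seq_len(n)) {
      r0 <- 4L + ((i - 1L) %/% ncol_grid) * (patch_px + 4L)
      c0 <- 4L + ((i - 1L) %% ncol_grid) * (patch_px + 4L)
      img[r0 + seq_len(patch_px), c0 + seq_len(patch_px)] <- values[i]
    }
    img
  }
  files <- character(0)
  for (nm in names(channels)) {
    f <- file.path(dir, paste0(nm, ".tif"))
    tiff::writeTIFF(paint(channels[[nm]]) / scale, f,
                    bits.per.sample = 16L)
    files <- c(files, f)
  }
  f <- file.path(dir, "roi_mask.tif")
  tiff::writeTIFF(paint(rois$roi_id) / 65535, f, bits.per.sample = 16L)
  files <- c(files, f)
  invisible(files)
}
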