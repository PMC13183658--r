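# Analysis chain for acceptor-photobleaching FRET tables: QC on the realized
# acceptor bleach, per-ROI efficiency from donor dequenching, tandem-construct
# calibration of the acceptor/donor ratio, plateau filtering to E_Fmax,
# interaction calling, baseline subtraction, and group statistics.

check_roi_table <- function(rois) {
  missing <- setdiff(ROI_REQUIRED_COLS, names(rois))
  if (length(missing)) {
    stop("ROI table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(rois)
}

#' Quality-control filter on realized acceptor bleaching
#'
#' Computes the realized acceptor bleach fraction
#' `1 - I_yfp_post / I_yfp_pre` for every ROI and keeps only measurements in
#' which it strictly exceeds `min_bleach` — incompletely bleached acceptors
#' still quench the donor and would bias the efficiency downward. ROIs with
#' non-positive pre-bleach acceptor signal cannot be assessed and are dropped.
#' Dropped rows and reasons are attached as the `"dropped"` attribute.
#'
#' The filter is idempotent: applying it twice equals applying it once.
#'
#' @param rois ROI measurement table (see [render_intensities()] /
#'   [read_roi_table()]).
#' @param min_bleach Minimum acceptor bleached fraction, default 0.80
#'   (exceeded strictly).
#' @return The retained rows with an added `bleach_fraction` column.
#' @export
qc_filter <- function(rois, min_bleach = 0.80) {
  check_roi_table(rois)
  rois <- tibble::as_tibble(rois)
  if (nrow(rois) == 0L) {
    rois$bleach_fraction <- numeric(0)
    attr(rois, "dropped") <- rois
    return(rois)
  }
  assessable <- rois$I_yfp_pre > 0
  bf <- rep(NA_real_, nrow(rois))
  bf[assessable] <- 1 - rois$I_yfp_post[assessable] / rois$I_yfp_pre[assessable]
  rois$bleach_fraction <- bf
  keep <- assessable & bf > min_bleach
  dropped <- rois[!keep, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$qc_reason <- ifelse(dropped$I_yfp_pre <= 0,
                                "no pre-bleach acceptor signal",
                                sprintf("bleach fraction %.3f <= %.2f",
                                        dropped$bleach_fraction, min_bleach))
  }
  out <- rois[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Per-ROI FRET efficiency from donor dequenching
#'
#' Averages the duplicate donor-channel frames into `I_B` (before bleach,
#' quenched) and `I_A` (after bleach, dequenched) and computes
#' \deqn{E_F = \frac{I_A - I_B}{I_A} \times 100\,\%.}
#' Negative values are preserved — they are the expected outcome for
#' non-interacting controls under measurement noise. ROIs whose post-bleach
#' donor intensity is non-positive cannot be evaluated and are flagged
#' `qc_pass = FALSE` with `E_F = NA`.
#'
#' @param rois ROI table, typically the output of [qc_filter()].
#' @return A per-ROI results table: `roi_id`, `condition`, `environment`,
#'   `I_B`, `I_A`, `E_F` (percent), `I_yfp_pre`, `bleach_fraction` (if
#'   present), `ground_truth_E` (if present), `qc_pass`.
#' @export
compute_ef <- function(rois) {
  check_roi_table(rois)
  rois <- tibble::as_tibble(rois)
  I_B <- (rois$I_cfp_pre_1 + rois$I_cfp_pre_2) / 2
  I_A <- (rois$I_cfp_post_1 + rois$I_cfp_post_2) / 2
  valid <- I_A > 0
  E_F <- ifelse(valid, (I_A - I_B) / I_A * 100, NA_real_)
  out <- tibble::tibble(
    roi_id = rois$roi_id,
    condition = rois$condition,
    environment = rois$environment,
    I_B = I_B, I_A = I_A, E_F = E_F,
    I_yfp_pre = rois$I_yfp_pre,
    qc_pass = valid
  )
  if ("bleach_fraction" %in% names(rois)) out$bleach_fraction <- rois$bleach_fraction
  if ("ground_truth_E" %in% names(rois)) out$ground_truth_E <- rois$ground_truth_E
  out
}

#' Tandem-construct calibration of the acceptor/donor ratio
#'
#' The tandem construct carries donor and acceptor at a fixed 1:1
#' stoichiometry, so its acceptor-channel signal before bleaching plotted
#' against its donor-channel signal after bleaching (the unquenched donor)
#' calibrates the relative channel gain, including bleed-through. The
#' correction factor is the slope of the least-squares line through the
#' origin,
#' \deqn{cf = \frac{\sum_i x_i y_i}{\sum_i x_i^2},}
#' with `x` the averaged post-bleach donor intensity and `y` the pre-bleach
#' acceptor intensity of each tandem ROI.
#'
#' @param tandem_rois ROI table of tandem-construct measurements (pass them
#'   through [qc_filter()] first).
#' @return An object of class `tandem_calibration` with elements `cf` and
#'   `points` (a tibble of the regression points, kept for audit).
#' @export
fit_correction_factor <- function(tandem_rois) {
  check_roi_table(tandem_rois)
  if (nrow(tandem_rois) < 1L) {
    stop("calibration requires at least one tandem ROI", call. = FALSE)
  }
  x <- (tandem_rois$I_cfp_post_1 + tandem_rois$I_cfp_post_2) / 2
  y <- tandem_rois$I_yfp_pre
  if (all(x == 0)) {
    stop("calibration failed: all post-bleach donor intensities are zero",
         call. = FALSE)
  }
  cf <- sum(x * y) / sum(x^2)
  if (!(cf > 0)) {
    stop("calibration failed: non-positive correction factor", call. = FALSE)
  }
  structure(list(cf = cf, points = tibble::tibble(x = x, y = y)),
            class = "tandem_calibration")
}

#' @export
print.tandem_calibration <- function(x, ...) {
  cat(sprintf("Tandem calibration: cf = %.4f from %d ROIs\n",
              x$cf, nrow(x$points)))
  invisible(x)
}

#' Corrected acceptor/donor ratio per ROI
#'
#' Standardizes each ROI's acceptor/donor ratio against the tandem reference:
#' \deqn{YFP_{corr}/CFP = \frac{I_{YFP,pre} / cf}{I_A},}
#' with `I_A` the averaged post-bleach (unquenched) donor intensity. A tandem
#' ROI analyzed with its own calibration yields a ratio near 1, reflecting its
#' 1:1 stoichiometry.
#'
#' @param results Per-ROI results from [compute_ef()] (or a raw ROI table).
#' @param calib A [fit_correction_factor()] calibration.
#' @return `results` with an added `ratio_corrected` column; ROIs with a
#'   non-positive denominator get `NA` and `qc_pass = FALSE`.
#' @export
correct_ratio <- function(results, calib) {
  if (!inherits(calib, "tandem_calibration")) {
    stop("`calib` must be a `tandem_calibration`", call. = FALSE)
  }
  if (!all(c("I_A", "I_yfp_pre") %in% names(results))) {
    results <- compute_ef(results)
  }
  valid <- results$I_A > 0
  results$ratio_corrected <-
    ifelse(valid, (results$I_yfp_pre / calib$cf) / results$I_A, NA_real_)
  results$qc_pass <- results$qc_pass & valid
  results
}

#' Group efficiency within the acceptor/donor plateau (E_Fmax)
#'
#' The apparent efficiency rises with the corrected acceptor/donor ratio and
#' plateaus once enough acceptors surround each donor. Restricting to ROIs
#' whose corrected ratio lies in the plateau window (inclusive bounds,
#' default \[0.6, 3\]) makes group means comparable across constructs; the
#' mean of `E_F` over those ROIs is E_Fmax, reported with its standard error
#' `sd / sqrt(n)`.
#'
#' @param results Per-ROI results with `E_F` and `ratio_corrected`
#'   (see [correct_ratio()]).
#' @param lo,hi Plateau bounds on the corrected ratio (inclusive).
#' @return One-row tibble: `condition`, `environment`, `n`, `E_Fmax_mean`,
#'   `E_Fmax_sem`. If no ROI falls in the window, `NULL` is returned with a
#'   warning stating the counts.
#' @export
efmax <- function(results, lo = 0.6, hi = 3.0) {
  stopifnot(lo <= hi)
  if (!"ratio_corrected" %in% names(results)) {
    stop("`results` lacks `ratio_corrected`; run correct_ratio() first",
         call. = FALSE)
  }
  ok <- results$qc_pass & !is.na(results$E_F) &
    !is.na(results$ratio_corrected) &
    results$ratio_corrected >= lo & results$ratio_corrected <= hi
  n <- sum(ok)
  if (n < 1L) {
    warning(sprintf(
      "no ROI in plateau range [%g, %g] (%d candidates); summary withheld",
      lo, hi, nrow(results)))
    return(NULL)
  }
  e <- results$E_F[ok]
  tibble::tibble(
    condition = unique(results$condition)[1],
    environment = unique(results$environment)[1],
    n = n,
    E_Fmax_mean = mean(e),
    E_Fmax_sem = if (n > 1) stats::sd(e) / sqrt(n) else 0
  )
}

#' Call an interaction from a group summary
#'
#' A construct pair is called positive when its E_Fmax mean strictly exceeds
#' the threshold below which no genuine energy transfer is observed for
#' unlinked fluorophores (default 5%).
#'
#' @param summary A group summary from [efmax()] (one or more rows).
#' @param threshold Interaction threshold in percent.
#' @return `summary` with an added `interaction_call` column
#'   (`"positive"`/`"negative"`).
#' @export
call_interaction <- function(summary, threshold = 5.0) {
  stopifnot("E_Fmax_mean" %in% names(summary))
  summary$interaction_call <-
    ifelse(summary$E_Fmax_mean > threshold, "positive", "negative")
  summary
}

#' Baseline-subtracted efficiency
#'
#' Subtracts the E_Fmax of a matched negative control (same environment) from
#' a sample group, the correction that brings fixed-cell values of a genuine
#' interaction back toward their live-cell magnitude.
#'
#' @param sample,negative One-row group summaries from [efmax()].
#' @return The difference of the `E_Fmax_mean` values, in percent (may be
#'   negative).
#' @export
#' @examples
#' s <- tibble::tibble(condition = "homomer", environment = "fixed",
#'                     n = 10, E_Fmax_mean = 33.1, E_Fmax_sem = 1.6)
#' b <- tibble::tibble(condition = "neg", environment = "fixed",
#'                     n = 10, E_Fmax_mean = 12.52, E_Fmax_sem = 1.6)
#' baseline_subtract(s, b)  # 20.58
baseline_subtract <- function(sample, negative) {
  stopifnot("E_Fmax_mean" %in% names(sample),
            "E_Fmax_mean" %in% names(negative))
  if (!identical(sample$environment[1], negative$environment[1])) {
    stop(sprintf("environment mismatch: sample is \"%s\", negative is \"%s\"",
                 sample$environment[1], negative$environment[1]),
         call. = FALSE)
  }
  sample$E_Fmax_mean[1] - negative$E_Fmax_mean[1]
}

#' Šidák adjustment for multiple comparisons
#'
#' `p_adj = 1 - (1 - p)^m`, the exact family-wise correction for `m`
#' independent tests; always at least the raw p and at most the Bonferroni
#' bound `m * p`.
#'
#' @param p Numeric vector of raw p values.
#' @param m Number of comparisons in the family; defaults to `length(p)`.
#' @return Adjusted p values in \[0, 1\].
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

#' Pairwise and overall comparison of group efficiencies
#'
#' Runs two-sample Student t tests (pooled variance by default, Welch
#' optionally) on all pairs of groups, adjusts the p values with the Šidák
#' correction using the number of pairwise tests actually performed, and adds
#' a one-way ANOVA F test across all groups. Groups with fewer than two
#' members are excluded from testing with a warning.
#'
#' @param groups Either a named list of numeric vectors of per-ROI `E_F`
#'   values, or a data frame with columns `E_F` and a grouping column named by
#'   `group_col`.
#' @param group_col Grouping column name when `groups` is a data frame.
#' @param var_equal Use the pooled-variance Student form (default `TRUE`);
#'   `FALSE` gives Welch tests.
#' @return A list of class `fret_comparison`: `pairwise` (tibble with
#'   `group_a`, `group_b`, `t`, `df`, `p`, `p_sidak`), `anova` (list with
#'   `F`, `df1`, `df2`, `p`), `m` (family size).
#' @export
compare_groups <- function(groups, group_col = "condition", var_equal = TRUE) {
  if (is.data.frame(groups)) {
    stopifnot("E_F" %in% names(groups), group_col %in% names(groups))
    groups <- split(groups$E_F, groups[[group_col]])
  }
  stopifnot(is.list(groups), !is.null(names(groups)))
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    warning("excluding group(s) with n < 2 from testing: ",
            paste(names(groups)[sizes < 2L], collapse = ", "))
    groups <- groups[sizes >= 2L]
  }
  if (length(groups) < 2L) {
    stop("need at least two groups with n >= 2", call. = FALSE)
  }
  pairs <- utils::combn(names(groups), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- groups[[pairs[1, i]]]
    b <- groups[[pairs[2, i]]]
    tt <- stats::t.test(a, b, var.equal = var_equal)
    tibble::tibble(group_a = pairs[1, i], group_b = pairs[2, i],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
  pairwise <- do.call(rbind, rows)
  pairwise$p_sidak <- sidak_adjust(pairwise$p, m)
  df <- data.frame(E_F = unlist(groups, use.names = FALSE),
                   group = rep(names(groups), lengths(groups)))
  aovfit <- stats::oneway.test(E_F ~ group, data = df, var.equal = TRUE)
  structure(list(pairwise = pairwise,
                 anova = list(F = unname(aovfit$statistic),
                              df1 = unname(aovfit$parameter[1]),
                              df2 = unname(aovfit$parameter[2]),
                              p = aovfit$p.value),
                 m = m),
            class = "fret_comparison")
}

#' @export
print.fret_comparison <- function(x, ...) {
  cat(sprintf("Pairwise Student t tests (Sidak-adjusted over m = %d):\n", x$m))
  print(as.data.frame(x$pairwise), digits = 4)
  cat(sprintf("One-way ANOVA: F(%g, %.1f) = %.3f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  invisible(x)
}

#' Run the full analysis chain on an ROI table
#'
#' Convenience composition: [qc_filter()] then [compute_ef()] then
#' [correct_ratio()] against a tandem calibration.
#'
#' @param rois ROI measurement table.
#' @param calib A [fit_correction_factor()] calibration.
#' @param min_bleach QC threshold on the realized acceptor bleach.
#' @return Per-ROI results table with `E_F` and `ratio_corrected`.
#' @export
analyze_rois <- function(rois, calib, min_bleach = 0.80) {
  correct_ratio(compute_ef(qc_filter(rois, min_bleach)), calib)
}
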