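#' Ordinal confusion matrix between reference (PF) and test (SF) labels
#'
#' Rows index the reference (PF) category, columns the test (SF)
#' category, both ordered none < mild < moderate < severe.
#'
#' @param ref_labels,test_labels Equal-length vectors of severity labels
#'   (ordered factors or category names).
#' @return A 4x4 integer matrix of class `confusion_matrix` with dimnames
#'   `PF`/`SF`.
#' @export
confusion <- function(ref_labels, test_labels) {
  if (length(ref_labels) != length(test_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  r <- factor(as.character(ref_labels), levels = severity_levels)
  s <- factor(as.character(test_labels), levels = severity_levels)
  if (any(is.na(r)) || any(is.na(s))) {
    stop("unknown severity label", call. = FALSE)
  }
  m <- unclass(table(PF = r, SF = s))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Overall accuracy and per-category recall
#'
#' Overall accuracy is the diagonal mass divided by the total; recall for
#' a category is its diagonal cell divided by its reference row total,
#' reported as `NA` (absent, not zero) for empty rows.
#'
#' @param matrix A [confusion()] matrix.
#' @return A list with `overall` (fraction) and `recall` (named numeric).
#' @export
accuracy_and_recall <- function(matrix) {
  total <- sum(matrix)
  if (total == 0) stop("empty confusion matrix: accuracy undefined",
                       call. = FALSE)
  row_totals <- rowSums(matrix)
  recall <- ifelse(row_totals > 0, diag(matrix) / row_totals, NA_real_)
  names(recall) <- rownames(matrix)
  list(overall = sum(diag(matrix)) / total, recall = recall)
}

#' Misclassification direction rates
#'
#' `over_rate` is the share of all classifications where the SF category
#' is more severe than the PF category (cells above the diagonal in the
#' none < mild < moderate < severe ordering), `under_rate` where it is
#' less severe; `over_share_misclassified` is the over mass as a fraction
#' of all off-diagonal mass (`NA` when nothing is misclassified). By
#' construction `over_rate + under_rate + overall accuracy = 1`.
#'
#' @param matrix A [confusion()] matrix.
#' @return A list with `over_rate`, `under_rate`,
#'   `over_share_misclassified`.
#' @export
direction_rates <- function(matrix) {
  total <- sum(matrix)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  over <- sum(matrix[upper.tri(matrix)])
  under <- sum(matrix[lower.tri(matrix)])
  list(
    over_rate = over / total,
    under_rate = under / total,
    over_share_misclassified =
      if (over + under > 0) over / (over + under) else NA_real_
  )
}

#' Classification accuracy binned by FiO2
#'
#' Bins labeled datapoints by FiO2 in percentage points, bins
#' `[center - w/2, center + w/2)` with centers at multiples of the bin
#' width (lower edge inclusive, upper exclusive), and reports the
#' PF-vs-SF category accuracy per bin. Empty bins are omitted. The
#' n-weighted mean of bin accuracies equals the pooled accuracy.
#'
#' @param labeled Output of [classify_datapoints()].
#' @param bin_width Bin width in FiO2 percentage points (default 5).
#' @return A tibble with `center` (percent), `n`, `accuracy`.
#' @export
fio2_binned_accuracy <- function(labeled, bin_width = 5) {
  stopifnot(all(c("fio2", "pf_class", "sf_class") %in% names(labeled)),
            bin_width > 0)
  pct <- labeled$fio2 * 100
  center <- floor((pct + bin_width / 2) / bin_width) * bin_width
  agree <- labeled$pf_class == labeled$sf_class
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(center = center, agree = agree), center),
    n = dplyr::n(), accuracy = mean(agree), .groups = "drop"
  )
  dplyr::arrange(out, center)
}

#' Pearson product-moment correlation
#'
#' A thin, argument-checked wrapper: errors (rather than returning `NA`)
#' on fewer than two pairs or zero variance in either margin, so callers
#' must handle the undefined case explicitly.
#'
#' @param x,y Equal-length numeric vectors.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ",
                                   call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least two complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Oximetry bias and precision
#'
#' Mean (bias) and sample standard deviation (precision) of paired
#' differences SpO2 - SaO2, both in percent.
#'
#' @param spo2_pct,sao2_pct Paired saturations in percent.
#' @return A list with `bias` and `precision`.
#' @export
bias_precision <- function(spo2_pct, sao2_pct) {
  if (length(spo2_pct) != length(sao2_pct)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  d <- spo2_pct - sao2_pct
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("need at least two pairs", call. = FALSE)
  list(bias = mean(d), precision = stats::sd(d))
}

#' Saturation-binned bias profile and zero-crossing estimate
#'
#' Mean bias (SpO2 - SaO2) per 1-percent SpO2 bin, plus an estimate of
#' the saturation at which the bias crosses zero, taken as
#' `-intercept / slope` of the least-squares line of bias on SpO2 over
#' the raw pairs. The crossing is reported as `NA` when the fitted slope
#' is (near) zero or fewer than 50 pairs are available.
#'
#' @inheritParams bias_precision
#' @param bin_width Bin width in SpO2 percentage points (default 1).
#' @return A list with `profile` (tibble: `spo2_bin`, `n`, `mean_bias`)
#'   and `crossing` (percent or `NA`).
#' @export
binned_bias_profile <- function(spo2_pct, sao2_pct, bin_width = 1) {
  if (length(spo2_pct) != length(sao2_pct)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(spo2_pct) & !is.na(sao2_pct)
  spo2 <- spo2_pct[ok]; bias <- spo2_pct[ok] - sao2_pct[ok]
  bin <- floor((spo2 + bin_width / 2) / bin_width) * bin_width
  profile <- dplyr::arrange(dplyr::summarise(
    dplyr::group_by(tibble::tibble(spo2_bin = bin, bias = bias), spo2_bin),
    n = dplyr::n(), mean_bias = mean(bias), .groups = "drop"
  ), spo2_bin)
  crossing <- NA_real_
  if (length(spo2) >= 50 && stats::sd(spo2) > 0) {
    fit <- stats::lm(bias ~ spo2)
    slope <- stats::coef(fit)[[2]]
    if (is.finite(slope) && abs(slope) > 1e-8) {
      crossing <- -stats::coef(fit)[[1]] / slope
    }
  }
  list(profile = profile, crossing = crossing)
}

#' Root-mean-square deviation from the Severinghaus curve
#'
#' How far paired (PaO2, saturation) observations sit from the
#' oxyhemoglobin dissociation curve: co-oximetric SaO2 follows the curve
#' closely, while pulse-oximetric SpO2 is diluted by measurement error.
#'
#' @param pao2 Oxygen tensions, mmHg.
#' @param saturation_fraction Paired saturations as fractions.
#' @return RMS deviation (saturation fraction units).
#' @export
curve_deviation <- function(pao2, saturation_fraction) {
  if (length(pao2) != length(saturation_fraction)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(pao2) & !is.na(saturation_fraction)
  sqrt(mean((saturation_fraction[ok] - severinghaus_sao2(pao2[ok]))^2))
}

#' Full agreement report at the datapoint or admission level
#'
#' Assembles the confusion matrix, overall accuracy, per-category recall,
#' misclassification direction rates, SF-PF ratio correlation (datapoint
#' level; ratios are pooled across admissions) and FiO2-binned accuracy
#' (datapoint level).
#'
#' @param labeled Output of [classify_datapoints()] (datapoint level) or
#'   a tibble with `pf_class`/`sf_class` per admission (admission level).
#' @param level `"datapoint"` or `"admission"`.
#' @param fio2_bin_width Bin width for [fio2_binned_accuracy()].
#' @return A list of class `agreement_report`.
#' @export
agreement_report <- function(labeled, level = c("datapoint", "admission"),
                             fio2_bin_width = 5) {
  level <- match.arg(level)
  m <- confusion(labeled$pf_class, labeled$sf_class)
  acc <- accuracy_and_recall(m)
  dir <- direction_rates(m)
  report <- list(
    level = level, n = sum(m), matrix = m,
    overall_accuracy = acc$overall, recall_per_category = acc$recall,
    over_rate = dir$over_rate, under_rate = dir$under_rate,
    over_share_misclassified = dir$over_share_misclassified
  )
  if (level == "datapoint") {
    report$pearson_r_sf_pf <- tryCatch(
      pearson_r(labeled$sf_ratio, labeled$pf_ratio),
      error = function(e) NA_real_)
    report$fio2_bins <- fio2_binned_accuracy(labeled, fio2_bin_width)
  }
  class(report) <- "agreement_report"
  report
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s level, n = %d\n", x$level, x$n))
  cat(sprintf("  overall accuracy %.1f%%; SF over %.1f%% / under %.1f%%\n",
              100 * x$overall_accuracy, 100 * x$over_rate,
              100 * x$under_rate))
  if (!is.null(x$pearson_r_sf_pf) && !is.na(x$pearson_r_sf_pf)) {
    cat(sprintf("  SF-PF ratio correlation r = %.2f\n", x$pearson_r_sf_pf))
  }
  invisible(x)
}
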