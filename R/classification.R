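#' ARDS severity category levels, least to most severe
#' @export
severity_levels <- c("none", "mild", "moderate", "severe")

# 2024 global-definition thresholds; intervals are closed on the
# more-severe side: PF severe <= 100 < moderate <= 200 < mild <= 300 < none
severity_thresholds <- list(
  PF = c(severe = 100, moderate = 200, mild = 300),
  SF = c(severe = 148, moderate = 235, mild = 315)
)

#' Classify an oxygenation ratio into an ARDS severity category
#'
#' Applies the 2024 global-definition thresholds. On the PF (PaO2/FiO2)
#' scale: severe <= 100 < moderate <= 200 < mild <= 300 < none. On the SF
#' (SpO2/FiO2) scale: severe <= 148 < moderate <= 235 < mild <= 315 <
#' none. Boundaries are inclusive on the more-severe side; values are
#' thresholded at full precision, never rounded first.
#'
#' @param value Ratio value(s), strictly positive.
#' @param scale `"PF"` or `"SF"`.
#' @return An ordered factor with levels none < mild < moderate < severe.
#' @examples
#' classify_ratio(c(100, 100.5, 300, 300.5), "PF")
#' classify_ratio(148, "SF") # severe (boundary inclusive)
#' @export
classify_ratio <- function(value, scale = c("PF", "SF")) {
  scale <- match.arg(scale)
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0)) {
    stop("ratio `value` must be finite and strictly positive", call. = FALSE)
  }
  th <- severity_thresholds[[scale]]
  cls <- cut(value, breaks = c(0, th, Inf),
             labels = c("severe", "moderate", "mild", "none"),
             right = TRUE)
  factor(as.character(cls), levels = severity_levels, ordered = TRUE)
}

#' Label datapoints on both scales
#'
#' Computes the PF and SF ratios from the same FiO2 and classifies both.
#' Refuses invalid datapoints: validity filtering is a precondition, not
#' an afterthought.
#'
#' @param dp A datapoint tibble with only valid rows (see
#'   [validity_filter()]).
#' @return The tibble with columns `pf_ratio`, `sf_ratio`, `pf_class`,
#'   `sf_class` appended.
#' @export
classify_datapoints <- function(dp) {
  dp <- validate_datapoints(dp)
  if (any(!dp$valid)) {
    stop("classify_datapoints() requires valid datapoints only; ",
         sum(!dp$valid), " invalid row(s) present", call. = FALSE)
  }
  dp$pf_ratio <- pf_ratio(dp$pao2, dp$fio2)
  dp$sf_ratio <- sf_ratio(dp$spo2, dp$fio2)
  dp$pf_class <- classify_ratio(dp$pf_ratio, "PF")
  dp$sf_class <- classify_ratio(dp$sf_ratio, "SF")
  dp
}

#' Most severe admission-level category under the two-consecutive rule
#'
#' An admission is assigned the most severe category `C` such that some
#' pair of adjacent classifications both reach at least `C` — i.e. a
#' severity must be sustained over two consecutive datapoints to count.
#' Equivalently, for n >= 2 the answer is the maximum over adjacent pairs
#' of the pairwise minimum. A single-label sequence falls back to that
#' label's category (the rule is undefined at n = 1; dropping such
#' admissions would silently bias the admission-level analysis).
#'
#' @param labels Time-ordered severity labels for one admission and one
#'   scale: an ordered factor from [classify_ratio()] or a character
#'   vector of category names.
#' @return A single ordered factor level.
#' @examples
#' admission_max_severity(c("mild", "severe", "mild"))      # mild
#' admission_max_severity(c("mild", "severe", "severe"))    # severe
#' @export
admission_max_severity <- function(labels) {
  if (!length(labels)) {
    stop("cannot aggregate an empty label sequence", call. = FALSE)
  }
  idx <- match(as.character(labels), severity_levels)
  if (any(is.na(idx))) stop("unknown severity label", call. = FALSE)
  n <- length(idx)
  best <- if (n == 1) idx else max(pmin(idx[-n], idx[-1]))
  factor(severity_levels[best], levels = severity_levels, ordered = TRUE)
}
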