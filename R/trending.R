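#' Consecutive datapoint pairs within admissions
#'
#' Builds one pair per adjacent valid datapoint within each admission
#' (never across admissions), carrying proportional changes
#' `(x2 - x1) / x1` of FiO2, PaO2 and SpO2, Respiratory Index values and
#' proportional RI change where PaCO2 permits their computation, and the
#' ordinal severity-category transitions (`down`/`same`/`up`) on each
#' scale.
#'
#' @param labeled Output of [classify_datapoints()]: valid, labeled
#'   datapoints.
#' @param constants A [physiology_constants()] object for the RI.
#' @return A tibble with one row per pair.
#' @export
consecutive_pairs <- function(labeled, constants = physiology_constants()) {
  stopifnot(all(c("admission_id", "time", "pao2", "spo2", "fio2", "paco2",
                  "pf_class", "sf_class") %in% names(labeled)))
  labeled <- dplyr::arrange(labeled, admission_id, time)
  grp <- split(seq_len(nrow(labeled)), labeled$admission_id)
  pieces <- lapply(grp, function(ix) {
    n <- length(ix)
    if (n < 2) return(NULL)
    a <- labeled[ix[-n], ]
    b <- labeled[ix[-1], ]
    ri1 <- ri_or_na(a$pao2, a$fio2, a$paco2, constants)
    ri2 <- ri_or_na(b$pao2, b$fio2, b$paco2, constants)
    tibble::tibble(
      admission_id = a$admission_id,
      time1 = a$time, time2 = b$time, dt = b$time - a$time,
      fio2_1 = a$fio2, fio2_2 = b$fio2,
      d_fio2 = (b$fio2 - a$fio2) / a$fio2,
      d_pao2 = (b$pao2 - a$pao2) / a$pao2,
      d_spo2 = (b$spo2 - a$spo2) / a$spo2,
      ri_first = ri1, ri_second = ri2,
      ri_change = (ri2 - ri1) / ri1,
      pf_transition = transition(a$pf_class, b$pf_class),
      sf_transition = transition(a$sf_class, b$sf_class)
    )
  })
  out <- dplyr::bind_rows(pieces)
  if (!nrow(out)) return(empty_pairs())
  out
}

ri_or_na <- function(pao2, fio2, paco2, constants) {
  ri <- rep(NA_real_, length(pao2))
  ok <- !is.na(paco2)
  if (any(ok)) {
    ri[ok] <- respiratory_index(pao2[ok], fio2[ok], paco2[ok], constants)
  }
  ri
}

transition <- function(from, to) {
  i <- match(as.character(from), severity_levels)
  j <- match(as.character(to), severity_levels)
  factor(c("down", "same", "up")[sign(j - i) + 2],
         levels = c("down", "same", "up"))
}

empty_pairs <- function() {
  tibble::tibble(
    admission_id = character(), time1 = numeric(), time2 = numeric(),
    dt = numeric(), fio2_1 = numeric(), fio2_2 = numeric(),
    d_fio2 = numeric(), d_pao2 = numeric(), d_spo2 = numeric(),
    ri_first = numeric(), ri_second = numeric(), ri_change = numeric(),
    pf_transition = factor(character(), levels = c("down", "same", "up")),
    sf_transition = factor(character(), levels = c("down", "same", "up"))
  )
}

#' Respiratory-condition stability gate for datapoint pairs
#'
#' Marks a pair as stable when the time interval does not exceed
#' `max_dt_hours` and the proportional Respiratory Index change
#' `(RI2 - RI1)/RI1` stays within `ri_tolerance` in magnitude — i.e. the
#' gas-exchange state is judged unchanged, so any FiO2-driven divergence
#' of the two ratios is a treatment effect, not disease progression.
#' Pairs whose RI cannot be evaluated (missing PaCO2) or whose first RI
#' lies below `ri_floor` (a proportional change on a near-zero base is
#' unstable) get `stable = NA` and are counted separately.
#'
#' @param pairs Output of [consecutive_pairs()].
#' @param max_dt_hours Maximum interval, hours (default 6).
#' @param ri_tolerance Maximum absolute proportional RI change
#'   (default 0.20).
#' @param ri_floor Minimum first-RI for the proportional change to be
#'   meaningful (default 0.05).
#' @return The pairs tibble with a `stable` column (`TRUE`/`FALSE`/`NA`);
#'   counts in attribute `gate_counts` (evaluated, not_evaluable, stable).
#' @export
stability_gate <- function(pairs, max_dt_hours = 6, ri_tolerance = 0.20,
                           ri_floor = 0.05) {
  stopifnot(max_dt_hours > 0, ri_tolerance >= 0, ri_floor >= 0)
  evaluable <- !is.na(pairs$ri_first) & !is.na(pairs$ri_second) &
    pairs$ri_first >= ri_floor
  stable <- rep(NA, nrow(pairs))
  # small epsilon so boundary changes (exactly +/- tolerance) computed
  # through the alveolar-gas round trip are not lost to float error
  stable[evaluable] <- pairs$dt[evaluable] <= max_dt_hours * 3600 &
    abs(pairs$ri_change[evaluable]) <= ri_tolerance + 1e-9
  pairs$stable <- stable
  attr(pairs, "gate_counts") <- c(
    evaluated = sum(evaluable), not_evaluable = sum(!evaluable),
    stable = sum(stable, na.rm = TRUE)
  )
  pairs
}

#' Proportional-change correlations under stable conditions
#'
#' On RI-stable pairs (optionally restricted to pairs where FiO2 actually
#' changed), correlates proportional FiO2 change with proportional PaO2
#' change and with proportional SpO2 change. A wide gap between the two —
#' FiO2 tracking PaO2 but not SpO2 — is the signature of the SF ratio's
#' FiO2 dependence: on the flat upper part of the dissociation curve an
#' FiO2 change moves PaO2 almost proportionally while SpO2 barely moves.
#' Correlations undefined by zero variance are reported as `NA`.
#'
#' @param pairs Output of [stability_gate()].
#' @param require_fio2_change Restrict to pairs with `d_fio2 != 0`
#'   (default `TRUE`).
#' @return A list with `r_fio2_pao2`, `r_fio2_spo2`, `n`.
#' @export
change_correlations <- function(pairs, require_fio2_change = TRUE) {
  if (!"stable" %in% names(pairs)) {
    stop("run stability_gate() first", call. = FALSE)
  }
  keep <- !is.na(pairs$stable) & pairs$stable
  if (require_fio2_change) keep <- keep & pairs$d_fio2 != 0
  sub <- pairs[keep, , drop = FALSE]
  safe_r <- function(x, y) tryCatch(pearson_r(x, y),
                                    error = function(e) NA_real_)
  list(
    r_fio2_pao2 = safe_r(sub$d_fio2, sub$d_pao2),
    r_fio2_spo2 = safe_r(sub$d_fio2, sub$d_spo2),
    n = nrow(sub)
  )
}

#' Severity-change detection analysis
#'
#' Cross-tabulates the direction of PF-category transitions (rows)
#' against SF-category transitions (columns) over consecutive pairs, and
#' reports the detection rate: among pairs where the PF category changed,
#' the fraction whose SF transition moved in the same direction. `NA`
#' when no PF transitions occurred.
#'
#' @param pairs Output of [consecutive_pairs()] (gating not required).
#' @return A list with `matrix` (3x3, down/same/up) and
#'   `detection_rate`.
#' @export
change_detection <- function(pairs) {
  m <- unclass(table(PF = pairs$pf_transition, SF = pairs$sf_transition))
  changed <- pairs$pf_transition != "same"
  rate <- if (any(changed)) {
    mean(pairs$sf_transition[changed] == pairs$pf_transition[changed])
  } else {
    NA_real_
  }
  list(matrix = m, detection_rate = rate)
}

#' Full trending report
#'
#' Runs [consecutive_pairs()], [stability_gate()],
#' [change_correlations()] and [change_detection()] with one set of
#' tunables.
#'
#' @inheritParams consecutive_pairs
#' @inheritParams stability_gate
#' @inheritParams change_correlations
#' @return A list of class `trend_report`.
#' @export
trend_report <- function(labeled, max_dt_hours = 6, ri_tolerance = 0.20,
                         ri_floor = 0.05, require_fio2_change = TRUE,
                         constants = physiology_constants()) {
  pairs <- consecutive_pairs(labeled, constants)
  pairs <- stability_gate(pairs, max_dt_hours, ri_tolerance, ri_floor)
  detection <- change_detection(pairs)
  out <- list(
    n_pairs = nrow(pairs),
    gate_counts = attr(pairs, "gate_counts"),
    correlations = change_correlations(pairs, require_fio2_change),
    transition_matrix = detection$matrix,
    detection_rate = detection$detection_rate
  )
  class(out) <- "trend_report"
  out
}

#' @export
print.trend_report <- function(x, ...) {
  cat(sprintf("<trend_report> %d pairs (%d RI-stable)\n", x$n_pairs,
              x$gate_counts[["stable"]]))
  cat(sprintf("  corr(dFiO2, dPaO2) = %.2f; corr(dFiO2, dSpO2) = %.2f (n = %d)\n",
              x$correlations$r_fio2_pao2, x$correlations$r_fio2_spo2,
              x$correlations$n))
  if (!is.na(x$detection_rate)) {
    cat(sprintf("  severity-change detection rate = %.1f%%\n",
                100 * x$detection_rate))
  }
  invisible(x)
}
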