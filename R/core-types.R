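#' A single physiologic channel as a regular or irregular time series
#'
#' One named signal for one admission: strictly increasing timestamps
#' (seconds since admission start) paired with finite values in the
#' channel's units.
#'
#' @param name Channel identifier, e.g. `"spo2"`, `"fio2"`, `"abp"`.
#' @param times Numeric vector of timestamps in seconds since admission
#'   start; must be strictly increasing.
#' @param values Numeric vector of the same length; must be finite.
#' @param units Unit string (`"%"`, `"fraction"`, `"mmHg"`, `"cmH2O"`,
#'   `"L/min"`).
#' @return An object of class `channel_series`.
#' @export
channel_series <- function(name, times, values, units) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(times), is.numeric(values),
            is.character(units), length(units) == 1)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  structure(
    list(name = name, times = as.numeric(times),
         values = as.numeric(values), units = units),
    class = "channel_series"
  )
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %s [%s], %d samples", x$name, x$units,
              length(x$times)))
  if (length(x$times)) {
    cat(sprintf(", t = %.0f..%.0f s", x$times[1], x$times[length(x$times)]))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.channel_series <- function(x) length(x$times)

valid_support_modes <- c("invasive_ventilation", "niv_cpap", "hfno", "none")

#' Respiratory support intervals for one admission
#'
#' Non-overlapping intervals of respiratory support. Modes with a PEEP
#' (invasive ventilation, NIV/CPAP) carry `peep` in cmH2O; HFNO carries
#' `flow` in L/min; mode `"none"` carries neither.
#'
#' @param start_s,end_s Interval bounds in seconds, `start_s < end_s`.
#' @param mode One of `"invasive_ventilation"`, `"niv_cpap"`, `"hfno"`,
#'   `"none"`.
#' @param peep PEEP in cmH2O; required (non-NA) iff the mode has a PEEP.
#' @param flow HFNO flow in L/min; required iff mode is `"hfno"`.
#' @return A tibble with one row per interval.
#' @export
support_intervals <- function(start_s, end_s, mode, peep = NA_real_,
                              flow = NA_real_) {
  tbl <- tibble::tibble(
    start_s = as.numeric(start_s), end_s = as.numeric(end_s),
    mode = as.character(mode),
    peep = as.numeric(peep), flow = as.numeric(flow)
  )
  validate_support(tbl)
}

validate_support <- function(tbl) {
  stopifnot(all(c("start_s", "end_s", "mode", "peep", "flow") %in% names(tbl)))
  if (any(!tbl$mode %in% valid_support_modes)) {
    stop("unknown support mode; must be one of ",
         paste(valid_support_modes, collapse = ", "), call. = FALSE)
  }
  if (any(tbl$start_s >= tbl$end_s)) {
    stop("support intervals must have start_s < end_s", call. = FALSE)
  }
  has_peep <- tbl$mode %in% c("invasive_ventilation", "niv_cpap")
  if (any(has_peep & is.na(tbl$peep))) {
    stop("modes with PEEP require a non-missing `peep`", call. = FALSE)
  }
  if (any(tbl$mode == "hfno" & is.na(tbl$flow))) {
    stop("HFNO intervals require a non-missing `flow`", call. = FALSE)
  }
  tbl <- tbl[order(tbl$start_s), , drop = FALSE]
  if (nrow(tbl) > 1 && any(tbl$start_s[-1] < tbl$end_s[-nrow(tbl)])) {
    stop("support intervals must be non-overlapping", call. = FALSE)
  }
  tbl
}

#' Arterial blood-gas events for one admission
#'
#' @param time_s Nominal (laboratory) timestamps, seconds since admission.
#' @param pao2 Arterial oxygen tension, mmHg, strictly positive.
#' @param sao2 Co-oximetric arterial saturation as a fraction in (0, 1];
#'   `NA` when not measured.
#' @param paco2 Arterial CO2 tension in mmHg; `NA` when not measured.
#' @return A tibble ordered by `time_s`.
#' @export
abg_events <- function(time_s, pao2, sao2 = NA_real_, paco2 = NA_real_) {
  tbl <- tibble::tibble(
    time_s = as.numeric(time_s), pao2 = as.numeric(pao2),
    sao2 = as.numeric(sao2), paco2 = as.numeric(paco2)
  )
  validate_abgs(tbl)
}

validate_abgs <- function(tbl) {
  stopifnot(all(c("time_s", "pao2", "sao2", "paco2") %in% names(tbl)))
  if (any(is.na(tbl$pao2)) || any(tbl$pao2 <= 0)) {
    stop("`pao2` must be present and strictly positive for every ABG",
         call. = FALSE)
  }
  ok_sao2 <- is.na(tbl$sao2) | (tbl$sao2 > 0 & tbl$sao2 <= 1)
  if (!all(ok_sao2)) {
    stop("`sao2` must be a fraction in (0, 1] when present", call. = FALSE)
  }
  if (any(!is.na(tbl$paco2) & tbl$paco2 <= 0)) {
    stop("`paco2` must be strictly positive when present", call. = FALSE)
  }
  tbl[order(tbl$time_s), , drop = FALSE]
}

#' One ICU admission: channels, support intervals and ABG events
#'
#' The container consumed by the matching stage. Must hold at least the
#' `spo2` and `fio2` channels; a 1-Hz arterial-pressure channel `abp` is
#' optional and enables ABG timestamp correction by gap detection.
#'
#' @param admission_id Admission identifier string.
#' @param channels Named list of [channel_series()] objects.
#' @param support Support-interval tibble ([support_intervals()]).
#' @param abgs ABG tibble ([abg_events()]).
#' @param resolution_class One of `"high"` (sub-second to 1 s), `"minute"`,
#'   `"hourly"`; controls the matching strategy used downstream.
#' @return An object of class `admission_record`.
#' @export
admission_record <- function(admission_id, channels, support, abgs,
                             resolution_class = c("minute", "high", "hourly")) {
  resolution_class <- match.arg(resolution_class)
  stopifnot(is.character(admission_id), length(admission_id) == 1)
  if (!is.list(channels) || is.null(names(channels))) {
    stop("`channels` must be a named list of channel_series", call. = FALSE)
  }
  if (!all(vapply(channels, inherits, logical(1), "channel_series"))) {
    stop("every element of `channels` must be a channel_series", call. = FALSE)
  }
  missing_ch <- setdiff(c("spo2", "fio2"), names(channels))
  if (length(missing_ch)) {
    stop("required channel(s) missing: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(admission_id = admission_id, channels = channels,
         support = validate_support(support), abgs = validate_abgs(abgs),
         resolution_class = resolution_class),
    class = "admission_record"
  )
}

#' @export
print.admission_record <- function(x, ...) {
  cat(sprintf("<admission_record> %s (%s resolution)\n", x$admission_id,
              x$resolution_class))
  cat("  channels:", paste(sprintf("%s[%d]", names(x$channels),
                                   vapply(x$channels, length, integer(1))),
                           collapse = ", "), "\n")
  cat(sprintf("  support intervals: %d; ABG events: %d\n",
              nrow(x$support), nrow(x$abgs)))
  invisible(x)
}

datapoint_exclusion_reasons <- c("none", "spo2_gt_97", "support_criteria",
                                 "incomplete")

#' Construct a datapoint table
#'
#' A datapoint is one time-matched tuple (PaO2, SpO2, FiO2 plus context)
#' anchored at an ABG event; it is the unit of all downstream analysis.
#' `valid` is always `exclusion_reason == "none"`.
#'
#' @param admission_id,time,pao2,spo2,fio2,sao2,paco2,mode,peep,flow Column
#'   vectors; `time` is the (corrected) ABG time in seconds, `spo2` in
#'   percent, `fio2` a fraction in [0.21, 1], `sao2` a fraction.
#' @param exclusion_reason One of `"none"`, `"spo2_gt_97"`,
#'   `"support_criteria"`, `"incomplete"`.
#' @return A tibble with class-stable columns, one row per datapoint.
#' @export
datapoints <- function(admission_id = character(), time = numeric(),
                       pao2 = numeric(), spo2 = numeric(), fio2 = numeric(),
                       sao2 = numeric(), paco2 = numeric(),
                       mode = character(), peep = numeric(), flow = numeric(),
                       exclusion_reason = character()) {
  tbl <- tibble::tibble(
    admission_id = as.character(admission_id), time = as.numeric(time),
    pao2 = as.numeric(pao2), spo2 = as.numeric(spo2),
    fio2 = as.numeric(fio2), sao2 = as.numeric(sao2),
    paco2 = as.numeric(paco2), mode = as.character(mode),
    peep = as.numeric(peep), flow = as.numeric(flow),
    exclusion_reason = as.character(exclusion_reason)
  )
  tbl$valid <- tbl$exclusion_reason == "none"
  validate_datapoints(tbl)
}

validate_datapoints <- function(tbl) {
  req <- c("admission_id", "time", "pao2", "spo2", "fio2", "sao2", "paco2",
           "mode", "peep", "flow", "valid", "exclusion_reason")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols)) {
    stop("datapoint table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!tbl$exclusion_reason %in% datapoint_exclusion_reasons)) {
    stop("unknown exclusion_reason", call. = FALSE)
  }
  if (!identical(tbl$valid, tbl$exclusion_reason == "none")) {
    stop("`valid` must equal `exclusion_reason == \"none\"`", call. = FALSE)
  }
  bad_fio2 <- !is.na(tbl$fio2) & (tbl$fio2 < 0.21 | tbl$fio2 > 1)
  if (any(bad_fio2)) {
    stop("`fio2` must lie in [0.21, 1.0]", call. = FALSE)
  }
  bad_spo2 <- !is.na(tbl$spo2) & (tbl$spo2 <= 0 | tbl$spo2 > 100)
  if (any(bad_spo2)) {
    stop("`spo2` must lie in (0, 100]", call. = FALSE)
  }
  tbl[, req, drop = FALSE]
}
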