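#' Time-matching policy
#'
#' Tunables of the datapoint-building stage. Defaults follow standard
#' practice for high-resolution ICU data: ABG timestamps are corrected to
#' the end of a pressure-waveform gap (>= 30 s) found within 15 min before
#' the laboratory timestamp; SpO2 and FiO2 are summarised as the median
#' over the window 5 to 2 minutes before the reference time; for
#' hourly-resolution data the nearest sample within 30 minutes is used
#' instead.
#'
#' @param gap_search_window Seconds before the nominal ABG time searched
#'   for a pressure gap (default 900).
#' @param gap_min_duration Minimum inter-sample gap counted as a blood
#'   draw, seconds (default 30).
#' @param median_window `c(start, end)`: the median is taken over samples
#'   in `[reference - start, reference - end]`, both ends closed
#'   (default `c(300, 120)`).
#' @param max_offset_minute_res Maximum offset for minute-resolution
#'   matching, seconds (default 300).
#' @param max_offset_hourly_res Maximum offset for hourly-resolution
#'   nearest-sample matching, seconds (default 1800).
#' @return An object of class `matching_policy`.
#' @export
matching_policy <- function(gap_search_window = 900, gap_min_duration = 30,
                            median_window = c(300, 120),
                            max_offset_minute_res = 300,
                            max_offset_hourly_res = 1800) {
  stopifnot(gap_search_window > 0, gap_min_duration > 0,
            length(median_window) == 2,
            median_window[1] > median_window[2], median_window[2] >= 0,
            max_offset_minute_res > 0, max_offset_hourly_res > 0)
  structure(
    list(gap_search_window = gap_search_window,
         gap_min_duration = gap_min_duration,
         median_window = median_window,
         max_offset_minute_res = max_offset_minute_res,
         max_offset_hourly_res = max_offset_hourly_res),
    class = "matching_policy"
  )
}

#' Correct an ABG timestamp using arterial-pressure gaps
#'
#' Blood draws interrupt the arterial pressure waveform; the end of the
#' interruption marks the true sampling time, which precedes the
#' laboratory timestamp. This returns the end of the latest inter-sample
#' gap of at least `gap_min_duration` seconds whose end lies within
#' `[nominal_time - gap_search_window, nominal_time]`, or `NA` when no
#' such gap exists (callers then fall back to the nominal time and the
#' median window).
#'
#' @param pressure A [channel_series()] sampled at roughly 1 Hz; may be
#'   empty.
#' @param nominal_time Laboratory ABG timestamp, seconds.
#' @param policy A [matching_policy()].
#' @return Corrected time in seconds, or `NA_real_`.
#' @export
detect_abg_time <- function(pressure, nominal_time,
                            policy = matching_policy()) {
  stopifnot(inherits(pressure, "channel_series"),
            inherits(policy, "matching_policy"))
  t <- pressure$times
  if (length(t) < 2) return(NA_real_)
  d <- diff(t)
  ends <- t[-1][d >= policy$gap_min_duration]
  ends <- ends[ends >= nominal_time - policy$gap_search_window &
                 ends <= nominal_time]
  if (!length(ends)) return(NA_real_)
  max(ends)
}

#' Windowed median of a channel
#'
#' Median of the samples with time in
#' `[reference_time - window[1], reference_time - window[2]]` (closed on
#' both ends); `NA` when the window holds no samples.
#'
#' @param series A [channel_series()].
#' @param reference_time Reference time in seconds.
#' @param window `c(start, end)` offsets in seconds before the reference.
#' @return The median value, or `NA_real_`.
#' @export
window_median <- function(series, reference_time, window = c(300, 120)) {
  stopifnot(inherits(series, "channel_series"), length(window) == 2,
            window[1] > window[2])
  sel <- series$times >= reference_time - window[1] &
    series$times <= reference_time - window[2]
  if (!any(sel)) return(NA_real_)
  stats::median(series$values[sel])
}

#' Nearest sample within a maximum offset
#'
#' Value of the sample minimising `|time - reference_time|`, provided that
#' minimum does not exceed `max_offset`; ties between an earlier and a
#' later sample resolve to the earlier one.
#'
#' @inheritParams window_median
#' @param max_offset Maximum allowed offset in seconds.
#' @return The sample value, or `NA_real_`.
#' @export
nearest_within <- function(series, reference_time, max_offset) {
  stopifnot(inherits(series, "channel_series"), max_offset > 0)
  if (!length(series$times)) return(NA_real_)
  off <- abs(series$times - reference_time)
  i <- which(off == min(off))[1] # ties -> earlier sample (times increasing)
  if (off[i] > max_offset) return(NA_real_)
  series$values[i]
}

locf_value <- function(series, reference_time) {
  sel <- which(series$times <= reference_time)
  if (!length(sel)) return(NA_real_)
  series$values[max(sel)]
}

#' Build time-matched datapoints from an admission
#'
#' Emits exactly one candidate datapoint per ABG event. The reference
#' time is the corrected draw time from [detect_abg_time()] when an
#' arterial-pressure channel is present and a gap is found, else the
#' nominal laboratory time. SpO2 and FiO2 are matched by [window_median()]
#' for high/minute-resolution admissions and by [nearest_within()] (30-min
#' tolerance) for hourly ones; because FiO2 is a ventilator setting that
#' may be recorded sparsely, an empty FiO2 median window falls back to the
#' last recorded setting at or before the reference time. Support mode,
#' PEEP and flow come from the interval covering the reference time.
#' Datapoints missing any of PaO2, SpO2 or FiO2 are emitted with
#' `exclusion_reason = "incomplete"`; all others pass through
#' [validity_filter()].
#'
#' @param admission An [admission_record()].
#' @param policy A [matching_policy()].
#' @return A datapoint tibble (see [datapoints()]).
#' @export
build_datapoints <- function(admission, policy = matching_policy()) {
  stopifnot(inherits(admission, "admission_record"),
            inherits(policy, "matching_policy"))
  abgs <- admission$abgs
  n <- nrow(abgs)
  spo2_ch <- admission$channels$spo2
  fio2_ch <- admission$channels$fio2
  abp <- admission$channels$abp
  hourly <- admission$resolution_class == "hourly"

  time <- pao2 <- spo2 <- fio2 <- sao2 <- paco2 <- rep(NA_real_, n)
  mode <- rep(NA_character_, n)
  peep <- flow <- rep(NA_real_, n)

  for (k in seq_len(n)) {
    ref <- abgs$time_s[k]
    if (!is.null(abp)) {
      corrected <- detect_abg_time(abp, ref, policy)
      if (!is.na(corrected)) ref <- corrected
    }
    time[k] <- ref
    pao2[k] <- abgs$pao2[k]
    sao2[k] <- abgs$sao2[k]
    paco2[k] <- abgs$paco2[k]
    if (hourly) {
      spo2[k] <- nearest_within(spo2_ch, ref, policy$max_offset_hourly_res)
      fio2[k] <- nearest_within(fio2_ch, ref, policy$max_offset_hourly_res)
    } else {
      spo2[k] <- window_median(spo2_ch, ref, policy$median_window)
      fio2[k] <- window_median(fio2_ch, ref, policy$median_window)
      if (is.na(fio2[k])) fio2[k] <- locf_value(fio2_ch, ref)
    }
    sup <- admission$support
    hit <- which(sup$start_s <= ref & ref < sup$end_s)
    if (length(hit)) {
      hit <- hit[1]
      mode[k] <- sup$mode[hit]
      peep[k] <- sup$peep[hit]
      flow[k] <- sup$flow[hit]
    } else {
      mode[k] <- "none"
    }
  }

  dp <- tibble::tibble(
    admission_id = rep(admission$admission_id, n),
    time = time, pao2 = pao2, spo2 = spo2, fio2 = fio2, sao2 = sao2,
    paco2 = paco2, mode = mode, peep = peep, flow = flow,
    valid = FALSE, exclusion_reason = "incomplete"
  )
  validity_filter(dp)
}

#' Apply the datapoint validity rules
#'
#' A datapoint is valid iff it is complete (PaO2, SpO2 and FiO2 all
#' present), its SpO2 does not exceed 97% (above which the saturation
#' ceiling makes the SF ratio uninformative), and it was measured during
#' invasive ventilation or NIV/CPAP with PEEP >= 5 cmH2O, or HFNO with
#' flow >= 30 L/min. Both boundaries are inclusive. The first failing rule
#' is recorded (completeness, then SpO2, then support); the filter is
#' idempotent and order-preserving.
#'
#' @param dp A datapoint tibble.
#' @return The same tibble with `valid` and `exclusion_reason` set.
#' @export
validity_filter <- function(dp) {
  req <- c("pao2", "spo2", "fio2")
  complete <- !Reduce(`|`, lapply(dp[req], is.na))
  spo2_ok <- !is.na(dp$spo2) & dp$spo2 <= 97
  support_ok <-
    (dp$mode %in% c("invasive_ventilation", "niv_cpap") &
       !is.na(dp$peep) & dp$peep >= 5) |
    (dp$mode == "hfno" & !is.na(dp$flow) & dp$flow >= 30)
  reason <- rep("none", nrow(dp))
  reason[!support_ok] <- "support_criteria"
  reason[!spo2_ok] <- "spo2_gt_97"
  reason[!complete] <- "incomplete"
  # precedence: incomplete > spo2_gt_97 > support_criteria
  dp$exclusion_reason <- reason
  dp$valid <- reason == "none"
  validate_datapoints(dp)
}
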