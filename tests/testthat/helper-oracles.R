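# Independent oracles used to cross-check package implementations.
# These deliberately avoid the code paths they verify.

# severity lookup by explicit if-chain (vs the cut()-based classifier)
oracle_classify <- function(value, scale) {
  th <- if (scale == "PF") c(100, 200, 300) else c(148, 235, 315)
  vapply(value, function(v) {
    if (v <= th[1]) "severe"
    else if (v <= th[2]) "moderate"
    else if (v <= th[3]) "mild"
    else "none"
  }, character(1))
}

# brute force over all adjacent pairs and all candidate categories
oracle_max_severity <- function(labels) {
  lv <- c("none", "mild", "moderate", "severe")
  idx <- match(labels, lv)
  n <- length(idx)
  if (n == 1) return(lv[idx])
  best <- "none"
  for (cand in seq_along(lv)) {
    ok <- FALSE
    for (i in seq_len(n - 1)) {
      if (idx[i] >= cand && idx[i + 1] >= cand) ok <- TRUE
    }
    if (ok) best <- lv[cand]
  }
  best
}

# exhaustive scan over every inter-sample gap
oracle_detect_gap <- function(times, nominal, window = 900, min_dur = 30) {
  best <- NA_real_
  for (i in seq_len(length(times) - 1)) {
    if (times[i + 1] - times[i] >= min_dur &&
        times[i + 1] >= nominal - window && times[i + 1] <= nominal) {
      if (is.na(best) || times[i + 1] > best) best <- times[i + 1]
    }
  }
  best
}

# small complete admission with fully controlled channels, for matching
# tests: SpO2/FiO2 sampled per minute, four ABGs, ventilated throughout
make_test_admission <- function(id = "adm-1", n_minutes = 240,
                                spo2 = 94, fio2 = 0.5,
                                abg_minutes = c(60, 120, 180, 230),
                                pao2 = 90, paco2 = 40,
                                resolution_class = "minute",
                                mode = "invasive_ventilation", peep = 8,
                                flow = NA_real_) {
  t <- (seq_len(n_minutes) - 1) * 60
  admission_record(
    id,
    channels = list(
      spo2 = channel_series("spo2", t, rep_len(spo2, n_minutes), "%"),
      fio2 = channel_series("fio2", t, rep_len(fio2, n_minutes), "fraction")
    ),
    support = tibble::tibble(start_s = 0, end_s = n_minutes * 60,
                             mode = mode, peep = peep, flow = flow),
    abgs = tibble::tibble(time_s = abg_minutes * 60,
                          pao2 = rep_len(pao2, length(abg_minutes)),
                          sao2 = NA_real_,
                          paco2 = rep_len(paco2, length(abg_minutes))),
    resolution_class = resolution_class
  )
}

# a pipeline configuration scaled down for unit tests
small_cfg <- function(seed = 31, n = 4, hours = 36) {
  cfg <- default_config(seed = seed)
  cfg$cohort <- cohort_config(n_admissions = n, duration_hours = hours,
                              seed = seed)
  cfg
}

# bare datapoint rows that already pass completeness, for filter tests
make_valid_dp <- function(n = 1, spo2 = 94, fio2 = 0.5, pao2 = 90,
                          mode = "invasive_ventilation", peep = 8,
                          flow = NA_real_, paco2 = 40, time = NULL) {
  datapoints(
    admission_id = rep_len("a", n),
    time = if (is.null(time)) seq_len(n) * 3600 else time,
    pao2 = rep_len(pao2, n), spo2 = rep_len(spo2, n),
    fio2 = rep_len(fio2, n), sao2 = rep_len(NA_real_, n),
    paco2 = rep_len(paco2, n), mode = rep_len(mode, n),
    peep = rep_len(peep, n), flow = rep_len(flow, n),
    exclusion_reason = rep_len("none", n)
  )
}
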