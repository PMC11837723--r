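pressure_with_gap <- function(total = 1800, gaps = list()) {
  t <- 0:total
  for (g in gaps) t <- t[!(t > g[1] & t < g[2])]
  channel_series("abp", t, rep(80, length(t)), "mmHg")
}

test_that("gap detection returns the end of the latest qualifying gap", {
  nominal <- 1800
  # gap spanning [t-420, t-360] -> corrected to t-360
  p <- pressure_with_gap(gaps = list(c(nominal - 420, nominal - 360)))
  expect_equal(detect_abg_time(p, nominal), nominal - 360)
  # no gap within the 15-min search window -> absent
  p2 <- pressure_with_gap(gaps = list(c(200, 300)))
  expect_true(is.na(detect_abg_time(p2, nominal)))
  # two qualifying gaps -> the later one
  p3 <- pressure_with_gap(gaps = list(c(nominal - 800, nominal - 700),
                                      c(nominal - 300, nominal - 200)))
  expect_equal(detect_abg_time(p3, nominal), nominal - 200)
  # sub-threshold interruptions are ignored
  p4 <- pressure_with_gap(gaps = list(c(nominal - 300, nominal - 280)))
  expect_true(is.na(detect_abg_time(p4, nominal)))
  # empty channel is absent, not an error
  empty <- channel_series("abp", numeric(0), numeric(0), "mmHg")
  expect_true(is.na(detect_abg_time(empty, nominal)))
})

test_that("window median handles odd, even and empty windows", {
  s <- channel_series("spo2", c(760, 820, 850), c(90, 92, 94), "%")
  expect_equal(window_median(s, 1000, c(300, 120)), 92)
  s2 <- channel_series("spo2", c(760, 850), c(90, 94), "%")
  expect_equal(window_median(s2, 1000, c(300, 120)), 92)
  expect_true(is.na(window_median(s, 5000, c(300, 120))))
  # window endpoints are closed
  s3 <- channel_series("spo2", c(700, 880), c(90, 94), "%")
  expect_equal(window_median(s3, 1000, c(300, 120)), 92)
})

test_that("nearest_within applies the offset cap and earlier-tie rule", {
  s <- channel_series("spo2", c(1000 - 1200, 1000 + 1200), c(91, 95), "%")
  expect_equal(nearest_within(s, 1000, 1800), 91)  # tie -> earlier
  far <- channel_series("spo2", 1000 + 2400, 95, "%")
  expect_true(is.na(nearest_within(far, 1000, 1800)))
  exact <- channel_series("spo2", c(500, 1000), c(91, 95), "%")
  expect_equal(nearest_within(exact, 1000, 1800), 95)
})

test_that("build_datapoints emits one datapoint per ABG", {
  adm <- make_test_admission()
  dp <- build_datapoints(adm)
  expect_equal(nrow(dp), 4)
  expect_true(all(dp$valid))
  expect_equal(dp$spo2, rep(94, 4))
  expect_equal(dp$fio2, rep(0.5, 4))
  expect_equal(dp$mode, rep("invasive_ventilation", 4))
})

test_that("a silent SpO2 channel makes the datapoint incomplete", {
  adm <- make_test_admission()
  # keep SpO2 samples only in the first hour; ABGs at 120/180/230 min lose it
  sp <- adm$channels$spo2
  keep <- sp$times < 3600
  adm$channels$spo2 <- channel_series("spo2", sp$times[keep],
                                      sp$values[keep], "%")
  dp <- build_datapoints(adm)
  expect_equal(dp$exclusion_reason, c("none", rep("incomplete", 3)))
  expect_equal(dp$valid, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("FiO2 falls back to the last recorded setting, SpO2 does not", {
  adm <- make_test_admission()
  # FiO2 recorded only once at t = 0 (a setting held constant)
  adm$channels$fio2 <- channel_series("fio2", 0, 0.5, "fraction")
  dp <- build_datapoints(adm)
  expect_true(all(dp$valid))
  expect_equal(dp$fio2, rep(0.5, 4))
})

test_that("hourly-resolution admissions match by nearest sample within 30 min", {
  t_hours <- seq(0, 4 * 3600, by = 3600)
  adm <- admission_record(
    "h1",
    channels = list(
      spo2 = channel_series("spo2", t_hours, rep(94, 5), "%"),
      fio2 = channel_series("fio2", t_hours, rep(0.5, 5), "fraction")
    ),
    support = tibble::tibble(start_s = 0, end_s = 5 * 3600,
                             mode = "invasive_ventilation", peep = 8,
                             flow = NA_real_),
    abgs = tibble::tibble(time_s = c(2 * 3600 + 25 * 60, 4 * 3600 + 40 * 60),
                          pao2 = c(90, 90), sao2 = NA_real_, paco2 = 40),
    resolution_class = "hourly"
  )
  dp <- build_datapoints(adm)
  expect_equal(dp$exclusion_reason, c("none", "incomplete"))  # 25 vs 40 min
})

test_that("corrected ABG times precede nominal times when gaps exist", {
  cfg <- cohort_config(n_admissions = 1, duration_hours = 6,
                       resolution_class = "high", seed = 1,
                       abg_interval_hours = c(1, 2))
  cfg$pressure$gap_prob <- 1
  adm <- simulate_admission(cfg, 1, seed = 11)
  dp <- build_datapoints(adm)
  expect_true(all(dp$time < adm$abgs$time_s))
})

test_that("validity filter applies the clinical rules with inclusive bounds", {
  expect_equal(validity_filter(make_valid_dp(spo2 = 98))$exclusion_reason,
               "spo2_gt_97")
  expect_equal(validity_filter(make_valid_dp(spo2 = 97))$exclusion_reason,
               "none")
  expect_equal(validity_filter(make_valid_dp(peep = 4))$exclusion_reason,
               "support_criteria")
  expect_equal(validity_filter(make_valid_dp(peep = 5))$exclusion_reason,
               "none")
  hf <- validity_filter(make_valid_dp(mode = "hfno", peep = NA_real_,
                                      flow = 30, spo2 = 95))
  expect_true(hf$valid)
  hf_low <- validity_filter(make_valid_dp(mode = "hfno", peep = NA_real_,
                                          flow = 29))
  expect_equal(hf_low$exclusion_reason, "support_criteria")
  off <- validity_filter(make_valid_dp(mode = "none", peep = NA_real_))
  expect_equal(off$exclusion_reason, "support_criteria")
})

test_that("validity filter is idempotent, order-preserving, partitioning", {
  dp <- dplyr::bind_rows(
    make_valid_dp(spo2 = 98), make_valid_dp(), make_valid_dp(peep = 3),
    make_valid_dp(mode = "hfno", peep = NA_real_, flow = 50)
  )
  once <- validity_filter(dp)
  twice <- validity_filter(once)
  expect_identical(once, twice)
  expect_equal(once$spo2, dp$spo2)  # order preserved
  expect_equal(sum(!once$valid),
               sum(table(once$exclusion_reason[!once$valid])))
})
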