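write_fixture_csvs <- function(dir, channel_rows, support_rows, abg_rows) {
  chp <- file.path(dir, "channels.csv")
  sup <- file.path(dir, "support.csv")
  abg <- file.path(dir, "abg.csv")
  writeLines(c("admission_id,channel,time_s,value,units", channel_rows), chp)
  writeLines(c("admission_id,start_s,end_s,mode,peep_cmh2o,flow_lpm",
               support_rows), sup)
  writeLines(c("admission_id,time_s,pao2_mmhg,sao2_frac,paco2_mmhg",
               abg_rows), abg)
  list(channels = chp, support = sup, abg = abg)
}

test_that("read_admission parses, sorts and collapses duplicates", {
  dir <- withr::local_tempdir()
  p <- write_fixture_csvs(
    dir,
    channel_rows = c(
      "a1,spo2,120,94,%",          # out of order on purpose
      "a1,spo2,0,95,%",
      "a1,spo2,60,95,%",
      "a1,spo2,60,97,%",           # duplicate timestamp -> median 96
      "a1,fio2,0,40,%"             # percent convention -> 0.40
    ),
    support_rows = "a1,0,7200,invasive_ventilation,8,",
    abg_rows = "a1,3600,90,0.96,40"
  )
  adm <- read_admission(p$channels, p$support, p$abg)
  expect_s3_class(adm, "admission_record")
  sp <- adm$channels$spo2
  expect_equal(sp$times, c(0, 60, 120))
  expect_equal(sp$values, c(95, 96, 94))
  expect_equal(adm$channels$fio2$values, 0.40)
  expect_equal(adm$abgs$pao2, 90)
  # reading twice yields identical records (sorting idempotent)
  expect_identical(adm, read_admission(p$channels, p$support, p$abg))
})

test_that("schema and parse errors name the offending column and row", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines(c("admission_id,channel,time_s,value",
               "a1,spo2,0,94"), bad)
  ok_sup <- file.path(dir, "s.csv")
  writeLines(c("admission_id,start_s,end_s,mode,peep_cmh2o,flow_lpm",
               "a1,0,100,invasive_ventilation,8,"), ok_sup)
  ok_abg <- file.path(dir, "a.csv")
  writeLines(c("admission_id,time_s,pao2_mmhg,sao2_frac,paco2_mmhg",
               "a1,50,90,,"), ok_abg)
  expect_error(read_admission(bad, ok_sup, ok_abg), "units")

  nonnum <- file.path(dir, "nn.csv")
  writeLines(c("admission_id,channel,time_s,value,units",
               "a1,spo2,0,94,%",
               "a1,spo2,60,oops,%"), nonnum)
  expect_error(read_admission(nonnum, ok_sup, ok_abg), "row 2")
})

test_that("FiO2 unit detection follows the percent/fraction rule", {
  expect_equal(normalize_fio2(c(40, 0.4, 1.0, 100)), c(0.4, 0.4, 1.0, 1.0))
  expect_error(normalize_fio2(0.1), "0.15")
})

test_that("datapoint tables round-trip losslessly through CSV", {
  dp <- datapoints(
    admission_id = c("a", "a", "b", "b", "b"),
    time = c(100, 200, 50, 60, 70),
    pao2 = c(90, 80, 100, NA, 70),
    spo2 = c(94, 98, 95, 93, 96),
    fio2 = c(0.5, 0.6, 0.4, 0.21, 1.0),
    sao2 = c(0.95, NA, 0.96, 0.94, 0.93),
    paco2 = c(40, 41, NA, 39, 44),
    mode = c("invasive_ventilation", "invasive_ventilation", "hfno",
             "none", "niv_cpap"),
    peep = c(8, 8, NA, NA, 5),
    flow = c(NA, NA, 45, NA, NA),
    exclusion_reason = c("none", "spo2_gt_97", "none", "incomplete",
                         "support_criteria")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  expect_equal(write_datapoints(dp, path), 5)
  back <- read_datapoints(path)
  expect_equal(as.data.frame(back), as.data.frame(dp))
  # absent sao2 survives as absent; booleans as true/false text
  raw <- readLines(path)
  expect_true(any(grepl(",true,", raw, fixed = TRUE)) ||
                any(grepl("true", raw)))
  expect_equal(write_datapoints(dp[0, ], path), 0)
})

test_that("config loading merges user values over defaults", {
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("trending:", "  ri_tolerance: 0.3",
               "physiology:", "  barometric_pressure: 700"), cfg_file)
  cfg <- load_config(cfg_file)
  expect_equal(cfg$trending$ri_tolerance, 0.3)
  expect_equal(cfg$trending$max_dt_hours, 6)       # untouched default
  expect_equal(cfg$physiology$barometric_pressure, 700)
  expect_equal(cfg$physiology$respiratory_quotient, 0.8)
})

test_that("core containers enforce their invariants", {
  expect_error(channel_series("x", c(0, 0), c(1, 2), "%"), "increasing")
  expect_error(channel_series("x", c(0, 1), c(1, Inf), "%"), "finite")
  expect_error(channel_series("x", c(0, 1), 1, "%"), "equal length")
  expect_error(support_intervals(10, 5, "invasive_ventilation", peep = 8),
               "start_s < end_s")
  expect_error(support_intervals(0, 10, "invasive_ventilation"), "peep")
  expect_error(support_intervals(0, 10, "hfno"), "flow")
  expect_error(
    support_intervals(c(0, 5), c(10, 20), c("none", "none")),
    "non-overlapping")
  expect_error(abg_events(0, -1), "positive")
  expect_error(abg_events(0, 90, sao2 = 1.2), "fraction")
  ch <- list(spo2 = channel_series("spo2", 0, 94, "%"))
  expect_error(
    admission_record("a", ch, support_intervals(0, 10, "none"),
                     abg_events(numeric(0), numeric(0))),
    "fio2")
})
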