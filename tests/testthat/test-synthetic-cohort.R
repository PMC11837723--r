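test_that("RI path is positive, deterministic, constant when noiseless", {
  cfg <- cohort_config(duration_hours = 5)
  cfg$ri$walk_sd_hourly <- 0
  cfg$ri$jump_prob_hourly <- 0
  set.seed(1); path <- simulate_ri_path(cfg)
  expect_equal(length(path), 300)
  expect_true(all(path$values > 0))
  expect_equal(stats::sd(path$values), 0) # constant when both noises off
  set.seed(7); p1 <- simulate_ri_path(cohort_config(duration_hours = 3))
  set.seed(7); p2 <- simulate_ri_path(cohort_config(duration_hours = 3))
  expect_identical(p1, p2)
})

test_that("hourly log-RI increments recover the configured walk sd", {
  cfg <- cohort_config(duration_hours = 10000)
  cfg$ri$jump_prob_hourly <- 0
  set.seed(44)
  path <- simulate_ri_path(cfg)
  hourly <- log(path$values[seq(1, length(path), by = 60)])
  expect_equal(stats::sd(diff(hourly)), cfg$ri$walk_sd_hourly,
               tolerance = 0.10)
})

test_that("RI path respects its reflecting bounds", {
  cfg <- cohort_config(duration_hours = 2000)
  set.seed(3)
  path <- simulate_ri_path(cfg)
  expect_true(all(path$values >= exp(cfg$ri$log_ri_min) - 1e-12))
  expect_true(all(path$values <= exp(cfg$ri$log_ri_max) + 1e-12))
})

test_that("oximeter model applies the bias line exactly when noiseless", {
  quiet <- oximeter_noise_model(sd = 0, rounding = FALSE)
  expect_equal(observe_spo2(94, quiet), 94)       # zero bias at crossing
  expect_equal(observe_spo2(90, quiet), 89)       # 90 + 0.25 * (90 - 94)
  expect_equal(observe_spo2(98, quiet), 99)
  expect_equal(observe_spo2(100, quiet), 100)     # clamped at ceiling
  rounded <- oximeter_noise_model(sd = 0)
  expect_equal(observe_spo2(90.3, rounded), round(90.3 + 0.25 * (90.3 - 94)))
  expect_error(observe_spo2(0, quiet), "percent")
})

test_that("noise-model parameters are recoverable from observed pairs", {
  set.seed(42)
  n <- 10000
  sat <- stats::runif(n, 85, 100)
  spo2 <- observe_spo2(sat)
  sao2 <- pmin(sat + stats::rnorm(n, 0, 0.5), 100)
  d <- spo2 - sao2
  expect_equal(stats::sd(d), 2.0, tolerance = 0.3 / 2.0)
  prof <- binned_bias_profile(spo2, sao2)
  expect_lt(abs(prof$crossing - 94), 1)
  # slope recovery away from the 100% ceiling (the validated range)
  sub <- sao2 <= 96
  slope <- stats::coef(stats::lm(d[sub] ~ sao2[sub]))[[2]]
  expect_equal(slope, 0.25, tolerance = 0.2)
  # bias is negative below and positive above the crossing
  expect_lt(mean(d[sao2 < 90]), 0)
  expect_gt(mean(d[sao2 > 96 & sao2 <= 99]), 0)
})

test_that("simulated admissions are internally consistent", {
  cfg <- cohort_config(n_admissions = 1, duration_hours = 24, seed = 5)
  adm <- simulate_admission(cfg, 1, seed = 123)
  expect_s3_class(adm, "admission_record")
  expect_true(all(c("spo2", "fio2") %in% names(adm$channels)))
  expect_true(all(adm$abgs$pao2 > 0))
  expect_true(all(adm$channels$fio2$values >= 0.21 &
                    adm$channels$fio2$values <= 1))
  # inter-ABG spacing respects the configured bounds (draws land on minutes)
  expect_true(all(diff(adm$abgs$time_s) >= cfg$abg_interval_hours[1] * 3600 - 60))
  # fixed seed -> byte-identical record
  expect_identical(adm, simulate_admission(cfg, 1, seed = 123))
})

test_that("disabling titration and flattening RI freezes the PF ratio", {
  cfg <- cohort_config(n_admissions = 1, duration_hours = 24, seed = 5,
                       sao2_noise_sd = 0,
                       policy = titration_policy(enabled = FALSE))
  cfg$ri$walk_sd_hourly <- 0
  cfg$ri$jump_prob_hourly <- 0
  cfg$paco2_sd <- 0
  adm <- simulate_admission(cfg, 1, seed = 9)
  pf <- adm$abgs$pao2 / adm$channels$fio2$values[1]
  expect_lt(stats::sd(pf) / mean(pf), 1e-12)
})

test_that("cohorts are deterministic and admissions independent", {
  cfg <- cohort_config(n_admissions = 4, duration_hours = 8, seed = 21)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  expect_length(simulate_cohort(cohort_config(n_admissions = 0)), 0)
  # regenerating admission 3 alone reproduces its cohort counterpart
  solo <- simulate_admission(cfg, 3, seed = derive_admission_seed(21, 3))
  expect_identical(c1[[3]], solo)
})

test_that("high-resolution admissions carry pressure gaps before ABGs", {
  cfg <- cohort_config(n_admissions = 1, duration_hours = 6,
                       resolution_class = "high", seed = 30,
                       abg_interval_hours = c(1, 2))
  cfg$pressure$gap_prob <- 1
  adm <- simulate_admission(cfg, 1, seed = 77)
  expect_true("abp" %in% names(adm$channels))
  expect_equal(adm$resolution_class, "high")
  # every nominal ABG time has a detectable gap shortly before it
  for (t in adm$abgs$time_s) {
    corrected <- detect_abg_time(adm$channels$abp, t)
    expect_false(is.na(corrected))
    expect_lt(corrected, t)
  }
})

test_that("sustained low FiO2 requirement liberates patients from support", {
  fio2 <- c(rep(0.5, 300), rep(0.3, 300), rep(0.6, 120))
  sup <- sfratio:::build_support_intervals(
    fio2, length(fio2),
    list(mode = "invasive_ventilation", peep = 8, flow = NA_real_,
         liberation_fio2 = 0.35, liberation_hours = 4))
  expect_equal(sup$mode, c("invasive_ventilation", "none",
                           "invasive_ventilation"))
  expect_equal(sup$start_s[2], 300 * 60)
  expect_equal(sup$end_s[2], 600 * 60)
  # short dips below the threshold do not liberate
  fio2b <- c(rep(0.5, 300), rep(0.3, 60), rep(0.6, 120))
  supb <- sfratio:::build_support_intervals(
    fio2b, length(fio2b),
    list(mode = "invasive_ventilation", peep = 8, flow = NA_real_,
         liberation_fio2 = 0.35, liberation_hours = 4))
  expect_equal(supb$mode, "invasive_ventilation")
})
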