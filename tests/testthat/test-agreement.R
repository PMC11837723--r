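test_that("confusion matrix counts reference/test label pairs", {
  m <- confusion(c("mild", "severe"), c("mild", "severe"))
  expect_equal(sum(diag(m)), 2)
  expect_equal(sum(m), 2)
  m2 <- confusion(c("mild", "severe"), c("moderate", "severe"))
  expect_equal(m2["mild", "moderate"], 1)
  expect_equal(m2["severe", "severe"], 1)
  m0 <- confusion(character(0), character(0))
  expect_equal(sum(m0), 0)
  expect_error(accuracy_and_recall(m0), "empty")
  expect_error(confusion("mild", c("mild", "severe")), "length")
  # marginals reproduce the label frequency tables
  set.seed(5)
  a <- sample(severity_levels, 200, replace = TRUE)
  b <- sample(severity_levels, 200, replace = TRUE)
  m3 <- confusion(a, b)
  expect_equal(as.numeric(rowSums(m3)),
               as.numeric(table(factor(a, severity_levels))))
  expect_equal(as.numeric(colSums(m3)),
               as.numeric(table(factor(b, severity_levels))))
})

test_that("accuracy and recall follow their definitions", {
  a <- rep(c("mild", "moderate"), c(6, 4))
  b <- c(rep("mild", 6), c("moderate", "mild", "mild", "mild"))
  res <- accuracy_and_recall(confusion(a, b))
  expect_equal(res$overall, 0.7)
  expect_equal(res$recall[["mild"]], 1)
  expect_equal(res$recall[["moderate"]], 0.25)
  expect_true(is.na(res$recall[["severe"]]))  # empty row -> absent, not 0
})

test_that("direction rates decompose the off-diagonal mass", {
  a <- c(rep("mild", 6), rep("moderate", 3), "severe")
  b <- c(rep("mild", 6), rep("severe", 3), "moderate")  # 3 over, 1 under
  m <- confusion(a, b)
  d <- direction_rates(m)
  expect_equal(d$over_rate, 0.3)
  expect_equal(d$under_rate, 0.1)
  expect_equal(d$over_share_misclassified, 0.75)
  acc <- accuracy_and_recall(m)$overall
  expect_equal(d$over_rate + d$under_rate + acc, 1)
  # transposing the matrix swaps over and under
  dt <- direction_rates(t(m))
  expect_equal(dt$over_rate, d$under_rate)
  expect_equal(dt$under_rate, d$over_rate)
  # all-diagonal case
  d0 <- direction_rates(confusion(a, a))
  expect_equal(d0$over_rate, 0)
  expect_true(is.na(d0$over_share_misclassified))
})

test_that("FiO2 bins are half-open with centers at multiples of 5%", {
  dp <- dplyr::bind_rows(
    make_valid_dp(fio2 = 0.675), # lower edge of the 70% bin
    make_valid_dp(fio2 = 0.674), # upper edge of the 65% bin
    make_valid_dp(fio2 = 0.50)
  )
  lab <- classify_datapoints(dp)
  bins <- fio2_binned_accuracy(lab)
  expect_equal(bins$center, c(50, 65, 70))
  expect_equal(bins$n, c(1, 1, 1))
  # single-bin all-concordant case
  one <- classify_datapoints(make_valid_dp(n = 5, fio2 = 0.5,
                                           pao2 = 90, spo2 = 94))
  expect_equal(fio2_binned_accuracy(one),
               tibble::tibble(center = 50, n = 5L, accuracy = 1))
})

test_that("pooled accuracy equals the n-weighted mean of bin accuracies", {
  cfg <- cohort_config(n_admissions = 6, duration_hours = 48, seed = 8)
  dp <- dplyr::bind_rows(lapply(simulate_cohort(cfg), build_datapoints))
  lab <- classify_datapoints(dp[dp$valid, ])
  bins <- fio2_binned_accuracy(lab)
  pooled <- mean(lab$pf_class == lab$sf_class)
  expect_equal(sum(bins$n * bins$accuracy) / sum(bins$n), pooled)
  expect_equal(sum(bins$n), nrow(lab))
})

test_that("pearson_r matches closed forms and rejects degenerate input", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 10)), "zero variance")
  expect_error(pearson_r(1, 2), "two complete")
  set.seed(9)
  expect_lt(abs(pearson_r(rnorm(10000), rnorm(10000))), 0.05)
})

test_that("bias and precision are the moments of the paired differences", {
  expect_equal(bias_precision(c(95, 94), c(95, 94)),
               list(bias = 0, precision = 0))
  bp <- bias_precision(c(95, 93), c(94, 94))  # differences +1, -1
  expect_equal(bp$bias, 0)
  expect_equal(bp$precision, sqrt(2), tolerance = 1e-12)
  expect_error(bias_precision(95, 94), "two pairs")
})

test_that("bias profile recovers the model crossing and sign structure", {
  set.seed(42)
  sat <- stats::runif(10000, 85, 100)
  spo2 <- observe_spo2(sat)
  sao2 <- pmin(sat + stats::rnorm(10000, 0, 0.5), 100)
  prof <- binned_bias_profile(spo2, sao2)
  expect_lt(abs(prof$crossing - 94), 1)
  expect_true(all(c("spo2_bin", "n", "mean_bias") %in% names(prof$profile)))
  # constant bias has no crossing; negation flips the profile
  base <- stats::runif(200, 85, 99)
  flat <- binned_bias_profile(base + 1, base)
  expect_true(is.na(flat$crossing))
  expect_true(all(abs(flat$profile$mean_bias - 1) < 1e-9))
})

test_that("curve deviation is zero on the curve and grows with noise", {
  p <- seq(40, 200, by = 5)
  expect_equal(curve_deviation(p, severinghaus_sao2(p)), 0)
  set.seed(3)
  noise <- stats::rnorm(5000, 0, 0.02)
  p2 <- stats::runif(5000, 40, 200)
  expect_equal(curve_deviation(p2, severinghaus_sao2(p2) + noise), 0.02,
               tolerance = 0.05)
})

test_that("agreement_report assembles consistent summaries", {
  cfg <- cohort_config(n_admissions = 5, duration_hours = 48, seed = 12)
  dp <- dplyr::bind_rows(lapply(simulate_cohort(cfg), build_datapoints))
  lab <- classify_datapoints(dp[dp$valid, ])
  rep <- agreement_report(lab, "datapoint")
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$n, nrow(lab))
  expect_equal(rep$over_rate + rep$under_rate + rep$overall_accuracy, 1)
  expect_equal(sum(rep$matrix), nrow(lab))
})
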