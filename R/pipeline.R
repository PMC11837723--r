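#' Run the full evaluation pipeline
#'
#' Orchestrates simulate -> match -> classify -> agreement -> trending ->
#' conversion from one configuration: simulates the synthetic cohort,
#' builds and filters time-matched datapoints, labels them on both
#' scales, aggregates admission-level severities under the
#' two-consecutive rule, and assembles agreement, trending, oximetry and
#' conversion analyses into a single machine-readable study report. The
#' report is a pure function of the configuration (including its seed):
#' running twice yields identical output.
#'
#' @param config A configuration list from [default_config()] or
#'   [load_config()].
#' @param out_dir Optional output directory; when given, intermediate
#'   CSVs (`datapoints.csv`, `labeled.csv`, `admissions.csv`) and
#'   `report.json` are written there.
#' @return A list of class `study_report`.
#' @examples
#' cfg <- default_config(seed = 7)
#' cfg$cohort <- cohort_config(n_admissions = 3, duration_hours = 12,
#'                             seed = 7)
#' rep <- run_pipeline(cfg)
#' rep$cohort_summary
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  consts <- do.call(physiology_constants, config$physiology)
  policy <- do.call(matching_policy, list(
    gap_search_window = config$matching$gap_search_window,
    gap_min_duration = config$matching$gap_min_duration,
    median_window = c(config$matching$median_window_start,
                      config$matching$median_window_end),
    max_offset_minute_res = config$matching$max_offset_minute_res,
    max_offset_hourly_res = config$matching$max_offset_hourly_res
  ))

  cohort <- simulate_cohort(config$cohort)
  dp <- dplyr::bind_rows(lapply(cohort, build_datapoints, policy = policy))
  if (!nrow(dp)) stop("pipeline produced no datapoints", call. = FALSE)

  valid <- dp[dp$valid, , drop = FALSE]
  labeled <- if (nrow(valid)) classify_datapoints(valid) else NULL

  # admission-level labels under the two-consecutive rule
  adm_tbl <- NULL
  if (!is.null(labeled) && nrow(labeled)) {
    labeled_sorted <- dplyr::arrange(labeled, admission_id, time)
    adm_tbl <- dplyr::summarise(
      dplyr::group_by(labeled_sorted, admission_id),
      n_datapoints = dplyr::n(),
      pf_class = admission_max_severity(pf_class),
      sf_class = admission_max_severity(sf_class),
      .groups = "drop"
    )
  }

  per_adm <- table(factor(dp$admission_id,
                          levels = vapply(cohort, `[[`, "", "admission_id")))
  report <- list(
    seed = config$seed,
    cohort_summary = list(
      admissions = length(cohort),
      datapoints_total = nrow(dp),
      datapoints_valid = nrow(valid),
      excluded_by_reason = as.list(table(
        dp$exclusion_reason[!dp$valid])),
      datapoints_per_admission_mean = mean(as.numeric(per_adm)),
      datapoints_per_admission_sd = stats::sd(as.numeric(per_adm))
    )
  )

  if (!is.null(labeled) && nrow(labeled)) {
    report$severity_distribution <- list(
      datapoint = list(
        PF = as.list(prop.table(table(labeled$pf_class))),
        SF = as.list(prop.table(table(labeled$sf_class)))
      )
    )
    report$agreement_datapoint <- agreement_report(
      labeled, "datapoint", config$agreement$fio2_bin_width)
    report$trending <- trend_report(
      labeled,
      max_dt_hours = config$trending$max_dt_hours,
      ri_tolerance = config$trending$ri_tolerance,
      ri_floor = config$trending$ri_floor,
      require_fio2_change = config$trending$require_fio2_change,
      constants = consts
    )
    has_sao2 <- dp[!is.na(dp$sao2) & !is.na(dp$spo2), , drop = FALSE]
    if (nrow(has_sao2) >= 2) {
      bp <- bias_precision(has_sao2$spo2, 100 * has_sao2$sao2)
      prof <- binned_bias_profile(has_sao2$spo2, 100 * has_sao2$sao2,
                                  config$agreement$bias_bin_width)
      report$oximetry <- list(
        n = nrow(has_sao2), bias = bp$bias, precision = bp$precision,
        bias_zero_crossing = prof$crossing,
        rms_from_curve_sao2 = curve_deviation(has_sao2$pao2, has_sao2$sao2),
        rms_from_curve_spo2 = curve_deviation(has_sao2$pao2,
                                              has_sao2$spo2 / 100)
      )
    }
    if (nrow(labeled) >= 3 && stats::sd(labeled$sf_ratio) > 0) {
      report$conversion <- conversion_table(labeled$sf_ratio,
                                            labeled$pf_ratio)
    }
  }

  if (!is.null(adm_tbl) && nrow(adm_tbl)) {
    report$severity_distribution$admission <- list(
      PF = as.list(prop.table(table(adm_tbl$pf_class))),
      SF = as.list(prop.table(table(adm_tbl$sf_class)))
    )
    report$agreement_admission <- agreement_report(adm_tbl, "admission")
  }

  report$config <- config_echo(config)
  class(report) <- "study_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_datapoints(dp, file.path(out_dir, "datapoints.csv"))
    if (!is.null(labeled)) {
      readr::write_csv(labeled, file.path(out_dir, "labeled.csv"),
                       na = "", progress = FALSE)
    }
    if (!is.null(adm_tbl)) {
      readr::write_csv(adm_tbl, file.path(out_dir, "admissions.csv"),
                       na = "", progress = FALSE)
    }
    jsonlite::write_json(report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# strip non-serialisable S3 pieces into plain lists for JSON output
config_echo <- function(config) {
  rapply(config, function(x) x, how = "list")
}

report_json <- function(report) {
  conv <- function(x) {
    if (inherits(x, "confusion_matrix") || (is.matrix(x) && !is.list(x))) {
      return(list(labels_rows = rownames(x), labels_cols = colnames(x),
                  counts = unclass(x)))
    }
    if (is.factor(x)) return(as.character(x))
    if (inherits(x, "tbl_df")) return(as.list(x))
    if (is.list(x)) return(lapply(x, conv))
    x
  }
  lapply(unclass(report), conv)
}

#' @export
print.study_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("<study_report> %d admissions, %d datapoints (%d valid)\n",
              cs$admissions, cs$datapoints_total, cs$datapoints_valid))
  cat(sprintf("  datapoints per admission %.1f +/- %.1f\n",
              cs$datapoints_per_admission_mean,
              cs$datapoints_per_admission_sd))
  if (!is.null(x$agreement_datapoint)) {
    cat(sprintf("  datapoint accuracy %.1f%%",
                100 * x$agreement_datapoint$overall_accuracy))
    if (!is.null(x$agreement_admission)) {
      cat(sprintf("; admission accuracy %.1f%%",
                  100 * x$agreement_admission$overall_accuracy))
    }
    cat("\n")
  }
  if (!is.null(x$trending) && !is.na(x$trending$detection_rate)) {
    cat(sprintf("  trend detection rate %.1f%%\n",
                100 * x$trending$detection_rate))
  }
  invisible(x)
}
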