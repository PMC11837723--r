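#' Read one admission from the long-format CSV schemas
#'
#' Reads the three per-admission tables — long-format channel samples,
#' support intervals and ABG events — and assembles a validated
#' [admission_record()]. Channel rows out of time order are sorted;
#' duplicated timestamps within a channel are collapsed to their median.
#' FiO2 values are normalised to fractions: values above 1 are taken to be
#' percentages and divided by 100; values in [0.15, 1] are fractions;
#' values below 0.15 are rejected as neither convention.
#'
#' Schemas (UTF-8, "." decimal, header required):
#' * channels: `admission_id, channel, time_s, value, units`
#' * support:  `admission_id, start_s, end_s, mode, peep_cmh2o, flow_lpm`
#' * abg:      `admission_id, time_s, pao2_mmhg, sao2_frac, paco2_mmhg`
#'
#' @param channel_csv_path,support_csv_path,abg_csv_path File paths.
#' @param admission_id Which admission to read when the files hold several;
#'   may be omitted when they hold exactly one.
#' @param resolution_class Passed through to [admission_record()].
#' @return An [admission_record()].
#' @export
read_admission <- function(channel_csv_path, support_csv_path, abg_csv_path,
                           admission_id = NULL,
                           resolution_class = c("minute", "high", "hourly")) {
  resolution_class <- match.arg(resolution_class)
  ch <- read_schema_csv(channel_csv_path,
                        c("admission_id", "channel", "time_s", "value", "units"),
                        numeric_cols = c("time_s", "value"))
  sup <- read_schema_csv(support_csv_path,
                         c("admission_id", "start_s", "end_s", "mode",
                           "peep_cmh2o", "flow_lpm"),
                         numeric_cols = c("start_s", "end_s", "peep_cmh2o",
                                          "flow_lpm"))
  abg <- read_schema_csv(abg_csv_path,
                         c("admission_id", "time_s", "pao2_mmhg", "sao2_frac",
                           "paco2_mmhg"),
                         numeric_cols = c("time_s", "pao2_mmhg", "sao2_frac",
                                          "paco2_mmhg"))
  ids <- unique(c(ch$admission_id, sup$admission_id, abg$admission_id))
  if (is.null(admission_id)) {
    if (length(ids) != 1) {
      stop("files contain ", length(ids),
           " admissions; supply `admission_id`", call. = FALSE)
    }
    admission_id <- ids
  }
  ch <- ch[ch$admission_id == admission_id, , drop = FALSE]
  sup <- sup[sup$admission_id == admission_id, , drop = FALSE]
  abg <- abg[abg$admission_id == admission_id, , drop = FALSE]
  if (!nrow(ch)) {
    stop("no channel rows for admission ", admission_id, call. = FALSE)
  }

  channels <- lapply(split(ch, ch$channel), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    name <- d$channel[1]
    values <- d$value
    if (name == "fio2") values <- normalize_fio2(values)
    # collapse duplicate timestamps to their median
    if (anyDuplicated(d$time_s)) {
      values <- as.numeric(tapply(values, d$time_s, stats::median))
      times <- sort(unique(d$time_s))
    } else {
      times <- d$time_s
    }
    units <- if (name == "fio2") "fraction" else d$units[1]
    channel_series(name, times, values, units)
  })

  support <- tibble::tibble(
    start_s = sup$start_s, end_s = sup$end_s, mode = sup$mode,
    peep = sup$peep_cmh2o, flow = sup$flow_lpm
  )
  abgs <- tibble::tibble(
    time_s = abg$time_s, pao2 = abg$pao2_mmhg, sao2 = abg$sao2_frac,
    paco2 = abg$paco2_mmhg
  )
  admission_record(admission_id, channels, support, abgs, resolution_class)
}

read_schema_csv <- function(path, required_cols, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(required_cols, names(tbl))
  if (length(missing_cols)) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in numeric_cols) {
    raw <- tbl[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
    if (length(bad)) {
      stop("parse error in ", basename(path), ", column `", col, "`, row ",
           bad[1], ": non-numeric value \"", raw[bad[1]], "\"", call. = FALSE)
    }
    parsed[!is.na(raw) & raw == ""] <- NA_real_
    tbl[[col]] <- parsed
  }
  tbl
}

#' Normalise FiO2 values to fractions
#'
#' Values above 1.0 are treated as percentages and divided by 100; values
#' in [0.15, 1.0] pass through as fractions; values below 0.15 are rejected
#' (below any plausible inspired oxygen fraction under either convention).
#'
#' @param x Numeric FiO2 values in either convention.
#' @return FiO2 as fractions.
#' @export
normalize_fio2 <- function(x) {
  bad <- which(!is.na(x) & x < 0.15)
  if (length(bad)) {
    stop("FiO2 value ", x[bad[1]],
         " below 0.15: not a valid fraction or percent", call. = FALSE)
  }
  ifelse(!is.na(x) & x > 1, x / 100, x)
}

#' Write / read a flat datapoint table
#'
#' One row per datapoint, all fields, booleans serialised as `true`/`false`,
#' absent optional values as empty fields. The pair round-trips losslessly.
#'
#' @param dp A datapoint table ([datapoints()]).
#' @param path Output CSV path.
#' @return `write_datapoints()` returns the number of rows written,
#'   invisibly `read_datapoints()` returns the datapoint tibble.
#' @export
write_datapoints <- function(dp, path) {
  dp <- validate_datapoints(dp)
  out <- dp
  out$valid <- ifelse(dp$valid, "true", "false")
  readr::write_csv(out, path, na = "", progress = FALSE)
  nrow(dp)
}

#' @rdname write_datapoints
#' @export
read_datapoints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      admission_id = "c", mode = "c", exclusion_reason = "c",
      valid = "c", .default = "d"
    ),
    progress = FALSE
  )
  tbl$valid <- tbl$valid == "true"
  validate_datapoints(tibble::as_tibble(tbl))
}

#' Load and merge an analysis configuration
#'
#' `default_config()` returns the full set of tunables for every pipeline
#' stage; `load_config()` reads a YAML (or JSON) file and merges it over
#' the defaults, so a user file only needs the keys it changes.
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return A nested named list of configuration values.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, override) {
  if (!is.list(override)) return(override)
  for (key in names(override)) {
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]])
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' @rdname load_config
#' @param seed Master random seed recorded in the configuration.
#' @export
default_config <- function(seed = 2026L) {
  list(
    seed = as.integer(seed),
    physiology = list(
      barometric_pressure = 760, water_vapor_pressure = 47,
      respiratory_quotient = 0.8
    ),
    cohort = cohort_config(seed = seed),
    matching = list(
      gap_search_window = 900, gap_min_duration = 30,
      median_window_start = 300, median_window_end = 120,
      max_offset_minute_res = 300, max_offset_hourly_res = 1800
    ),
    trending = list(
      max_dt_hours = 6, ri_tolerance = 0.20, ri_floor = 0.05,
      require_fio2_change = TRUE
    ),
    agreement = list(fio2_bin_width = 5, bias_bin_width = 1)
  )
}
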