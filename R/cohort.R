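#' Pulse-oximeter measurement-error model
#'
#' SpO2 is modelled as the true saturation plus a bias linear in
#' saturation — negative below and positive above a crossing point — plus
#' Gaussian noise, rounded to integer percent (as bedside monitors report)
#' and clamped to (0, `clamp_high`]:
#' \deqn{SpO_2 = round(SaO_2 + slope (SaO_2 - crossing) + \epsilon),\quad
#'   \epsilon \sim N(0, sd^2)}
#' The defaults (crossing 94\%, sd 2.0\%) reproduce the heteroscedastic
#' bias pattern reported for real oximeters: bias crossing zero near 94\%
#' saturation with an overall precision near 2\%.
#'
#' @param bias_slope Bias per percent of saturation distance from the
#'   crossing (default 0.25).
#' @param bias_crossing Saturation (percent) where the bias changes sign
#'   (default 94).
#' @param sd Noise standard deviation in percent (default 2.0).
#' @param rounding Round to integer percent? (default `TRUE`).
#' @param clamp_high Upper clamp in percent (default 100).
#' @return An object of class `oximeter_noise_model`.
#' @export
oximeter_noise_model <- function(bias_slope = 0.25, bias_crossing = 94,
                                 sd = 2.0, rounding = TRUE,
                                 clamp_high = 100) {
  stopifnot(sd >= 0, bias_crossing > 50, bias_crossing < 100, clamp_high > 0)
  structure(
    list(bias_slope = bias_slope, bias_crossing = bias_crossing, sd = sd,
         rounding = rounding, clamp_high = clamp_high),
    class = "oximeter_noise_model"
  )
}

#' Observe SpO2 through the oximeter noise model
#'
#' @param sao2 True saturation in percent, in (0, 100].
#' @param model An [oximeter_noise_model()].
#' @param eps Optional pre-drawn noise vector (same length as `sao2`);
#'   drawn internally from `N(0, sd^2)` when `NULL`. Supplying it lets a
#'   simulator reuse one noise stream across passes.
#' @return Observed SpO2 in percent.
#' @examples
#' set.seed(1)
#' observe_spo2(94, oximeter_noise_model(sd = 0, rounding = FALSE)) # 94
#' @export
observe_spo2 <- function(sao2, model = oximeter_noise_model(), eps = NULL) {
  stopifnot(inherits(model, "oximeter_noise_model"))
  if (any(sao2 <= 0) || any(sao2 > 100)) {
    stop("`sao2` must lie in (0, 100] percent", call. = FALSE)
  }
  if (is.null(eps)) {
    eps <- if (model$sd > 0) stats::rnorm(length(sao2), 0, model$sd) else 0
  }
  spo2 <- sao2 + model$bias_slope * (sao2 - model$bias_crossing) + eps
  if (model$rounding) spo2 <- round(spo2)
  pmin(pmax(spo2, 1), model$clamp_high)
}

#' Clinician FiO2 titration policy
#'
#' The simulator's embodiment of bedside oxygen titration: at each review,
#' FiO2 is stepped up when the observed SpO2 sits below the target band and
#' stepped down when it sits above, within [`fio2_min`, `fio2_max`]. The
#' asymmetric steps (larger up than down) mirror the clinical priority of
#' escaping hypoxemia quickly and weaning cautiously.
#'
#' @param target_low,target_high SpO2 target band in percent (defaults
#'   94, 98 — the band most commonly prescribed outside conservative-
#'   oxygenation protocols; under median-based review it induces a
#'   cohort mean saturation near 96\%, the level implied by a +0.5\%
#'   mean oximeter bias with a 94\% zero-crossing and 0.25/% slope).
#' @param step_up,step_down FiO2 step sizes as fractions (defaults 0.10,
#'   0.05).
#' @param review_interval Seconds between titration reviews (default 900).
#' @param fio2_min,fio2_max FiO2 bounds (defaults 0.21, 1.0).
#' @param enabled Set `FALSE` to hold FiO2 fixed at its initial value.
#' @return An object of class `titration_policy`.
#' @export
titration_policy <- function(target_low = 94, target_high = 98,
                             step_up = 0.10, step_down = 0.05,
                             review_interval = 900,
                             fio2_min = 0.21, fio2_max = 1.0,
                             enabled = TRUE) {
  stopifnot(target_low < target_high, step_up > 0, step_down > 0,
            review_interval > 0, fio2_min >= 0.21, fio2_max <= 1.0,
            fio2_min < fio2_max)
  structure(
    list(target_low = target_low, target_high = target_high,
         step_up = step_up, step_down = step_down,
         review_interval = review_interval,
         fio2_min = fio2_min, fio2_max = fio2_max, enabled = enabled),
    class = "titration_policy"
  )
}

#' Synthetic-cohort configuration
#'
#' All tunables of the cohort generator. The generator emulates the
#' statistical structure of high-resolution ICU databases: a latent
#' gas-exchange state (Respiratory Index) following a geometric random
#' walk with occasional worsening jumps, clinician FiO2 titration toward
#' an SpO2 target band, heteroscedastic oximeter error, intermittent ABG
#' sampling, and (for high-resolution admissions) a 1-Hz arterial-pressure
#' channel with gaps at blood draws.
#'
#' @param n_admissions Number of admissions (default 200).
#' @param duration_hours Admission length in hours (default 72).
#' @param resolution_class `"high"`, `"minute"` or `"hourly"`; recycled to
#'   `n_admissions` (default `"minute"`).
#' @param ri Respiratory-Index process: `log_ri_mean`/`log_ri_sd` for the
#'   initial state (defaults 1.2, 0.55 — under titration this spans the
#'   no-ARDS to severe range with a datapoint severity mix resembling
#'   published ARDS cohorts), `walk_sd_hourly` for the hourly log-RI
#'   random-walk standard deviation (default 0.10), `jump_prob_hourly`
#'   and `jump_log_magnitude` for upward worsening jumps (defaults 0.01,
#'   `log(1.5)`), and reflecting bounds `log_ri_min`/`log_ri_max`
#'   (defaults `log(0.05)`, `log(12)`): gas exchange worse than RI ~12
#'   means refractory hypoxemia on pure oxygen, a state managed with
#'   extracorporeal support and excluded from the emulated population.
#' @param abg_interval_hours Bounds of the uniform inter-ABG interval
#'   (default `c(2, 6)` hours, giving roughly 18 ABGs over 72 h).
#' @param paco2_mean,paco2_sd,paco2_range PaCO2 draws per ABG, mmHg:
#'   Normal(42, 5) clamped to [25, 80].
#' @param sao2_noise_sd Co-oximeter noise on recorded SaO2, as a saturation
#'   fraction (default 0.005).
#' @param pressure Pressure-waveform model for high-resolution admissions:
#'   `gap_prob` that a blood draw leaves a detectable gap (default 0.9),
#'   `gap_duration_s` bounds (default `c(30, 90)`), `lab_delay_s` bounds
#'   between draw and laboratory timestamp (default `c(120, 600)`).
#' @param noise An [oximeter_noise_model()].
#' @param policy A [titration_policy()].
#' @param support Respiratory support model: a list with `mode`, `peep`,
#'   `flow` (default invasive ventilation, PEEP 8) plus a liberation
#'   rule — patients whose FiO2 requirement stays at or below
#'   `liberation_fio2` for `liberation_hours` consecutive hours are
#'   liberated from the support (mode `"none"`) until the requirement
#'   rises again. This mirrors ICU weaning practice (a sustained
#'   requirement at or below roughly 0.35-0.40 is a standard
#'   spontaneous-breathing-trial / extubation criterion) and
#'   matters structurally: measurements taken off qualifying support are
#'   excluded by the validity filter, so a generator without liberation
#'   would over-produce near-room-air datapoints that real cohorts do
#'   not contain. Set `liberation_fio2 = 0` to disable.
#' @param seed Master seed; per-admission seeds are derived from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_admissions = 200,
                          duration_hours = 72,
                          resolution_class = "minute",
                          ri = list(log_ri_mean = 1.2, log_ri_sd = 0.55,
                                    walk_sd_hourly = 0.10,
                                    jump_prob_hourly = 0.01,
                                    jump_log_magnitude = log(1.5),
                                    log_ri_min = log(0.05),
                                    log_ri_max = log(12)),
                          abg_interval_hours = c(2, 6),
                          paco2_mean = 42, paco2_sd = 5,
                          paco2_range = c(25, 80),
                          sao2_noise_sd = 0.005,
                          pressure = list(gap_prob = 0.9,
                                          gap_duration_s = c(30, 90),
                                          lab_delay_s = c(120, 600)),
                          noise = oximeter_noise_model(),
                          policy = titration_policy(),
                          support = list(mode = "invasive_ventilation",
                                         peep = 8, flow = NA_real_,
                                         liberation_fio2 = 0.35,
                                         liberation_hours = 4),
                          seed = 2026L) {
  stopifnot(n_admissions >= 0, duration_hours > 0,
            all(resolution_class %in% c("high", "minute", "hourly")),
            ri$log_ri_sd >= 0, ri$walk_sd_hourly >= 0,
            ri$jump_prob_hourly >= 0, ri$jump_prob_hourly <= 1,
            length(abg_interval_hours) == 2,
            abg_interval_hours[1] > 0,
            abg_interval_hours[1] <= abg_interval_hours[2],
            paco2_sd >= 0, sao2_noise_sd >= 0,
            pressure$gap_prob >= 0, pressure$gap_prob <= 1,
            inherits(noise, "oximeter_noise_model"),
            inherits(policy, "titration_policy"))
  structure(
    list(n_admissions = as.integer(n_admissions),
         duration_hours = duration_hours,
         resolution_class = resolution_class, ri = ri,
         abg_interval_hours = abg_interval_hours,
         paco2_mean = paco2_mean, paco2_sd = paco2_sd,
         paco2_range = paco2_range, sao2_noise_sd = sao2_noise_sd,
         pressure = pressure, noise = noise, policy = policy,
         support = support, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate a Respiratory-Index path
#'
#' Geometric random walk of the Respiratory Index at one-minute
#' resolution: the log-RI takes independent Gaussian increments with
#' per-minute standard deviation `walk_sd_hourly / sqrt(60)` (so hourly
#' log-increments have the configured standard deviation) plus occasional
#' upward jumps modelling acute worsening. The walk is folded back at the
#' reflecting bounds `log_ri_min`/`log_ri_max`, which keeps RI inside the
#' clinically survivable (non-ECMO) range while preserving increment
#' magnitudes away from the bounds. RI stays strictly positive by
#' construction.
#'
#' @param config A [cohort_config()]; only the `duration_hours` and `ri`
#'   entries are used.
#' @return A [channel_series()] named `"ri"` at 1-minute resolution.
#'   Consumes the R random number stream; seed with `set.seed()`.
#' @export
simulate_ri_path <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  m <- as.integer(round(config$duration_hours * 60))
  stopifnot(m >= 1)
  p <- config$ri
  log_ri0 <- stats::rnorm(1, p$log_ri_mean, p$log_ri_sd)
  inc <- if (m > 1) {
    stats::rnorm(m - 1, 0, p$walk_sd_hourly / sqrt(60))
  } else {
    numeric(0)
  }
  if (p$jump_prob_hourly > 0 && m > 1) {
    jumps <- stats::rbinom(m - 1, 1, min(p$jump_prob_hourly / 60, 1))
    inc <- inc + jumps * p$jump_log_magnitude
  }
  log_ri <- reflect_into(log_ri0 + c(0, cumsum(inc)),
                         p$log_ri_min, p$log_ri_max)
  channel_series("ri", (seq_len(m) - 1) * 60, exp(log_ri), "dimensionless")
}

# fold x into [lo, hi] by reflection at both bounds
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y <= w, y, 2 * w - y)
}

derive_admission_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + index * 104729) %% 2147483629)
}

#' Simulate one ICU admission
#'
#' Generates an internally consistent [admission_record()]: at each
#' minute the true PaO2 follows from the latent Respiratory Index, the
#' current FiO2 setting and PaCO2 via the alveolar gas equation
#' ([pao2_given_ri()]); the true saturation follows the Severinghaus
#' curve; the SpO2 channel is the true saturation observed through the
#' oximeter noise model; and FiO2 follows the titration policy evaluated
#' on the observed SpO2 at each review. ABGs are drawn at random
#' intervals and record exact PaO2, co-oximeter-noised SaO2 and the PaCO2
#' current at the draw (PaCO2 is redrawn i.i.d. at each ABG and held
#' between draws). High-resolution admissions additionally carry a 1-Hz
#' arterial-pressure channel with a gap ending at each blood-draw time
#' (with configured probability) and lab timestamps delayed relative to
#' the draw; for minute/hourly admissions the nominal ABG time is the
#' draw time.
#'
#' @param config A [cohort_config()].
#' @param admission_index Integer index used for the admission id.
#' @param seed Optional seed applied before simulation (as
#'   [simulate_cohort()] does); `NULL` uses the current RNG state.
#' @return An [admission_record()].
#' @export
simulate_admission <- function(config, admission_index = 1L, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  res <- rep(config$resolution_class,
             length.out = max(admission_index, 1))[admission_index]
  m <- as.integer(round(config$duration_hours * 60))
  minute_t <- (seq_len(m) - 1) * 60
  consts <- physiology_constants()

  # 1) ABG draw schedule (whole minutes, first draw >= 1 h in)
  lo <- config$abg_interval_hours[1]
  hi <- config$abg_interval_hours[2]
  t_h <- max(1, stats::runif(1, lo / 2, hi))
  abg_minutes <- integer(0)
  while (t_h * 60 < m - 1) {
    abg_minutes <- c(abg_minutes, as.integer(round(t_h * 60)))
    t_h <- t_h + stats::runif(1, lo, hi)
  }
  abg_minutes <- abg_minutes[abg_minutes >= 10 & abg_minutes <= m - 1]
  n_abg <- length(abg_minutes)

  # 2) PaCO2: one initial value plus one redraw per ABG, held between draws
  v_paco2 <- pmin(pmax(stats::rnorm(n_abg + 1, config$paco2_mean,
                                    config$paco2_sd),
                       config$paco2_range[1]), config$paco2_range[2])
  paco2_min <- v_paco2[findInterval(seq_len(m) - 1, abg_minutes) + 1]

  # 3) Latent gas-exchange state
  ri <- simulate_ri_path(config)$values

  # 4) Oximeter noise stream shared by titration and channel emission
  eps <- stats::rnorm(m, 0, config$noise$sd)

  # 5) FiO2 titration (sequential over review blocks). The review decision
  # uses the median of the last five minutes of observed SpO2, not a
  # single reading: clinicians act on sustained values, and a controller
  # driven by single noisy readings chatters in FiO2 and rides the lower
  # half of the target band.
  pol <- config$policy
  pb <- consts$barometric_pressure - consts$water_vapor_pressure
  f0 <- (severinghaus_pao2(0.94) * (1 + ri[1]) +
           paco2_min[1] / consts$respiratory_quotient) / pb
  f <- min(max(round(f0 / 0.05) * 0.05, pol$fio2_min), pol$fio2_max)
  fio2_min_vec <- numeric(m)
  pao2_truth <- sat_truth <- spo2_obs <- numeric(m)
  block <- max(1L, as.integer(round(pol$review_interval / 60)))
  starts <- seq(1L, m, by = block)
  for (s in starts) {
    e <- min(s + block - 1L, m)
    ix <- s:e
    fio2_min_vec[ix] <- f
    pao2_truth[ix] <- pao2_given_ri(ri[ix], f, paco2_min[ix], consts)
    sat_truth[ix] <- severinghaus_sao2(pao2_truth[ix])
    spo2_obs[ix] <- observe_spo2(pmin(100 * sat_truth[ix], 100),
                                 config$noise, eps = eps[ix])
    if (pol$enabled) {
      obs <- stats::median(spo2_obs[max(s, e - 4L):e])
      if (obs < pol$target_low) {
        f <- min(f + pol$step_up, pol$fio2_max)
      } else if (obs > pol$target_high) {
        f <- max(f - pol$step_down, pol$fio2_min)
      }
    }
  }

  channels <- list()
  if (res == "high") {
    n_s <- m * 60L
    sec_t <- seq_len(n_s) - 1
    sat_s <- rep(sat_truth, each = 60)
    spo2_s <- observe_spo2(pmin(100 * sat_s, 100), config$noise,
                           eps = stats::rnorm(n_s, 0, config$noise$sd))
    channels$spo2 <- channel_series("spo2", sec_t, spo2_s, "%")
    channels$fio2 <- channel_series("fio2", minute_t, fio2_min_vec,
                                    "fraction")
    abp_vals <- 80 + stats::rnorm(n_s, 0, 3)
    channels$abp <- list(times = sec_t, values = abp_vals) # gaps cut below
  } else if (res == "minute") {
    channels$spo2 <- channel_series("spo2", minute_t, spo2_obs, "%")
    channels$fio2 <- channel_series("fio2", minute_t, fio2_min_vec,
                                    "fraction")
  } else {
    idx <- seq(1L, m, by = 60L)
    channels$spo2 <- channel_series("spo2", minute_t[idx], spo2_obs[idx], "%")
    channels$fio2 <- channel_series("fio2", minute_t[idx],
                                    fio2_min_vec[idx], "fraction")
  }

  # 7) ABG events (recorded values) and pressure gaps / lab delays
  draw_s <- abg_minutes * 60
  sao2_rec <- pmin(pmax(sat_truth[abg_minutes + 1] +
                          stats::rnorm(n_abg, 0, config$sao2_noise_sd),
                        0.5), 1)
  nominal_s <- as.numeric(draw_s)
  if (res == "high") {
    pr <- config$pressure
    has_gap <- stats::runif(n_abg) < pr$gap_prob
    gap_dur <- stats::runif(n_abg, pr$gap_duration_s[1], pr$gap_duration_s[2])
    delay <- stats::runif(n_abg, pr$lab_delay_s[1], pr$lab_delay_s[2])
    nominal_s <- draw_s + delay
    keep <- rep(TRUE, length(channels$abp$times))
    for (k in seq_len(n_abg)) {
      if (has_gap[k]) {
        keep <- keep & !(channels$abp$times > draw_s[k] - gap_dur[k] &
                           channels$abp$times < draw_s[k])
      }
    }
    channels$abp <- channel_series("abp", channels$abp$times[keep],
                                   channels$abp$values[keep], "mmHg")
  }
  abgs <- tibble::tibble(
    time_s = nominal_s,
    pao2 = pao2_truth[abg_minutes + 1],
    sao2 = sao2_rec,
    paco2 = v_paco2[seq_len(n_abg) + 1]
  )

  support <- build_support_intervals(fio2_min_vec, m, config$support)
  admission_record(sprintf("sim-%04d", admission_index), channels, support,
                   abgs, res)
}

# support intervals with liberation: stretches where the FiO2 requirement
# stays <= liberation_fio2 for >= liberation_hours become mode "none"
build_support_intervals <- function(fio2_min_vec, m, sup) {
  lib_f <- if (is.null(sup$liberation_fio2)) 0 else sup$liberation_fio2
  lib_h <- if (is.null(sup$liberation_hours)) Inf else sup$liberation_hours
  low <- fio2_min_vec <= lib_f
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  liberated <- r$values & r$lengths >= lib_h * 60
  on_support <- rep(TRUE, m)
  for (k in which(liberated)) on_support[starts[k]:ends[k]] <- FALSE
  r2 <- rle(on_support)
  ends2 <- cumsum(r2$lengths)
  starts2 <- ends2 - r2$lengths + 1
  tibble::tibble(
    start_s = (starts2 - 1) * 60,
    end_s = ends2 * 60,
    mode = ifelse(r2$values, sup$mode, "none"),
    peep = ifelse(r2$values, as.numeric(sup$peep), NA_real_),
    flow = ifelse(r2$values, as.numeric(sup$flow), NA_real_)
  )
}

#' Simulate a cohort of admissions
#'
#' Each admission is simulated under its own seed derived from the master
#' seed, so cohorts are fully deterministic and admissions are mutually
#' independent (regenerating any single admission never perturbs the
#' others).
#'
#' @param config A [cohort_config()].
#' @return A list of [admission_record()] objects of length
#'   `config$n_admissions`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_admissions = 2,
#'                                         duration_hours = 6))
#' cohort[[1]]
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lapply(seq_len(config$n_admissions), function(i) {
    simulate_admission(config, i, seed = derive_admission_seed(config$seed, i))
  })
}
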