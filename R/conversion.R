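#' An SF/PF imputation equation
#'
#' Linear form: `out = intercept + slope * in`; log-linear form:
#' `ln(out) = intercept + slope * ln(in)` (natural logs on both ratios).
#' `direction` names which ratio is the input: `"sf_from_pf"` equations
#' predict SF from PF (and are inverted to predict PF), `"pf_from_sf"`
#' the reverse.
#'
#' @param name Short identifier, e.g. `"rice_2007"`.
#' @param form `"linear"` or `"loglinear"`.
#' @param direction `"sf_from_pf"` or `"pf_from_sf"`.
#' @param intercept,slope Coefficients; `slope` must be nonzero.
#' @param source Citation or provenance string.
#' @return An object of class `imputation_equation`.
#' @export
imputation_equation <- function(name, form = c("linear", "loglinear"),
                                direction = c("sf_from_pf", "pf_from_sf"),
                                intercept, slope, source = "") {
  form <- match.arg(form)
  direction <- match.arg(direction)
  stopifnot(is.numeric(intercept), is.numeric(slope), slope != 0)
  structure(
    list(name = name, form = form, direction = direction,
         intercept = intercept, slope = slope, source = source),
    class = "imputation_equation"
  )
}

#' @export
print.imputation_equation <- function(x, ...) {
  lhs <- if (x$direction == "sf_from_pf") c("SF", "PF") else c("PF", "SF")
  eqn <- if (x$form == "linear") {
    sprintf("%s = %g + %g * %s", lhs[1], x$intercept, x$slope, lhs[2])
  } else {
    sprintf("ln %s = %g + %g * ln %s", lhs[1], x$intercept, x$slope, lhs[2])
  }
  cat(sprintf("<imputation_equation> %s: %s\n", x$name, eqn))
  invisible(x)
}

#' Apply or invert an imputation equation
#'
#' `apply_imputation()` maps a value through the equation in its native
#' direction; `invert_imputation()` solves it backwards. Inversion of a
#' linear equation fails (domain error) when the operand leaves the
#' positive ratio range, e.g. SF at or below the intercept for a positive
#' slope.
#'
#' @param eq An [imputation_equation()].
#' @param value Strictly positive ratio value(s) in the equation's input
#'   (resp. output) scale.
#' @return The converted ratio value(s).
#' @examples
#' rice <- imputation_equation("rice_2007", "linear", "sf_from_pf", 64, 0.84)
#' apply_imputation(rice, 200)   # SF predicted at PF 200
#' invert_imputation(rice, 232)  # back to PF 200
#' @export
apply_imputation <- function(eq, value) {
  stopifnot(inherits(eq, "imputation_equation"))
  if (any(value <= 0)) stop("ratio values must be positive", call. = FALSE)
  if (eq$form == "linear") {
    eq$intercept + eq$slope * value
  } else {
    exp(eq$intercept + eq$slope * log(value))
  }
}

#' @rdname apply_imputation
#' @export
invert_imputation <- function(eq, value) {
  stopifnot(inherits(eq, "imputation_equation"))
  if (any(value <= 0)) stop("ratio values must be positive", call. = FALSE)
  if (eq$form == "linear") {
    out <- (value - eq$intercept) / eq$slope
    if (any(out <= 0)) {
      stop("non-invertible input: result leaves the positive ratio range",
           call. = FALSE)
    }
    out
  } else {
    exp((log(value) - eq$intercept) / eq$slope)
  }
}

#' Predict the PF ratio from the SF ratio with any equation
#'
#' Uses the equation directly when its direction is `pf_from_sf`, else
#' inverts it.
#'
#' @inheritParams apply_imputation
#' @param sf SF ratio value(s).
#' @return Predicted PF ratio(s).
#' @export
predict_pf <- function(eq, sf) {
  if (eq$direction == "pf_from_sf") apply_imputation(eq, sf)
  else invert_imputation(eq, sf)
}

#' Published and fitted conversion equations
#'
#' Reads the bundled registry of SF/PF conversion equations
#' (`inst/extdata/imputation_registry.csv`), or a user-supplied CSV with
#' columns `name, form, direction, intercept, slope, source`. The bundled
#' registry ships the widely used linear imputations of Rice et al.
#' (2007) and Bilan et al. (2015) plus a log-linear entry fitted by this
#' package to noise-free Severinghaus-curve data (named
#' `severinghaus_loglinear_synthetic`; it is a synthetic stand-in, not a
#' published equation). Further published equations can be added to the
#' CSV without code changes.
#'
#' @param path Optional path to a registry CSV; default uses the bundled
#'   file.
#' @return A named list of [imputation_equation()] objects.
#' @export
imputation_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "imputation_registry.csv",
                        package = "sfratio", mustWork = TRUE)
  }
  tbl <- readr::read_csv(path, col_types = readr::cols(
    name = "c", form = "c", direction = "c",
    intercept = "d", slope = "d", source = "c"
  ), progress = FALSE)
  eqs <- lapply(seq_len(nrow(tbl)), function(i) {
    imputation_equation(tbl$name[i], tbl$form[i], tbl$direction[i],
                        tbl$intercept[i], tbl$slope[i], tbl$source[i])
  })
  stats::setNames(eqs, tbl$name)
}

#' Least-squares SF-to-PF conversion fits
#'
#' Ordinary least squares of PF on SF on the raw scale (`fit_linear()`)
#' or on natural logs of both ratios (`fit_loglinear()`). The upstream
#' SpO2 <= 97% restriction is assumed already applied.
#'
#' @param sf_values,pf_values Paired ratio observations, n >= 3.
#' @return An [imputation_equation()] with direction `pf_from_sf`.
#' @export
fit_linear <- function(sf_values, pf_values) {
  check_fit_inputs(sf_values, pf_values)
  fit <- stats::lm(pf_values ~ sf_values)
  imputation_equation("ols_linear", "linear", "pf_from_sf",
                      stats::coef(fit)[[1]], stats::coef(fit)[[2]],
                      "least-squares fit on the supplied data")
}

#' @rdname fit_linear
#' @export
fit_loglinear <- function(sf_values, pf_values) {
  check_fit_inputs(sf_values, pf_values)
  fit <- stats::lm(log(pf_values) ~ log(sf_values))
  imputation_equation("ols_loglinear", "loglinear", "pf_from_sf",
                      stats::coef(fit)[[1]], stats::coef(fit)[[2]],
                      "least-squares log-log fit on the supplied data")
}

check_fit_inputs <- function(sf, pf) {
  if (length(sf) != length(pf)) stop("paired vectors differ in length",
                                     call. = FALSE)
  if (length(sf) < 3) stop("need at least three pairs", call. = FALSE)
  if (any(sf <= 0) || any(pf <= 0)) {
    stop("ratio values must be positive", call. = FALSE)
  }
  if (stats::sd(sf) == 0) stop("degenerate design: SF has zero variance",
                               call. = FALSE)
  invisible(NULL)
}

#' Evaluate an equation's PF predictions
#'
#' R-squared (`1 - SS_res / SS_tot` of predicted versus observed PF) and
#' mean absolute error, both on the PF scale — log-linear predictions are
#' exponentiated first, so forms are comparable.
#'
#' @inheritParams apply_imputation
#' @param sf_values,pf_values Paired observed ratios, n >= 2.
#' @return A list with `r_squared` and `mae` (mmHg).
#' @export
evaluate_imputation <- function(eq, sf_values, pf_values) {
  if (length(sf_values) != length(pf_values)) {
    stop("paired vectors differ in length", call. = FALSE)
  }
  if (length(sf_values) < 2) stop("need at least two pairs", call. = FALSE)
  if (stats::sd(pf_values) == 0) {
    stop("zero variance in observed PF: R-squared undefined", call. = FALSE)
  }
  pred <- predict_pf(eq, sf_values)
  ss_res <- sum((pf_values - pred)^2)
  ss_tot <- sum((pf_values - mean(pf_values))^2)
  list(r_squared = 1 - ss_res / ss_tot, mae = mean(abs(pred - pf_values)))
}

#' Compare all registry equations and fresh OLS fits on one dataset
#'
#' @param sf_values,pf_values Paired observed ratios.
#' @param registry A list of equations ([imputation_registry()]); the OLS
#'   linear and log-linear fits on the supplied data are appended.
#' @return A tibble with one row per equation: name, form, direction,
#'   intercept, slope, r_squared, mae.
#' @export
conversion_table <- function(sf_values, pf_values,
                             registry = imputation_registry()) {
  eqs <- c(registry,
           list(ols_linear = fit_linear(sf_values, pf_values),
                ols_loglinear = fit_loglinear(sf_values, pf_values)))
  rows <- lapply(eqs, function(eq) {
    perf <- tryCatch(evaluate_imputation(eq, sf_values, pf_values),
                     error = function(e) list(r_squared = NA_real_,
                                              mae = NA_real_))
    tibble::tibble(name = eq$name, form = eq$form, direction = eq$direction,
                   intercept = eq$intercept, slope = eq$slope,
                   r_squared = perf$r_squared, mae = perf$mae)
  })
  dplyr::bind_rows(rows)
}
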