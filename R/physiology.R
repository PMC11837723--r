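#' Physiology constants for the alveolar gas equation
#'
#' Bundles the constants entering the alveolar gas equation
#' \eqn{P_AO_2 = FiO_2 (P_b - P_{H_2O}) - PaCO_2 / RQ}. Defaults are the
#' sea-level standard values; all three are configurable so the assumption
#' is explicit rather than baked in.
#'
#' @param barometric_pressure Barometric pressure in mmHg (default 760).
#' @param water_vapor_pressure Saturated water vapor pressure at body
#'   temperature in mmHg (default 47).
#' @param respiratory_quotient Respiratory quotient, dimensionless
#'   (default 0.8).
#' @return An object of class `physiology_constants`.
#' @examples
#' physiology_constants()
#' physiology_constants(barometric_pressure = 700) # altitude
#' @export
physiology_constants <- function(barometric_pressure = 760,
                                 water_vapor_pressure = 47,
                                 respiratory_quotient = 0.8) {
  stopifnot(
    is.numeric(barometric_pressure), barometric_pressure > 0,
    is.numeric(water_vapor_pressure), water_vapor_pressure > 0,
    is.numeric(respiratory_quotient), respiratory_quotient > 0,
    water_vapor_pressure < barometric_pressure
  )
  structure(
    list(
      barometric_pressure = barometric_pressure,
      water_vapor_pressure = water_vapor_pressure,
      respiratory_quotient = respiratory_quotient
    ),
    class = "physiology_constants"
  )
}

#' @export
print.physiology_constants <- function(x, ...) {
  cat("Physiology constants: Pb =", x$barometric_pressure,
      "mmHg, PH2O =", x$water_vapor_pressure,
      "mmHg, RQ =", x$respiratory_quotient, "\n")
  invisible(x)
}

#' Severinghaus oxyhemoglobin dissociation curve
#'
#' Hemoglobin oxygen saturation as a function of arterial oxygen tension,
#' using the Severinghaus empirical form
#' \eqn{S = (P^3 + 150 P) / (P^3 + 150 P + 23400)}.
#' The curve is strictly increasing on \eqn{P > 0}, bounded in (0, 1), with
#' half-saturation (P50) at 26.86 mmHg.
#'
#' @param pao2 Arterial oxygen partial pressure in mmHg; strictly positive.
#' @param shift Scalar multiplier applied to `pao2` before evaluating the
#'   curve; a hook for left/right shifts of the dissociation curve
#'   (pCO2, pH, temperature). Default 1 (no shift); values other than 1 are
#'   outside the validated scope of the package.
#' @return Saturation as a fraction in (0, 1), same length as `pao2`.
#' @seealso [severinghaus_pao2()] for the inverse.
#' @examples
#' severinghaus_sao2(26.86) # ~0.50, the P50
#' severinghaus_sao2(100)   # ~0.977
#' @export
severinghaus_sao2 <- function(pao2, shift = 1) {
  if (!is.numeric(pao2) || any(!is.finite(pao2)) || any(pao2 <= 0)) {
    stop("`pao2` must be finite and strictly positive (mmHg)", call. = FALSE)
  }
  p <- pao2 * shift
  x <- p^3 + 150 * p
  x / (x + 23400)
}

#' Inverse Severinghaus curve: oxygen tension from saturation
#'
#' Solves \eqn{P^3 + 150 P = 23400 \, S / (1 - S)} for \eqn{P}. The cubic
#' has a single real positive root, obtained in closed form (Cardano) and
#' polished with one Newton step so the forward/inverse round trip is exact
#' to well below 1e-9 in saturation.
#'
#' @param sao2 Saturation fraction, strictly inside (0, 1). Saturation 1 is
#'   the curve's asymptote and has no finite tension.
#' @inheritParams severinghaus_sao2
#' @return Oxygen tension in mmHg, same length as `sao2`.
#' @examples
#' severinghaus_pao2(0.5)  # ~26.86 mmHg
#' severinghaus_pao2(severinghaus_sao2(80)) # 80
#' @export
severinghaus_pao2 <- function(sao2, shift = 1) {
  if (!is.numeric(sao2) || any(!is.finite(sao2)) ||
      any(sao2 <= 0) || any(sao2 >= 1)) {
    stop("`sao2` must lie strictly inside (0, 1)", call. = FALSE)
  }
  k <- 23400 * sao2 / (1 - sao2)
  disc <- sqrt(k^2 / 4 + 125000) # (150/3)^3 = 125000
  cbrt <- function(x) sign(x) * abs(x)^(1 / 3)
  p <- cbrt(k / 2 + disc) - cbrt(disc - k / 2)
  # one Newton step on f(p) = p^3 + 150 p - k
  p <- p - (p^3 + 150 * p - k) / (3 * p^2 + 150)
  p / shift
}

#' Alveolar oxygen tension (alveolar gas equation)
#'
#' \eqn{P_AO_2 = FiO_2 (P_b - P_{H_2O}) - PaCO_2 / RQ}, the ideal alveolar
#' oxygen tension. Linear in both `fio2` and `paco2`.
#'
#' @param fio2 Inspired oxygen fraction in (0, 1].
#' @param paco2 Arterial carbon dioxide tension in mmHg, non-negative.
#' @param constants A [physiology_constants()] object.
#' @return Alveolar oxygen tension in mmHg. Errors if a combination of
#'   inputs yields a non-positive tension (physically impossible).
#' @examples
#' alveolar_po2(0.21, 40) # 99.73 (room air)
#' alveolar_po2(1.0, 40)  # 663
#' @export
alveolar_po2 <- function(fio2, paco2, constants = physiology_constants()) {
  stopifnot(inherits(constants, "physiology_constants"))
  if (!is.numeric(fio2) || any(fio2 <= 0) || any(fio2 > 1)) {
    stop("`fio2` must be a fraction in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(paco2) || any(paco2 < 0)) {
    stop("`paco2` must be non-negative (mmHg)", call. = FALSE)
  }
  pao2_alv <- fio2 * (constants$barometric_pressure - constants$water_vapor_pressure) -
    paco2 / constants$respiratory_quotient
  if (any(pao2_alv <= 0)) {
    stop("alveolar PO2 <= 0: FiO2/PaCO2 combination is physically impossible",
         call. = FALSE)
  }
  pao2_alv
}

#' Respiratory Index
#'
#' The Respiratory Index (RI) is the alveolar-arterial oxygen gradient
#' divided by the arterial oxygen tension:
#' \eqn{RI = (P_AO_2 - PaO_2) / PaO_2}. It is a tension-based oxygenation
#' index that varies less with FiO2 than the PaO2/FiO2 ratio, which is why
#' it serves as the stability gate for trending analysis. Slightly negative
#' values (measured PaO2 above the computed alveolar tension, possible
#' under measurement noise) are returned as-is, not clipped: clipping would
#' bias proportional-change gating.
#'
#' @param pao2 Arterial oxygen tension in mmHg, strictly positive.
#' @inheritParams alveolar_po2
#' @return Dimensionless RI, same length as the inputs.
#' @examples
#' respiratory_index(99.73, 0.21, 40) # 0: PaO2 equals alveolar PO2
#' respiratory_index(100, 1.0, 40)    # 5.63
#' @export
respiratory_index <- function(pao2, fio2, paco2,
                              constants = physiology_constants()) {
  if (!is.numeric(pao2) || any(pao2 <= 0)) {
    stop("`pao2` must be strictly positive (mmHg)", call. = FALSE)
  }
  (alveolar_po2(fio2, paco2, constants) - pao2) / pao2
}

#' Arterial oxygen tension implied by a Respiratory Index
#'
#' Inverse of [respiratory_index()] in its first argument:
#' \eqn{PaO_2 = P_AO_2 / (1 + RI)}. Used by the cohort simulator to turn a
#' latent gas-exchange state (RI) and a ventilator setting (FiO2) into a
#' true arterial tension.
#'
#' @param ri Respiratory Index, must exceed -1.
#' @inheritParams alveolar_po2
#' @return PaO2 in mmHg.
#' @examples
#' pao2_given_ri(0, 0.21, 40)    # 99.73
#' pao2_given_ri(5.63, 1.0, 40)  # ~100
#' @export
pao2_given_ri <- function(ri, fio2, paco2, constants = physiology_constants()) {
  if (!is.numeric(ri) || any(ri <= -1)) {
    stop("`ri` must be greater than -1", call. = FALSE)
  }
  alveolar_po2(fio2, paco2, constants) / (1 + ri)
}

#' Oxygenation ratios
#'
#' `pf_ratio()` is PaO2 (mmHg) divided by FiO2 (fraction); `sf_ratio()` is
#' SpO2 (percent) divided by FiO2 (fraction). Note the unit asymmetry: the
#' SF ratio consumes the saturation in percent, so SpO2 97 at FiO2 1.0
#' gives SF = 97.
#'
#' @param pao2 Arterial oxygen tension, mmHg.
#' @param spo2 Pulse-oximetric saturation, percent.
#' @param fio2 Inspired oxygen fraction, restricted to [0.21, 1.0].
#' @return The ratio (mmHg for PF, dimensionless for SF).
#' @examples
#' pf_ratio(100, 0.5) # 200
#' sf_ratio(94, 0.4)  # 235, a severity-threshold boundary
#' @export
pf_ratio <- function(pao2, fio2) {
  check_fio2_range(fio2)
  pao2 / fio2
}

#' @rdname pf_ratio
#' @export
sf_ratio <- function(spo2, fio2) {
  check_fio2_range(fio2)
  spo2 / fio2
}

check_fio2_range <- function(fio2) {
  if (!is.numeric(fio2) || any(!is.finite(fio2)) ||
      any(fio2 < 0.21) || any(fio2 > 1)) {
    stop("`fio2` must lie in [0.21, 1.0]", call. = FALSE)
  }
  invisible(fio2)
}
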