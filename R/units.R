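#' Universal gas constant (J mol-1 K-1)
#'
#' @export
R_GAS <- 8.314462

#' Gas-phase reference conditions
#'
#' Temperature and pressure used for every ppbv <-> molar conversion.
#' The chamber conditions are not part of the sampler chemistry, so they are
#' carried explicitly wherever a mixing-ratio conversion occurs. Defaults are
#' standard room conditions (25 degC, 1 atm).
#'
#' @param temperature Kelvin, > 0.
#' @param pressure Pascal, > 0.
#' @return An object of class `gas_conditions`.
#' @examples
#' gas_conditions()            # 298.15 K, 101325 Pa
#' gas_conditions(293.15)      # 20 degC
#' @export
gas_conditions <- function(temperature = 298.15, pressure = 101325) {
  chk_num(temperature, "temperature", lower = 0, strict = TRUE, len = 1L)
  chk_num(pressure, "pressure", lower = 0, strict = TRUE, len = 1L)
  structure(list(temperature = temperature, pressure = pressure),
            class = "gas_conditions")
}

#' @export
print.gas_conditions <- function(x, ...) {
  cat(sprintf("gas conditions: %.2f K, %.0f Pa\n", x$temperature, x$pressure))
  invisible(x)
}

as_gas_conditions <- function(cond) {
  if (inherits(cond, "gas_conditions")) return(cond)
  if (is.list(cond) && all(c("temperature", "pressure") %in% names(cond)))
    return(gas_conditions(cond$temperature, cond$pressure))
  stop_input("cond must be a gas_conditions object")
}

#' Convert a gas mixing ratio (ppbv) to a molar concentration
#'
#' Ideal-gas conversion: `c_molar = c_ppbv * 1e-9 * P / (R * T)`.
#'
#' @param c Mixing ratio in ppbv, >= 0 (vectorised).
#' @param cond [gas_conditions()].
#' @return Molar concentration, mol m-3.
#' @examples
#' ppbv_to_molar(500)  # ~2.04e-5 mol m-3 at 298.15 K / 101325 Pa
#' @export
ppbv_to_molar <- function(c, cond = gas_conditions()) {
  chk_num(c, "c (ppbv)", lower = 0)
  cond <- as_gas_conditions(cond)
  c * 1e-9 * cond$pressure / (R_GAS * cond$temperature)
}

#' Convert a molar gas concentration to a mixing ratio (ppbv)
#'
#' Exact inverse of [ppbv_to_molar()] at the same conditions.
#'
#' @param c Molar concentration in mol m-3, >= 0 (vectorised).
#' @param cond [gas_conditions()].
#' @return Mixing ratio, ppbv.
#' @export
molar_to_ppbv <- function(c, cond = gas_conditions()) {
  chk_num(c, "c (mol m-3)", lower = 0)
  cond <- as_gas_conditions(cond)
  c * 1e9 * R_GAS * cond$temperature / cond$pressure
}

#' CT dose metric (concentration x time)
#'
#' The CT value treats inhalation burden as the product of the time-weighted
#' average concentration and the exposure duration; equal CT values are taken
#' as toxicologically equivalent when comparing against guideline levels.
#'
#' @param twa Time-weighted average concentration, ppbv, >= 0.
#' @param duration Exposure duration, minutes, >= 0.
#' @return A `ct_value` object with fields `value` (ppbv min), `twa`,
#'   `duration`.
#' @examples
#' ct_value(878, 120)   # 105360 ppbv min
#' @export
ct_value <- function(twa, duration) {
  chk_num(twa, "twa", lower = 0, len = 1L)
  chk_num(duration, "duration", lower = 0, len = 1L)
  structure(list(value = twa * duration, twa = twa, duration = duration),
            class = "ct_value")
}

#' @export
print.ct_value <- function(x, ...) {
  cat(sprintf("CT = %.4g ppbv min  (TWA %.4g ppbv over %.4g min)\n",
              x$value, x$twa, x$duration))
  invisible(x)
}

#' Duration of a constant-concentration exposure with the same CT
#'
#' Answers "how long at the reference level would deliver this dose": e.g. a
#' CT of 104000 ppbv min corresponds to 208 min at a constant 500 ppbv.
#'
#' @param ct A [ct_value()] object, or a bare CT value in ppbv min.
#' @param reference Reference concentration, ppbv, > 0 (default: the 500 ppbv
#'   chlorine occupational limit).
#' @return Equivalent exposure duration, minutes.
#' @export
equivalent_exposure_time <- function(ct, reference = 500) {
  v <- if (inherits(ct, "ct_value")) ct$value else ct
  chk_num(v, "ct", lower = 0, len = 1L)
  chk_num(reference, "reference", lower = 0, strict = TRUE, len = 1L)
  v / reference
}

#' Chlorine exposure guideline table
#'
#' Default thresholds: the OSHA permissible exposure limit (500 ppbv TWA) and
#' AEGL-1 (500 ppbv, defined for exposures of 10 min to 8 h). Stored as a
#' table so other gases or limits can be added.
#'
#' @return data.frame with columns `label`, `threshold_ppbv`,
#'   `min_duration_min`, `max_duration_min`.
#' @export
chlorine_guidelines <- function() {
  data.frame(
    label = c("OSHA_PEL", "AEGL-1"),
    threshold_ppbv = c(500, 500),
    min_duration_min = c(0, 10),
    max_duration_min = c(Inf, 480),
    stringsAsFactors = FALSE
  )
}

#' Guideline exceedance labels for a TWA exposure
#'
#' A label is returned when the TWA is at or above the guideline threshold
#' and the exposure duration falls inside the guideline's applicability
#' window.
#'
#' @param twa Time-weighted average concentration, ppbv, >= 0.
#' @param duration Exposure duration, minutes, >= 0.
#' @param guidelines Guideline table, defaults to [chlorine_guidelines()].
#' @return Character vector of exceeded guideline labels (possibly empty).
#' @examples
#' guideline_flags(600, 60)  # both OSHA_PEL and AEGL-1
#' guideline_flags(600, 5)   # AEGL-1 window starts at 10 min
#' @export
guideline_flags <- function(twa, duration, guidelines = chlorine_guidelines()) {
  chk_num(twa, "twa", lower = 0, len = 1L)
  chk_num(duration, "duration", lower = 0, len = 1L)
  hit <- twa >= guidelines$threshold_ppbv &
    duration >= guidelines$min_duration_min &
    duration <= guidelines$max_duration_min
  guidelines$label[hit]
}
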