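# Empirical links between plankton biomass and the indirectly measured
# quantities (Secchi clarity, chlorophyll-a): forward proxies, inversion
# for zooplankton, and filter-state initialization.

#' Calibration coefficients of the indirect observations
#'
#' The proxies act on the "effective" phytoplankton biomass
#' `Peff = P - alpha*Z` (what remains visible to clarity and pigment after
#' zooplankton consumption): `S = cS * Peff` and `Cchl = kchl * Peff`.
#' All three coefficients depend on pond morphometry and must be calibrated
#' per pond; the defaults are test-scale placeholders.
#'
#' @param cS Secchi clarity per unit effective biomass, m per g/m^3. The
#'   sign convention (clarity falling or rising with biomass) is part of the
#'   per-pond calibration; `cS` is treated as a signed linear coefficient.
#' @param kchl Chlorophyll-a per unit effective biomass, ug/L per g/m^3 (> 0).
#' @param alpha Phytoplankton consumed per unit zooplankton biomass,
#'   dimensionless (>= 0).
#' @param epsS_std Secchi measurement noise, m (>= 0).
#' @param quiet Suppress the placeholder-calibration warning.
#' @return An object of class `indirect_coeffs`.
#' @export
indirect_coeffs <- function(cS = 1.0, kchl = 4.0, alpha = 0.3,
                            epsS_std = 0, quiet = FALSE) {
  stopifnot(kchl > 0, alpha >= 0, epsS_std >= 0)
  if (!quiet && missing(cS) && missing(kchl) && missing(alpha))
    warning("indirect_coeffs(): using placeholder calibration; cS, kchl and ",
            "alpha should be calibrated per pond", call. = FALSE)
  structure(list(cS = cS, kchl = kchl, alpha = alpha, epsS_std = epsS_std),
            class = "indirect_coeffs")
}

#' Predict Secchi clarity and chlorophyll-a from plankton biomass
#'
#' @param P Phytoplankton biomass, g/m^3 (>= 0).
#' @param Z Zooplankton biomass, g/m^3 (>= 0).
#' @param coeffs An [indirect_coeffs()] object.
#' @return List with `Peff` (g/m^3, floored at 0), `S` (m) and `Cchl`
#'   (ug/L). When `alpha*Z` exceeds `P` the effective biomass is clipped to
#'   zero with a warning (the linear proxy has no meaning there).
#' @examples
#' predict_indirect(2, 1, indirect_coeffs(kchl = 4, alpha = 0.3, quiet = TRUE))$Cchl  # 6.8
#' @export
predict_indirect <- function(P, Z, coeffs) {
  stopifnot(inherits(coeffs, "indirect_coeffs"), P >= 0, Z >= 0)
  peff <- P - coeffs$alpha * Z
  if (any(peff < 0)) {
    warning("effective biomass P - alpha*Z is negative; floored at 0",
            call. = FALSE)
    peff <- pmax(peff, 0)
  }
  list(Peff = peff, S = coeffs$cS * peff, Cchl = coeffs$kchl * peff)
}

#' Invert the chlorophyll proxy for zooplankton biomass
#'
#' Given a chlorophyll-a reading and an (estimated) phytoplankton biomass,
#' solves `Cchl = kchl * (P - alpha*Z)` for `Z`, clipped to be nonnegative.
#'
#' @param Cchl Chlorophyll-a concentration, ug/L.
#' @param P Phytoplankton biomass, g/m^3.
#' @param coeffs An [indirect_coeffs()] object with `alpha > 0`.
#' @return Zooplankton biomass estimate, g/m^3.
#' @export
invert_for_Z <- function(Cchl, P, coeffs) {
  stopifnot(inherits(coeffs, "indirect_coeffs"))
  if (coeffs$alpha <= 0)
    stop("alpha must be positive to invert the proxy for Z")
  pmax((P - Cchl / coeffs$kchl) / coeffs$alpha, 0)
}

#' Initialize a filter state from a chlorophyll-a reading
#'
#' Phytoplankton is initialized from the chlorophyll proxy (`P0 = Cchl /
#' kchl`, zooplankton assumed at its configured default), zooplankton and
#' fish from stocking records, and dissolved oxygen from the first DO
#' measurement when available, else from the temperature-dependent
#' saturation level.
#'
#' @param Cchl Chlorophyll-a concentration, ug/L (>= 0).
#' @param coeffs An [indirect_coeffs()] object.
#' @param defaults State vector supplying the fallback `Z`, `F` (and `P`,
#'   unused) values, e.g. from stocking records.
#' @param temp_c Water temperature, degrees C.
#' @param Osat_base Saturation DO at 20 degrees C, mg/L.
#' @param first_do Optional first DO measurement, mg/L.
#' @return A state vector `[P0, Z0, F0, O0]`.
#' @export
init_state <- function(Cchl, coeffs, defaults = state_vec(1, 0.5, 0.3, 9),
                       temp_c = 20, Osat_base = 9.1, first_do = NULL) {
  stopifnot(inherits(coeffs, "indirect_coeffs"), Cchl >= 0)
  if (is.null(coeffs$kchl) || !is.finite(coeffs$kchl))
    stop("kchl missing from the indirect-observation calibration")
  O0 <- if (!is.null(first_do)) first_do else oxygen_saturation(temp_c, Osat_base)
  state_vec(P = Cchl / coeffs$kchl, Z = defaults[[2]], F = defaults[[3]], O = O0)
}
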