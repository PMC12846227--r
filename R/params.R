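# Parameter containers for the P-Z-F-O pond model.

# Normal ranges used by validation. Typical values are the constructor
# defaults below; ranges bound what a pond parameterization may look like
# without an explicit override.
.PARAM_RANGES <- list(
  rP        = c(0.5, 2.0),
  K         = c(3.0, 8.0),
  hP        = c(0.1, 1.0),
  mP        = c(0.05, 0.2),
  gZ        = c(0.3, 1.0),
  eZ        = c(0.3, 0.6),
  hZ        = c(0.1, 0.5),
  mZ        = c(0.05, 0.15),
  gF        = c(0.1, 0.5),
  eF        = c(0.2, 0.4),
  mF        = c(0.02, 0.1),
  aP        = c(0.1, 0.5),
  bR        = c(0.05, 0.2),
  k2        = c(0.1, 0.3),
  Osat_base = c(8.0, 10.0)
)

#' Ecosystem parameters of the P-Z-F-O pond model
#'
#' Bundles the growth, trophic-interaction, mortality and oxygen-balance
#' constants of the four-state pond model. All rates are per day, biomasses
#' in g/m^3 and oxygen terms in mg/L. Defaults are the typical literature
#' values for a temperate fish pond.
#'
#' @param rP Phytoplankton intrinsic growth rate, 1/day.
#' @param K Phytoplankton carrying capacity, g/m^3.
#' @param gZ Zooplankton grazing rate on phytoplankton, 1/day.
#' @param gF Fish predation rate on zooplankton, 1/day.
#' @param hP Half-saturation constant of the grazing response, g/m^3.
#' @param hZ Half-saturation constant of the predation response, g/m^3.
#' @param eZ Zooplankton assimilation efficiency, dimensionless in (0,1).
#' @param eF Fish assimilation efficiency, dimensionless in (0,1).
#' @param mP,mZ,mF Mortality rates of the three biomass pools, 1/day.
#' @param aP Oxygen production per unit phytoplankton, mg/(L day).
#' @param bR Respiratory oxygen consumption per unit biomass, mg/(L day).
#' @param k2 Atmospheric reaeration coefficient, 1/day.
#' @param Osat_base Dissolved-oxygen saturation at 20 degrees C, mg/L.
#' @param allow_outside_range If `TRUE`, values outside the published normal
#'   ranges are accepted (a pond can be atypical); otherwise they are an error.
#' @return An object of class `ecosystem_params` (a named list).
#' @examples
#' p <- ecosystem_params()           # typical temperate pond
#' p51 <- ecosystem_params(Osat_base = 10)  # simulation-study configuration
#' @export
ecosystem_params <- function(rP = 0.8, K = 5.0, gZ = 0.6, gF = 0.3,
                             hP = 0.5, hZ = 0.3, eZ = 0.4, eF = 0.3,
                             mP = 0.1, mZ = 0.08, mF = 0.05,
                             aP = 0.3, bR = 0.1, k2 = 0.15,
                             Osat_base = 9.1,
                             allow_outside_range = FALSE) {
  p <- list(rP = rP, K = K, gZ = gZ, gF = gF, hP = hP, hZ = hZ,
            eZ = eZ, eF = eF, mP = mP, mZ = mZ, mF = mF,
            aP = aP, bR = bR, k2 = k2, Osat_base = Osat_base)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive finite number")
  }
  if (eZ >= 1 || eF >= 1)
    stop("assimilation efficiencies eZ, eF must lie in (0, 1)")
  if (!allow_outside_range) {
    for (nm in names(.PARAM_RANGES)) {
      rg <- .PARAM_RANGES[[nm]]
      if (p[[nm]] < rg[1] || p[[nm]] > rg[2])
        stop("parameter '", nm, "' = ", p[[nm]], " is outside its normal range [",
             rg[1], ", ", rg[2], "]; set allow_outside_range = TRUE to override")
    }
  }
  structure(p, class = "ecosystem_params")
}

#' @export
print.ecosystem_params <- function(x, ...) {
  cat("P-Z-F-O ecosystem parameters (per-day rates, g/m^3, mg/L):\n")
  print(unlist(x))
  invisible(x)
}

#' Sinusoidal water-temperature forcing
#'
#' Water temperature is modelled as
#' `T(t) = T_mean + amplitude * sin(2*pi*t/period + phase)` with `t` in days.
#' The default describes a temperate open pond whose temperature swings
#' between 10 and 26 degrees C over a 25-day weather cycle.
#'
#' @param T_mean Mean water temperature, degrees C.
#' @param amplitude Half peak-to-peak temperature swing, degrees C (>= 0).
#' @param period Oscillation period, days (> 0).
#' @param phase Phase offset, radians.
#' @return An object of class `temperature_forcing`.
#' @seealso [temperature_series()] to evaluate the forcing.
#' @export
temperature_forcing <- function(T_mean = 18, amplitude = 8, period = 25,
                                phase = 0) {
  stopifnot(is.numeric(T_mean), is.numeric(amplitude), is.numeric(period),
            is.numeric(phase), length(T_mean) == 1L, length(amplitude) == 1L,
            length(period) == 1L, length(phase) == 1L)
  if (period <= 0) stop("forcing period must be > 0")
  if (amplitude < 0) stop("forcing amplitude must be >= 0")
  structure(list(T_mean = T_mean, amplitude = amplitude, period = period,
                 phase = phase),
            class = "temperature_forcing")
}

#' Evaluate a temperature forcing at given times
#'
#' @param forcing A [temperature_forcing()] object.
#' @param times Numeric vector of times in days (sorted, nonnegative for
#'   simulation use; any finite time is accepted).
#' @return Numeric vector of water temperatures, degrees C.
#' @examples
#' temperature_series(temperature_forcing(), c(0, 6.25, 18.75))
#' @export
temperature_series <- function(forcing, times) {
  stopifnot(inherits(forcing, "temperature_forcing"), is.numeric(times))
  forcing$T_mean +
    forcing$amplitude * sin(2 * pi * times / forcing$period + forcing$phase)
}

#' Construct a pond state vector
#'
#' The state is `[P, Z, F, O]`: phytoplankton, zooplankton and fish biomass
#' (g/m^3) and dissolved oxygen (mg/L). Biomasses must be nonnegative.
#'
#' @param P,Z,F Biomasses, g/m^3.
#' @param O Dissolved oxygen, mg/L.
#' @return Named numeric vector of length 4.
#' @export
state_vec <- function(P, Z, F, O) {
  x <- c(P = P, Z = Z, F = F, O = O)
  validate_state(x)
  x
}

#' Validate a pond state vector
#'
#' @param x Numeric vector of length 4 (`P`, `Z`, `F`, `O`).
#' @return `x`, invisibly, after validation.
#' @export
validate_state <- function(x) {
  if (!is.numeric(x) || length(x) != 4L || any(!is.finite(x)))
    stop("state must be a finite numeric vector of length 4 [P, Z, F, O]")
  if (any(x[1:3] < 0))
    stop("biomasses P, Z, F must be nonnegative")
  invisible(x)
}
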