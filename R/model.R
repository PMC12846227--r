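# Deterministic core of the P-Z-F-O model: right-hand side, analytic
# Jacobian, oxygen saturation, and fixed-step RK4 integration.

#' Temperature-dependent dissolved-oxygen saturation
#'
#' Linearized saturation law `Osat(T) = Osat_base * (1 - 0.02 * (T - 20))`,
#' anchored at the 20 degrees C reference value. Valid for liquid pond water,
#' 0--40 degrees C.
#'
#' @param temp_c Water temperature, degrees C; vectorized.
#' @param Osat_base Saturation concentration at 20 degrees C, mg/L (> 0).
#' @return Saturation DO concentration, mg/L.
#' @examples
#' oxygen_saturation(20, 9.1)  # 9.1 at the reference temperature
#' oxygen_saturation(30, 9.1)  # 7.28, warm water holds less oxygen
#' @export
oxygen_saturation <- function(temp_c, Osat_base) {
  stopifnot(is.numeric(temp_c), is.numeric(Osat_base), Osat_base > 0)
  if (any(temp_c < 0 | temp_c > 40))
    stop("temperature ", temp_c[which(temp_c < 0 | temp_c > 40)[1]],
         " degrees C is outside the supported range [0, 40]")
  Osat_base * (1 - 0.02 * (temp_c - 20))
}

#' Right-hand side of the P-Z-F-O ordinary differential equations
#'
#' Phytoplankton grow logistically and are grazed through a saturating
#' (Michaelis-Menten) response; zooplankton assimilate part of that intake and
#' are preyed on by fish through a second saturating response; fish assimilate
#' part of the predation; dissolved oxygen balances photosynthetic production,
#' community respiration and atmospheric reaeration toward `Osat(T)`.
#'
#' @param x State vector `[P, Z, F, O]` (see [state_vec()]).
#' @param params An [ecosystem_params()] object.
#' @param temp_c Water temperature, degrees C.
#' @return Named numeric vector of per-day derivatives `[dP, dZ, dF, dO]`.
#' @export
pond_rhs <- function(x, params, temp_c) {
  P <- x[[1]]; Z <- x[[2]]; F_ <- x[[3]]; O <- x[[4]]
  Osat <- oxygen_saturation(temp_c, params$Osat_base)
  graz <- params$gZ * P * Z / (params$hP + P)
  pred <- params$gF * Z * F_ / (params$hZ + Z)
  c(P = params$rP * P * (1 - P / params$K) - graz - params$mP * P,
    Z = params$eZ * graz - pred - params$mZ * Z,
    F = params$eF * pred - params$mF * F_,
    O = params$aP * P - params$bR * (P + Z + F_) + params$k2 * (Osat - O))
}

#' Analytic Jacobian of the P-Z-F-O right-hand side
#'
#' Closed-form partial derivatives of [pond_rhs()] with respect to the state.
#' The fourth row is constant: `[aP - bR, -bR, -bR, -k2]`.
#'
#' @inheritParams pond_rhs
#' @return A 4x4 numeric matrix `J[i, j] = d f_i / d x_j`.
#' @export
pond_jacobian <- function(x, params, temp_c) {
  P <- x[[1]]; Z <- x[[2]]; F_ <- x[[3]]
  dP <- params$hP + P
  dZ <- params$hZ + Z
  J <- matrix(0, 4L, 4L,
              dimnames = list(c("P", "Z", "F", "O"), c("P", "Z", "F", "O")))
  J[1, 1] <- params$rP * (1 - 2 * P / params$K) -
    params$gZ * Z * params$hP / dP^2 - params$mP
  J[1, 2] <- -params$gZ * P / dP
  J[2, 1] <- params$eZ * params$gZ * Z * params$hP / dP^2
  J[2, 2] <- params$eZ * params$gZ * P / dP -
    params$gF * F_ * params$hZ / dZ^2 - params$mZ
  J[2, 3] <- -params$gF * Z / dZ
  J[3, 2] <- params$eF * params$gF * F_ * params$hZ / dZ^2
  J[3, 3] <- params$eF * params$gF * Z / dZ - params$mF
  J[4, ] <- c(params$aP - params$bR, -params$bR, -params$bR, -params$k2)
  J
}

# One classical 4th-order Runge-Kutta step of the forced system.
.rk4_step <- function(x, t, dt, params, forcing) {
  k1 <- pond_rhs(x, params, temperature_series(forcing, t))
  th <- temperature_series(forcing, t + dt / 2)
  k2 <- pond_rhs(x + dt / 2 * k1, params, th)
  k3 <- pond_rhs(x + dt / 2 * k2, params, th)
  k4 <- pond_rhs(x + dt * k3, params, temperature_series(forcing, t + dt))
  unname(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
}

#' Integrate the P-Z-F-O model with fixed-step RK4
#'
#' Classical 4th-order Runge-Kutta with a fixed step. After every step the
#' state is projected onto the physically admissible set (all components
#' clipped to be nonnegative), so small negative excursions near extinction
#' boundaries cannot grow.
#'
#' @param x0 Initial state `[P, Z, F, O]`.
#' @param params An [ecosystem_params()] object.
#' @param forcing A [temperature_forcing()] object.
#' @param t_span Length of the integration, days (> 0).
#' @param dt Step size, days (default 0.01).
#' @param t0 Start time, days.
#' @return A `pond_trajectory`: data frame with columns `time`, `P`, `Z`,
#'   `F`, `O`, `temp_c`, one row per grid point `t0, t0+dt, ...`.
#' @examples
#' tr <- pond_integrate(state_vec(1.5, 0.8, 0.3, 9.0),
#'                      ecosystem_params(Osat_base = 10),
#'                      temperature_forcing(), t_span = 5)
#' @export
pond_integrate <- function(x0, params, forcing, t_span, dt = 0.01, t0 = 0) {
  validate_state(x0)
  stopifnot(inherits(params, "ecosystem_params"),
            inherits(forcing, "temperature_forcing"))
  if (dt <= 0) stop("dt must be > 0")
  if (t_span <= 0) stop("t_span must be > 0")
  n <- round(t_span / dt)
  times <- t0 + dt * (0:n)
  out <- matrix(NA_real_, n + 1L, 4L)
  out[1L, ] <- x0
  x <- as.numeric(x0)
  for (i in seq_len(n)) {
    x <- .rk4_step(x, times[i], dt, params, forcing)
    if (any(!is.finite(x)))
      stop("integration diverged (non-finite state) at step ", i,
           ", t = ", signif(times[i + 1L], 6), " days")
    x <- pmax(x, 0)
    out[i + 1L, ] <- x
  }
  res <- data.frame(time = times, P = out[, 1], Z = out[, 2],
                    F = out[, 3], O = out[, 4],
                    temp_c = temperature_series(forcing, times))
  class(res) <- c("pond_trajectory", "data.frame")
  res
}

#' @export
plot.pond_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$time, cbind(x$P, x$Z, x$F), type = "l", lty = 1,
                    xlab = "time, days", ylab = "biomass, g/m^3", ...)
  graphics::legend("topright", c("P", "Z", "F"), col = 1:3, lty = 1, bty = "n")
  graphics::plot(x$time, x$O, type = "l", xlab = "time, days",
                 ylab = "DO, mg/L", ...)
}
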