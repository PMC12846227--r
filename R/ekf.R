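# Constrained, adaptive Extended Kalman Filter over the P-Z-F-O model.
#
# The filter cycle per DO record is: predict (RK4 mean propagation +
# first-order covariance transition) -> anomaly gate (Mahalanobis / chi^2
# and physical-limit checks) -> measurement update -> constraint projection
# -> innovation-based Q/R adaptation. Rejected measurements leave the filter
# in prediction-only ("simple prognosis") mode for that step.

.H_DO <- matrix(c(0, 0, 0, 1), 1L, 4L)  # DO-only observation row

#' Filter configuration
#'
#' @param dt Sampling interval, days (default 1/24: hourly DO).
#' @param alpha Per-state dimensionless uncertainty coefficients used in the
#'   process-noise initialization; usually 0.05--0.15.
#' @param Xi_max Per-state expected maxima used in the process-noise
#'   initialization and the default prior: carrying capacity for P, a
#'   sub-carrying zooplankton scale, the simulated fish-biomass scale and the
#'   physical DO cap.
#' @param Omin,Omax Physically possible DO bounds, mg/L.
#' @param chi2_level Probability level of the chi-square innovation gate.
#' @param adapt_lambda Forgetting factor of the innovation-covariance
#'   estimate (0 < lambda <= 1); R adapts ten times slower than Q.
#' @param adapt If `FALSE`, Q and R stay at their initial values.
#' @param R_floor,Q_floor Positive lower bounds for the adapted covariances.
#' @param n_substeps RK substeps per prediction interval.
#' @param integrator Mean-propagation scheme: classical `"rk4"` (default) or
#'   first-order `"euler"`, which matches the first-order covariance
#'   transition exactly (useful for linear-filter cross-checks).
#' @param allow_outside_range Accept `alpha` outside the usual 0.05--0.15 band.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(dt = 1 / 24,
                          alpha = rep(0.1, 4L),
                          Xi_max = c(5, 3, 2, 20),
                          Omin = 0, Omax = 20,
                          chi2_level = 0.90,
                          adapt_lambda = 0.05,
                          adapt = TRUE,
                          R_floor = 1e-4, Q_floor = 1e-12,
                          n_substeps = 1L,
                          integrator = c("rk4", "euler"),
                          allow_outside_range = FALSE) {
  integrator <- match.arg(integrator)
  if (length(alpha) == 1L) alpha <- rep(alpha, 4L)
  stopifnot(length(alpha) == 4L, length(Xi_max) == 4L,
            dt > 0, Omin < Omax, n_substeps >= 1L,
            chi2_level > 0, chi2_level < 1,
            adapt_lambda > 0, adapt_lambda <= 1,
            R_floor > 0, Q_floor > 0)
  bad <- alpha != 0 & (alpha < 0.05 - 1e-12 | alpha > 0.15 + 1e-12)
  if (!allow_outside_range && any(bad))
    stop("uncertainty coefficients alpha are usually in [0.05, 0.15] (or 0); ",
         "set allow_outside_range = TRUE to override")
  if (any(Xi_max <= 0)) stop("Xi_max entries must be positive")
  structure(list(dt = dt, alpha = alpha, Xi_max = Xi_max,
                 Omin = Omin, Omax = Omax, chi2_level = chi2_level,
                 adapt_lambda = adapt_lambda, adapt = adapt,
                 R_floor = R_floor, Q_floor = Q_floor,
                 n_substeps = as.integer(n_substeps),
                 integrator = integrator),
            class = "filter_config")
}

#' Initial process- and measurement-noise covariances
#'
#' `R0 = meas_std^2` follows the DO sensor's quoted mean-square error. The
#' initial `Q0` is diagonal with `q_ii = (alpha_i * Xi_max_i * dt)^2`: the
#' squared fraction of each state's expected maximum that may change,
#' unmodelled, during one sampling interval.
#'
#' @param config A [filter_config()] object.
#' @param meas_std DO sensor noise standard deviation, mg/L (> 0).
#' @return List with `Q0` (4x4 diagonal matrix) and `R0` (scalar).
#' @examples
#' init_noise(filter_config(), meas_std = 0.1)$R0  # 0.01
#' @export
init_noise <- function(config, meas_std) {
  stopifnot(inherits(config, "filter_config"), meas_std > 0)
  q <- (config$alpha * config$Xi_max * config$dt)^2
  list(Q0 = diag(pmax(q, 0), 4L), R0 = meas_std^2)
}

# Default prior covariance: broad (0.5 * Xi_max)^2 on the unobserved
# biomasses with the fish entry inflated 4x (fish biomass is only weakly
# observable from DO), and the sensor variance on O.
.default_P0 <- function(config, meas_std) {
  diag(c((0.5 * config$Xi_max[1])^2,
         (0.5 * config$Xi_max[2])^2,
         4 * (0.5 * config$Xi_max[3])^2,
         meas_std^2), 4L)
}

#' Create the initial filter state
#'
#' @param x0 Initial state estimate `[P, Z, F, O]`.
#' @param config A [filter_config()] object.
#' @param meas_std DO sensor noise standard deviation, mg/L.
#' @param P0 Optional 4x4 prior covariance; defaults to a broad diagonal
#'   prior with the fish entry inflated (weak observability).
#' @param t0 Time of the initial estimate, days.
#' @return An object of class `filter_state` carrying the estimate `x`,
#'   covariance `P`, noise matrices `Q` and `R`, the smoothed innovation
#'   variance `Chat`, a step counter and the innovation history.
#' @export
filter_init <- function(x0, config = filter_config(), meas_std = 0.08,
                        P0 = NULL, t0 = 0) {
  validate_state(x0)
  qr0 <- init_noise(config, meas_std)
  if (is.null(P0)) P0 <- .default_P0(config, meas_std)
  stopifnot(is.matrix(P0), all(dim(P0) == c(4L, 4L)))
  structure(list(x = as.numeric(x0), P = P0,
                 Q = qr0$Q0, Q0 = qr0$Q0, R = qr0$R0,
                 Chat = P0[4, 4] + qr0$R0,
                 t = t0, k = 0L,
                 innovations = numeric(0), S_hist = numeric(0)),
            class = "filter_state")
}

#' EKF prediction step
#'
#' Propagates the mean estimate through the pond dynamics over one sampling
#' interval (`config$n_substeps` RK substeps) and the covariance through the
#' first-order discrete transition `F1 = I + J*h` composed across substeps,
#' with the Jacobian evaluated along the propagated state. The covariance is
#' symmetrized and the process noise `Q` added once per interval.
#'
#' @param fs A `filter_state`.
#' @param params An [ecosystem_params()] object.
#' @param forcing A [temperature_forcing()] object.
#' @param config A [filter_config()] object.
#' @return The a-priori `filter_state` at `fs$t + config$dt`.
#' @export
ekf_predict <- function(fs, params, forcing, config) {
  stopifnot(inherits(fs, "filter_state"))
  h <- config$dt / config$n_substeps
  x <- fs$x
  t <- fs$t
  F1 <- diag(4L)
  for (s in seq_len(config$n_substeps)) {
    F1 <- (diag(4L) + pond_jacobian(x, params, temperature_series(forcing, t)) * h) %*% F1
    x <- if (config$integrator == "rk4")
      .rk4_step(x, t, h, params, forcing)
    else
      x + h * pond_rhs(x, params, temperature_series(forcing, t))
    if (any(!is.finite(x)))
      stop("filter diverged during prediction at t = ", signif(t, 6), " days")
    x <- pmax(x, 0)
    t <- t + h
  }
  P <- F1 %*% fs$P %*% t(F1) + fs$Q
  dimnames(P) <- NULL
  fs$x <- x
  fs$P <- (P + t(P)) / 2
  fs$t <- t
  fs
}

#' EKF measurement update with a DO observation
#'
#' Standard update: innovation `Y = z - H x`, innovation variance
#' `S = H P H' + R`, gain `K = P H' / S`, then `x <- x + K Y` and
#' `P <- (I - K H) P`, followed by symmetrization and constraint projection
#' of the state.
#'
#' @param fs An a-priori `filter_state` (from [ekf_predict()]).
#' @param z_do Measured DO, mg/L.
#' @param config A [filter_config()] object.
#' @return The a-posteriori `filter_state`; fields `innovation` and `S` hold
#'   the innovation record of this step.
#' @export
ekf_update <- function(fs, z_do, config = filter_config()) {
  stopifnot(inherits(fs, "filter_state"), is.finite(z_do))
  Y <- z_do - fs$x[4]
  S <- fs$P[4, 4] + fs$R
  if (S <= 0) stop("innovation variance is not positive (numerical degeneracy)")
  K <- fs$P[, 4] / S
  fs$x <- fs$x + K * Y
  P <- (diag(4L) - K %*% .H_DO) %*% fs$P
  fs$P <- (P + t(P)) / 2
  fs$x <- project_state(fs$x, config)
  fs$k <- fs$k + 1L
  fs$innovation <- Y
  fs$S <- S
  fs$innovations <- c(fs$innovations, Y)
  fs$S_hist <- c(fs$S_hist, S)
  fs
}

#' Project a state onto the physically admissible set
#'
#' Componentwise clipping: biomasses to `[0, Inf)`, dissolved oxygen to
#' `[Omin, Omax]`.
#'
#' @param x State vector `[P, Z, F, O]`.
#' @param config A [filter_config()] object supplying `Omin`, `Omax`.
#' @return The projected state vector.
#' @export
project_state <- function(x, config = filter_config()) {
  x[1:3] <- pmax(x[1:3], 0)
  x[4] <- min(max(x[4], config$Omin), config$Omax)
  x
}

#' Mahalanobis innovation gate
#'
#' Computes `D^2 = Y' S^-1 Y` and accepts the measurement iff `D^2` does not
#' exceed the chi-square quantile at `chi2_level` with `length(Y)` degrees of
#' freedom. Rejected measurements are skipped: the filter keeps its
#' prediction for that step.
#'
#' @param Y Innovation (scalar for DO-only operation).
#' @param S Innovation covariance (scalar or matrix, positive definite).
#' @param config A [filter_config()] object.
#' @return List with `D2` and logical `accept`.
#' @export
anomaly_gate <- function(Y, S, config = filter_config()) {
  Y <- as.numeric(Y)
  d <- length(Y)
  D2 <- if (d == 1L) Y^2 / as.numeric(S)
        else as.numeric(crossprod(Y, solve(S, Y)))
  list(D2 = D2, accept = D2 <= stats::qchisq(config$chi2_level, df = d))
}

#' Physical-limit anomaly check
#'
#' Flags states that violate the biological or physical constraints (negative
#' biomass, DO outside `[Omin, Omax]`) before projection. A flagged state is
#' treated like a gated-out measurement: the update is skipped.
#'
#' @param x State vector `[P, Z, F, O]`.
#' @param config A [filter_config()] object.
#' @return List with logical `flagged` and a character vector `violations`.
#' @export
check_physical_anomaly <- function(x, config = filter_config()) {
  v <- character(0)
  if (x[1] < 0) v <- c(v, "P < 0")
  if (x[2] < 0) v <- c(v, "Z < 0")
  if (x[3] < 0) v <- c(v, "F < 0")
  if (x[4] < config$Omin) v <- c(v, "O < Omin")
  if (x[4] > config$Omax) v <- c(v, "O > Omax")
  list(flagged = length(v) > 0L, violations = v)
}

# Expected value of min(chi^2_1, g): winsorization correction that keeps the
# gated innovation-variance estimate unbiased under Gaussian operation.
.winsor_kappa <- function(g) {
  stats::pchisq(g, df = 3) + g * (1 - stats::pchisq(g, df = 1))
}

#' Innovation-based adaptation of Q and R
#'
#' Maintains an exponentially forgetting estimate `Chat` of the innovation
#' variance, updated with winsorized squared innovations
#' `min(Y^2, g*S) / kappa(g)` so the chi-square gate does not bias the
#' estimate low. The measurement variance tracks
#' `max(Chat - H P- H', R_floor)` at a tenth of the forgetting rate (the
#' sensor anchors R; Q absorbs fast changes), and the process noise is the
#' initial `Q0` scaled by the consistency ratio `Chat / S`, clipped to
#' `[0.1, 10] x Q0`.
#'
#' @param fs A `filter_state` that has seen at least one innovation.
#' @param config A [filter_config()] object.
#' @param P44_prior A-priori DO variance of the current step; defaults to
#'   `fs$S - fs$R`.
#' @return The `filter_state` with updated `Chat`, `R` and `Q`.
#' @export
adapt_noise <- function(fs, config = filter_config(), P44_prior = NULL) {
  stopifnot(inherits(fs, "filter_state"))
  if (is.null(fs$innovation) || length(fs$innovations) == 0L)
    stop("adapt_noise requires at least one innovation")
  if (!config$adapt) return(fs)
  lam <- config$adapt_lambda
  g <- stats::qchisq(config$chi2_level, df = 1)
  kap <- .winsor_kappa(g)
  Y <- fs$innovation
  S <- fs$S
  if (is.null(P44_prior)) P44_prior <- S - fs$R
  fs$Chat <- (1 - lam) * fs$Chat + lam * min(Y^2, g * S) / kap
  lamR <- lam / 10
  fs$R <- max((1 - lamR) * fs$R + lamR * max(fs$Chat - P44_prior, config$R_floor),
              config$R_floor)
  ratio <- fs$Chat / S
  Qnew <- fs$Q0 * min(max(ratio, 0.1), 10)
  diag(Qnew) <- pmax(diag(Qnew), config$Q_floor)
  fs$Q <- Qnew
  fs
}

#' Run the full constrained adaptive EKF over a DO record stream
#'
#' Executes the predict -> gate -> update -> project -> adapt cycle for every
#' measurement record and exposes the one-step-ahead DO predictions for
#' residual analysis. Measurements rejected by the Mahalanobis gate or lying
#' outside the physical DO limits leave the filter in prediction-only mode
#' for that step.
#'
#' @param records Data frame with columns `time` (days, sorted increasing)
#'   and `do_mg_l`; e.g. from [sample_measurements()]. The first record is
#'   used only to anchor the clock (the initial estimate is taken as given).
#' @param params An [ecosystem_params()] object.
#' @param forcing A [temperature_forcing()] object.
#' @param config A [filter_config()] object.
#' @param x0 Initial state estimate.
#' @param P0 Optional prior covariance (see [filter_init()]).
#' @param meas_std Sensor noise used for `R0` and the default prior.
#' @return An `ekf_run`: list with `estimates` (data frame: `time`,
#'   a-priori `pred_O`, a-posteriori `P`, `Z`, `F`, `O`, `innovation`, `S`,
#'   `D2`, `accepted`, `R`, `trQ`, and per-state posterior standard
#'   deviations `sd_P`, `sd_Z`, `sd_F`, `sd_O`), the final `filter_state`,
#'   and the configuration.
#' @export
run_ekf <- function(records, params, forcing, config = filter_config(),
                    x0, P0 = NULL, meas_std = 0.08) {
  stopifnot(is.data.frame(records), all(c("time", "do_mg_l") %in% names(records)))
  if (nrow(records) == 0L) stop("empty measurement record sequence")
  if (is.unsorted(records$time)) stop("records must be time-sorted")
  fs <- filter_init(x0, config, meas_std, P0, t0 = records$time[1])
  n <- nrow(records)
  out <- data.frame(time = records$time,
                    pred_O = NA_real_, P = NA_real_, Z = NA_real_,
                    F = NA_real_, O = NA_real_, innovation = NA_real_,
                    S = NA_real_, D2 = NA_real_, accepted = NA,
                    R = NA_real_, trQ = NA_real_,
                    sd_P = NA_real_, sd_Z = NA_real_,
                    sd_F = NA_real_, sd_O = NA_real_)
  out[1L, c("P", "Z", "F", "O")] <- fs$x
  out[1L, c("sd_P", "sd_Z", "sd_F", "sd_O")] <- sqrt(diag(fs$P))
  out$R[1L] <- fs$R
  out$trQ[1L] <- sum(diag(fs$Q))
  for (i in 2:n) {
    step_cfg <- config
    step_cfg$dt <- records$time[i] - records$time[i - 1L]
    if (step_cfg$dt <= 0) stop("records must be strictly increasing in time")
    fs <- ekf_predict(fs, params, forcing, step_cfg)
    z <- records$do_mg_l[i]
    out$pred_O[i] <- fs$x[4]
    Y <- z - fs$x[4]
    S <- fs$P[4, 4] + fs$R
    P44_prior <- fs$P[4, 4]
    gate <- anomaly_gate(Y, S, config)
    phys <- check_physical_anomaly(c(fs$x[1:3], z), config)
    accept <- gate$accept && !phys$flagged
    out$innovation[i] <- Y
    out$S[i] <- S
    out$D2[i] <- gate$D2
    out$accepted[i] <- accept
    if (accept) {
      fs <- ekf_update(fs, z, config)
    } else {
      # simple prognosis mode: keep the a-priori estimate for this step
      fs$x <- project_state(fs$x, config)
      fs$innovation <- Y
      fs$S <- S
      fs$innovations <- c(fs$innovations, Y)
      fs$S_hist <- c(fs$S_hist, S)
    }
    # adaptation sees every innovation; winsorization caps rejected spikes
    fs <- adapt_noise(fs, config, P44_prior = P44_prior)
    out[i, c("P", "Z", "F", "O")] <- fs$x
    out[i, c("sd_P", "sd_Z", "sd_F", "sd_O")] <- sqrt(pmax(diag(fs$P), 0))
    out$R[i] <- fs$R
    out$trQ[i] <- sum(diag(fs$Q))
  }
  structure(list(estimates = out, filter_state = fs, config = config),
            class = "ekf_run")
}

#' @export
print.ekf_run <- function(x, ...) {
  est <- x$estimates
  n <- nrow(est)
  cat("EKF run:", n, "records over",
      signif(est$time[n] - est$time[1], 4), "days;",
      sum(!est$accepted, na.rm = TRUE), "measurement(s) rejected\n")
  res <- est$innovation[est$accepted %in% TRUE]
  cat("one-step DO innovation sd:", signif(stats::sd(res), 3), "mg/L;",
      "final R:", signif(x$filter_state$R, 3), "\n")
  invisible(x)
}

#' Root-mean-square state-estimation error
#'
#' `RMSE = sqrt(mean_k ||x_true,k - x_hat,k||^2)` over the per-step Euclidean
#' norm of the state error; optionally per state component.
#'
#' @param truth,estimate Matrices or data frames of aligned state sequences
#'   (columns `P`, `Z`, `F`, `O` are used when present, otherwise all
#'   numeric columns).
#' @param per_component If `TRUE`, return the four componentwise RMSEs.
#' @return A scalar (or named numeric vector) in the state's units.
#' @export
state_rmse <- function(truth, estimate, per_component = FALSE) {
  pick <- function(a) {
    if (is.data.frame(a)) {
      cols <- intersect(c("P", "Z", "F", "O"), names(a))
      if (length(cols)) a <- a[cols]
      a <- as.matrix(a[vapply(a, is.numeric, TRUE)])
    }
    as.matrix(a)
  }
  A <- pick(truth); B <- pick(estimate)
  if (!all(dim(A) == dim(B))) stop("truth and estimate lengths differ")
  E <- A - B
  if (per_component) sqrt(colMeans(E^2)) else sqrt(mean(rowSums(E^2)))
}

#' Dimensionless system stability index
#'
#' `SI = 1 - mean_i(s_i / m_i)` where `s_i` and `m_i` are the standard
#' deviation and mean of each state component over the window. A constant
#' (quiescent) system has SI = 1; growing fluctuations push SI down.
#'
#' @param trajectory Matrix or data frame of state columns over the
#'   assessment window.
#' @return Scalar stability index.
#' @export
stability_index <- function(trajectory) {
  if (is.data.frame(trajectory)) {
    cols <- intersect(c("P", "Z", "F", "O"), names(trajectory))
    if (length(cols)) trajectory <- trajectory[cols]
    trajectory <- as.matrix(trajectory[vapply(trajectory, is.numeric, TRUE)])
  }
  X <- as.matrix(trajectory)
  if (nrow(X) == 0L) stop("empty window")
  m <- colMeans(X)
  if (any(abs(m) < 1e-9))
    stop("stability index undefined: a component mean is (near) zero")
  s <- apply(X, 2, stats::sd)
  1 - mean(s / m)
}
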