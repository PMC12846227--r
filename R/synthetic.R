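# Synthetic ground truth and sensor streams: the stand-in for field data.
# Emulates hourly DO sampling with Gaussian sensor noise, sparse chlorophyll-a
# sampling, per-step process noise on the true state, and isolated outliers.

#' Noise specification for synthetic data
#'
#' @param meas_std_DO DO measurement noise standard deviation, mg/L
#'   (default 0.08, a typical optical-probe error).
#' @param process_std Per-state, per-sampling-step process-noise standard
#'   deviation (default 0.02): unmodelled weather, inflow and biology.
#' @param chl_noise_std Chlorophyll-a measurement noise, ug/L.
#' @param outlier_rate Probability that a DO sample is an isolated spike.
#' @param outlier_magnitude Absolute spike size, mg/L.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   synthetic data.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(meas_std_DO = 0.08, process_std = 0.02,
                       chl_noise_std = 0.5, outlier_rate = 0,
                       outlier_magnitude = 5, seed = NULL) {
  stopifnot(meas_std_DO >= 0, process_std >= 0, chl_noise_std >= 0,
            outlier_rate >= 0, outlier_rate < 1, outlier_magnitude >= 0)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(meas_std_DO = meas_std_DO, process_std = process_std,
                 chl_noise_std = chl_noise_std, outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude, seed = seed),
            class = "noise_spec")
}

#' Sampling schedule of the sensor network
#'
#' @param do_interval Interval between DO/temperature samples, hours.
#' @param chl_interval Interval between chlorophyll-a samples, days.
#' @param duration Length of the record, days.
#' @return An object of class `sampling_schedule`.
#' @export
sampling_schedule <- function(do_interval = 1, chl_interval = 3,
                              duration = 30) {
  stopifnot(do_interval > 0, chl_interval > 0, duration > 0)
  structure(list(do_interval = do_interval, chl_interval = chl_interval,
                 duration = duration),
            class = "sampling_schedule")
}

# Run `expr` under a local RNG state seeded with `seed` (NULL = use the
# current stream). The caller's RNG state is restored afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate the true pond trajectory at the sensor sampling grid
#'
#' Integrates the P-Z-F-O model between consecutive DO sampling instants
#' (fixed-step RK4 substeps) and, if `process_std > 0`, perturbs every state
#' component at each sampling instant with independent zero-mean Gaussian
#' noise before projecting back to the admissible set (biomasses >= 0, DO
#' clipped to `[0, 20]` mg/L).
#'
#' @param params An [ecosystem_params()] object.
#' @param forcing A [temperature_forcing()] object.
#' @param noise A [noise_spec()] object; only `process_std` and `seed` are
#'   used here.
#' @param x0 Initial state `[P, Z, F, O]`.
#' @param schedule A [sampling_schedule()] object.
#' @param dt Integration substep, days (default 0.01).
#' @return A `pond_sim`: data frame with columns `time` (days), `P`, `Z`,
#'   `F`, `O`, `temp_c`, one row per DO sampling instant.
#' @export
simulate_truth <- function(params, forcing, noise, x0, schedule, dt = 0.01) {
  validate_state(x0)
  stopifnot(inherits(noise, "noise_spec"), inherits(schedule, "sampling_schedule"))
  step_days <- schedule$do_interval / 24
  times <- seq(0, schedule$duration, by = step_days)
  n <- length(times)
  n_sub <- max(1L, ceiling(step_days / dt))
  h <- step_days / n_sub
  .with_seed(noise$seed, {
    out <- matrix(NA_real_, n, 4L)
    x <- as.numeric(x0)
    out[1L, ] <- x
    for (i in 2:n) {
      t <- times[i - 1L]
      for (s in seq_len(n_sub)) {
        x <- .rk4_step(x, t, h, params, forcing)
        x <- pmax(x, 0)
        t <- t + h
      }
      if (any(!is.finite(x)))
        stop("truth simulation diverged at t = ", signif(times[i], 6), " days")
      if (noise$process_std > 0) {
        x <- x + stats::rnorm(4L, 0, noise$process_std)
        x[1:3] <- pmax(x[1:3], 0)
        x[4] <- min(max(x[4], 0), 20)
      }
      out[i, ] <- x
    }
    res <- data.frame(time = times, P = out[, 1], Z = out[, 2], F = out[, 3],
                      O = out[, 4], temp_c = temperature_series(forcing, times))
    class(res) <- c("pond_sim", "pond_trajectory", "data.frame")
    res
  })
}

#' Sample sensor measurements from a simulated truth
#'
#' DO records are drawn at every sampling instant with Gaussian measurement
#' noise; temperature is copied noise-free; chlorophyll-a records are placed
#' every `chl_interval` days and computed from the true `P` and `Z` through
#' the effective-biomass proxy `Cchl = kchl * max(P - alpha*Z, 0)` plus
#' Gaussian noise.
#'
#' @param sim A `pond_sim` from [simulate_truth()].
#' @param coeffs An [indirect_coeffs()] calibration; used for chlorophyll.
#' @param noise A [noise_spec()] object.
#' @param schedule A [sampling_schedule()] object (must not exceed the
#'   simulated duration).
#' @return Data frame of measurement records: `time` (days), `do_mg_l`,
#'   `temp_c`, `chl_ug_l` (`NA` between chlorophyll samples), and a logical
#'   `has_chl` flag.
#' @export
sample_measurements <- function(sim, coeffs = indirect_coeffs(quiet = TRUE),
                                noise = noise_spec(), schedule = sampling_schedule()) {
  stopifnot(inherits(sim, "pond_sim") || is.data.frame(sim),
            inherits(coeffs, "indirect_coeffs"),
            inherits(noise, "noise_spec"),
            inherits(schedule, "sampling_schedule"))
  if (schedule$duration > max(sim$time) + 1e-9)
    stop("schedule duration exceeds the simulated time span")
  step_days <- schedule$do_interval / 24
  keep <- sim$time <= schedule$duration + 1e-9
  sim <- sim[keep, , drop = FALSE]
  n <- nrow(sim)
  .with_seed(noise$seed, {
    do_meas <- sim$O + stats::rnorm(n, 0, noise$meas_std_DO)
    chl_at <- seq(0, schedule$duration, by = schedule$chl_interval)
    idx <- vapply(chl_at, function(tc) which.min(abs(sim$time - tc)), 1L)
    chl <- rep(NA_real_, n)
    peff <- pmax(sim$P[idx] - coeffs$alpha * sim$Z[idx], 0)
    chl[idx] <- coeffs$kchl * peff +
      stats::rnorm(length(idx), 0, noise$chl_noise_std)
    data.frame(time = sim$time, do_mg_l = do_meas, temp_c = sim$temp_c,
               chl_ug_l = chl, has_chl = !is.na(chl))
  })
}

#' Inject isolated outlier spikes into DO records
#'
#' Each DO record is independently spiked by `+/- outlier_magnitude` with
#' probability `outlier_rate` (sign chosen at random). The true outlier
#' positions are returned so downstream outlier-elimination can be scored.
#'
#' @param records Measurement records from [sample_measurements()].
#' @param noise A [noise_spec()] object (`outlier_rate`, `outlier_magnitude`,
#'   `seed`).
#' @return List with elements `records` (spiked copy) and `outlier_idx`
#'   (integer positions of injected spikes).
#' @export
inject_outliers <- function(records, noise) {
  stopifnot(is.data.frame(records), "do_mg_l" %in% names(records),
            inherits(noise, "noise_spec"))
  n <- nrow(records)
  .with_seed(noise$seed, {
    hit <- stats::runif(n) < noise$outlier_rate
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    records$do_mg_l <- records$do_mg_l +
      ifelse(hit, sgn * noise$outlier_magnitude, 0)
    list(records = records, outlier_idx = which(hit))
  })
}
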