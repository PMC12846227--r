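# Shared fixtures: the simulation-study configuration and small generators.

std_params <- function() ecosystem_params(Osat_base = 10)
std_forcing <- function() temperature_forcing(T_mean = 18, amplitude = 8,
                                              period = 25)
std_x0 <- function() state_vec(1.5, 0.8, 0.3, 9.0)

# A random valid state in the physically plausible box.
random_state <- function() {
  c(P = runif(1, 0.05, 4.5), Z = runif(1, 0.05, 2.5),
    F = runif(1, 0.05, 1.5), O = runif(1, 4, 14))
}

# Central finite-difference Jacobian of the model right-hand side.
fd_jacobian <- function(x, params, temp_c, h = 1e-6) {
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    e <- numeric(4); e[j] <- h
    J[, j] <- (pond_rhs(x + e, params, temp_c) -
               pond_rhs(x - e, params, temp_c)) / (2 * h)
  }
  J
}

# A standard noisy 30-day synthetic run plus its EKF pass, used by several
# filter tests.
std_run <- function(seed = 1, days = 30) {
  ns <- noise_spec(seed = seed)
  sch <- sampling_schedule(duration = days)
  sim <- simulate_truth(std_params(), std_forcing(), ns, std_x0(), sch)
  rec <- sample_measurements(sim, noise = ns, schedule = sch)
  run <- run_ekf(rec, std_params(), std_forcing(), filter_config(), std_x0())
  list(sim = sim, rec = rec, run = run)
}

# Hourly timestamps starting at local midnight, for the clock-based layers.
hourly_timestamps <- function(n, origin = "2025-09-01 00:00:00") {
  as.POSIXct(origin, tz = "UTC") + 3600 * (seq_len(n) - 1L)
}
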