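# Constrained adaptive EKF: noise initialization, predict/update algebra,
# gating, projection, adaptation and full runs.

test_that("noise initialization follows the sensor spec and the Q rule", {
  cfg <- filter_config()
  expect_equal(init_noise(cfg, 0.1)$R0, 0.01)
  q <- init_noise(filter_config(Xi_max = c(5, 5, 5, 5)), 0.1)$Q0
  expect_equal(q[1, 1], (0.1 * 5 / 24)^2, tolerance = 1e-12)
  q0 <- init_noise(filter_config(alpha = 0, Xi_max = c(5, 3, 2, 20)), 0.1)$Q0
  expect_equal(diag(q0), rep(0, 4))
})

test_that("prediction is the identity under frozen dynamics and zero Q", {
  p0 <- ecosystem_params(rP = 1e-12, K = 5, gZ = 1e-12, gF = 1e-12,
                         hP = 0.5, hZ = 0.3, eZ = 0.4, eF = 0.3,
                         mP = 1e-12, mZ = 1e-12, mF = 1e-12,
                         aP = 1e-12, bR = 1e-12, k2 = 1e-12,
                         Osat_base = 10, allow_outside_range = TRUE)
  cfg <- filter_config(alpha = 0)
  fs <- filter_init(c(1, 0.5, 0.3, 9), cfg, meas_std = 0.08)
  fs2 <- ekf_predict(fs, p0, std_forcing(), cfg)
  expect_equal(fs2$x, fs$x, tolerance = 1e-10)
  expect_equal(fs2$P, fs$P, tolerance = 1e-10)
})

test_that("one-substep covariance prediction matches direct matrix arithmetic", {
  cfg <- filter_config(n_substeps = 1)
  fs <- filter_init(std_x0(), cfg, meas_std = 0.08)
  P0 <- fs$P
  fs2 <- ekf_predict(fs, std_params(), std_forcing(), cfg)
  J <- pond_jacobian(std_x0(), std_params(), temperature_series(std_forcing(), 0))
  F1 <- diag(4) + J / 24
  expect_equal(fs2$P, F1 %*% P0 %*% t(F1) + fs$Q, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("covariance stays symmetric positive semidefinite over many steps", {
  set.seed(31)
  cfg <- filter_config()
  fs <- filter_init(std_x0(), cfg, meas_std = 0.08)
  for (i in 1:300) {
    fs <- ekf_predict(fs, std_params(), std_forcing(), cfg)
    expect_equal(fs$P, t(fs$P))
    if (i %% 3 == 0) {
      prior_var_O <- fs$P[4, 4]
      fs <- ekf_update(fs, fs$x[4] + rnorm(1, 0, 0.1), cfg)
      expect_lte(fs$P[4, 4], prior_var_O + 1e-12)  # update never adds variance
    }
    expect_gte(min(eigen(fs$P, symmetric = TRUE, only.values = TRUE)$values),
               -1e-9)
  }
})

test_that("measurement update follows scalar Kalman algebra", {
  cfg <- filter_config()
  fs <- filter_init(c(1, 0.5, 0.3, 9), cfg, meas_std = 0.08)
  fs$P <- diag(c(0.1, 0.1, 0.1, 1))
  fs$R <- 1
  # exact agreement: innovation zero, state unchanged
  fs0 <- ekf_update(fs, 9, cfg)
  expect_equal(fs0$x, fs$x)
  # S = 2, gain on O = 0.5, posterior var(O) = 0.5
  fs1 <- ekf_update(fs, 10, cfg)
  expect_equal(fs1$S, 2)
  expect_equal(fs1$x[4], 9.5)
  expect_equal(fs1$P[4, 4], 0.5)
  # no-information limit
  fs$R <- 1e12
  fs2 <- ekf_update(fs, 15, cfg)
  expect_equal(fs2$x, fs$x, tolerance = 1e-6)
})

test_that("constraint projection clips to the admissible set", {
  cfg <- filter_config(Omin = 0, Omax = 20)
  expect_equal(project_state(c(-0.1, 0.5, 0.2, 25), cfg), c(0, 0.5, 0.2, 20))
  expect_equal(project_state(c(1, 0.5, 0.2, 9), cfg), c(1, 0.5, 0.2, 9))
  expect_equal(project_state(c(-1, -1, -1, -5), cfg), c(0, 0, 0, 0))
})

test_that("chi-square gate accepts and rejects on the 90% critical value", {
  cfg <- filter_config(chi2_level = 0.90)
  g0 <- anomaly_gate(0, 1, cfg)
  expect_equal(g0$D2, 0)
  expect_true(g0$accept)
  g1 <- anomaly_gate(1, 1, cfg)
  expect_equal(g1$D2, 1)
  expect_true(g1$accept)          # 1 <= 2.7055
  g2 <- anomaly_gate(2, 1, cfg)
  expect_equal(g2$D2, 4)
  expect_false(g2$accept)         # 4 > 2.7055
})

test_that("physical-limit check flags impossible states", {
  cfg <- filter_config(Omin = 0, Omax = 20)
  bad <- check_physical_anomaly(c(1, 0.5, 0.3, 25), cfg)
  expect_true(bad$flagged)
  expect_true("O > Omax" %in% bad$violations)
  expect_false(check_physical_anomaly(c(1, 0.5, 0.3, 9), cfg)$flagged)
  expect_true(check_physical_anomaly(c(1, 0.5, -0.01, 9), cfg)$flagged)
})

test_that("noise adaptation is consistent, responsive and floored", {
  cfg <- filter_config()
  R_true <- 0.0064
  P44 <- 0.002
  S <- P44 + R_true
  mk <- function() {
    fs <- filter_init(std_x0(), cfg, meas_std = 0.08)
    fs$Chat <- S
    fs$R <- R_true
    fs
  }
  # innovations exactly consistent with S: R drifts by < 5%
  set.seed(5)
  fs <- mk()
  for (i in 1:5000) {
    fs$innovation <- rnorm(1, 0, sqrt(S))
    fs$S <- S
    fs$innovations <- 1
    fs <- adapt_noise(fs, cfg, P44_prior = P44)
  }
  expect_lt(abs(fs$R - R_true) / R_true, 0.05)
  # doubling the true measurement noise raises the estimate
  set.seed(6)
  fs <- mk()
  for (i in 1:2000) {
    fs$innovation <- rnorm(1, 0, sqrt(S))
    fs$S <- S
    fs$innovations <- 1
    fs <- adapt_noise(fs, cfg, P44_prior = P44)
  }
  R_before <- fs$R
  S2 <- P44 + 4 * R_true          # doubled noise std
  for (i in 1:2000) {
    fs$innovation <- rnorm(1, 0, sqrt(S2))
    fs$S <- S2
    fs$innovations <- 1
    fs <- adapt_noise(fs, cfg, P44_prior = P44)
  }
  expect_gt(fs$R, R_before)
  # the floor is never undercut
  fs <- mk()
  for (i in 1:3000) {
    fs$innovation <- 0
    fs$S <- S
    fs$innovations <- 1
    fs <- adapt_noise(fs, cfg, P44_prior = P44)
  }
  expect_gte(fs$R, cfg$R_floor)
})

test_that("EKF reduces to a textbook linear Kalman filter on affine dynamics", {
  eps <- 1e-12
  p <- ecosystem_params(rP = eps, K = 5, gZ = eps, gF = eps,
                        hP = 0.5, hZ = 0.3, eZ = 0.4, eF = 0.3,
                        mP = 0.05, mZ = 0.05, mF = 0.02,
                        aP = 0.3, bR = 0.1, k2 = 0.15, Osat_base = 10,
                        allow_outside_range = TRUE)
  f0 <- temperature_forcing(T_mean = 20, amplitude = 0)
  cfg <- filter_config(integrator = "euler", n_substeps = 1, adapt = FALSE)
  h <- cfg$dt
  x0 <- c(1, 0.5, 0.3, 9)
  set.seed(8)
  n <- 120
  z <- 9 + rnorm(n, 0, 0.05)
  rec <- data.frame(time = (0:(n - 1)) / 24, do_mg_l = z)
  P0 <- diag(c(0.25, 0.25, 0.25, 0.08^2))
  run <- run_ekf(rec, p, f0, cfg, x0, P0 = P0, meas_std = 0.08)
  # hand-coded affine KF with the same first-order discretization
  A <- diag(4) + h * rbind(c(-0.05, 0, 0, 0),
                           c(0, -0.05, 0, 0),
                           c(0, 0, -0.02, 0),
                           c(0.3 - 0.1, -0.1, -0.1, -0.15))
  b <- h * c(0, 0, 0, 0.15 * 10)
  H <- c(0, 0, 0, 1)
  qr0 <- init_noise(cfg, 0.08)
  P <- P0
  x <- x0
  R <- qr0$R0
  for (i in 2:n) {
    x <- A %*% x + b
    P <- A %*% P %*% t(A) + qr0$Q0
    S <- drop(t(H) %*% P %*% H) + R
    K <- P %*% H / S
    x <- x + K * (z[i] - x[4])
    P <- (diag(4) - K %*% t(H)) %*% P
  }
  expect_lt(max(abs(run$estimates[n, c("P", "Z", "F", "O")] - t(x))), 1e-8)
})

test_that("a perfect model with exact start tracks the truth tightly", {
  ns <- noise_spec(meas_std_DO = 0, process_std = 0)
  sch <- sampling_schedule(duration = 30)
  sim <- simulate_truth(std_params(), std_forcing(), ns, std_x0(), sch)
  rec <- sample_measurements(sim, noise = ns, schedule = sch)
  run <- run_ekf(rec, std_params(), std_forcing(), filter_config(), std_x0())
  err <- abs(as.matrix(run$estimates[c("P", "Z", "F", "O")]) -
             as.matrix(sim[c("P", "Z", "F", "O")]))
  expect_lt(max(err), 1e-3)
})

test_that("an injected spike is gated out without disturbing the estimate", {
  ns <- noise_spec(seed = 12)
  sch <- sampling_schedule(duration = 10)
  sim <- simulate_truth(std_params(), std_forcing(), ns, std_x0(), sch)
  rec <- sample_measurements(sim, noise = ns, schedule = sch)
  k <- 150
  rec$do_mg_l[k] <- rec$do_mg_l[k] + 10
  run <- run_ekf(rec, std_params(), std_forcing(), filter_config(), std_x0())
  est <- run$estimates
  expect_false(est$accepted[k])
  expect_lt(abs(est$O[k] - est$pred_O[k]), 0.5)
})

test_that("state RMSE follows its definition", {
  A <- matrix(0, 2, 1)
  expect_equal(state_rmse(A, A), 0)
  expect_equal(state_rmse(A, matrix(c(1, -1), 2, 1)), 1)
  tr <- matrix(rnorm(40), 10, 4)
  off <- tr
  off[, 2] <- off[, 2] + 0.7   # constant offset on one component
  expect_equal(state_rmse(tr, off), 0.7)
  expect_equal(unname(state_rmse(tr, off, per_component = TRUE)),
               c(0, 0.7, 0, 0))
  expect_error(state_rmse(tr, tr[1:5, ]), "differ")
})

test_that("stability index is 1 for quiescent windows and falls with swings", {
  const <- matrix(3, 20, 4)
  expect_equal(stability_index(const), 1)
  two <- cbind(rep(2, 100), 4 + rep(c(-1, 1), 50) * sqrt(99 / 100))
  expect_equal(stability_index(two), 0.875, tolerance = 1e-9)
  tt <- seq(0, 4 * pi, length.out = 200)
  small <- cbind(10 + sin(tt), 10 + sin(tt))
  big <- cbind(10 + 3 * sin(tt), 10 + 3 * sin(tt))
  expect_gt(stability_index(small), stability_index(big))
  expect_error(stability_index(cbind(rep(0, 5), rep(1, 5))), "undefined")
})
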