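# Operative layer: outlier elimination, cleaning, aggregation, trend fits,
# time-to-critical and the decision procedure.

test_that("isolated spikes and band violations are eliminated", {
  y <- c(5.0, 5.1, 9.9, 5.2, 5.0)
  out <- eliminate_outliers(1:5, y, neighbor_delta = 2)
  expect_equal(which(out$outlier), 3L)
  expect_equal(out$y, y[-3])
  # all consecutive gaps below the threshold: nothing flagged
  smooth <- eliminate_outliers(1:6, c(5, 5.5, 6, 6.4, 6.8, 7),
                               neighbor_delta = 2)
  expect_false(any(smooth$outlier))
  # absolute band overrides neighbours
  low <- eliminate_outliers(1:4, c(5, 1, 5.2, 5.3), abs_low = 3,
                            neighbor_delta = Inf)
  expect_equal(which(low$outlier), 2L)
  expect_error(eliminate_outliers(1:2, c(1, 2)), "too few")
})

test_that("outlier elimination agrees with a brute-force rule application", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    y <- cumsum(rnorm(n))
    y[sample(n, 2)] <- y[sample(n, 2)] + sample(c(-8, 8), 2, replace = TRUE)
    lo <- -6; hi <- 6; del <- 3
    out <- eliminate_outliers(seq_len(n), y, lo, hi, del)
    brute <- vapply(seq_len(n), function(i) {
      if (y[i] < lo || y[i] > hi) return(TRUE)
      nb <- c(if (i > 1) y[i - 1], if (i < n) y[i + 1])
      all(abs(y[i] - nb) > del)
    }, TRUE)
    expect_identical(out$outlier, brute)
  }
})

test_that("median filter interpolates anomalies and preserves clean series", {
  expect_equal(median_filter_clean(c(5, 5, 50, 5, 5), window = 3),
               c(5, 5, 5, 5, 5))
  ramp <- seq(1, 10, by = 0.5)
  expect_equal(median_filter_clean(ramp, window = 3), ramp)
  expect_equal(median_filter_clean(rep(4, 10), window = 5), rep(4, 10))
  expect_error(median_filter_clean(1:3, window = 5), "longer")
})

test_that("daily statistics group by calendar day", {
  ts <- hourly_timestamps(720)
  rec <- data.frame(timestamp = ts, do_mg_l = rep(7, 720), temp_c = 18)
  ds <- daily_stats(rec)
  expect_equal(nrow(ds), 30)
  expect_equal(ds$do_mg_l_min, ds$do_mg_l_max)
  # a sinusoid with known daily extremes
  hod <- as.numeric(format(ts, "%H"))
  rec2 <- data.frame(timestamp = ts,
                     do_mg_l = 8 + 2 * sin(2 * pi * (hod - 6) / 24))
  ds2 <- daily_stats(rec2)
  expect_equal(max(ds2$do_mg_l_max), 10, tolerance = 0.05)
  expect_equal(min(ds2$do_mg_l_min), 6, tolerance = 0.05)
})

test_that("day/night segmentation uses the 06:00/21:00 boundaries", {
  ts <- as.POSIXct("2025-09-01 00:00:00", tz = "UTC") +
    c(5.9833, 6, 20.9833, 21) * 3600
  seg <- segment_day_night(data.frame(timestamp = ts))$segment
  expect_equal(as.character(seg), c("night", "day", "day", "night"))
  day1 <- segment_day_night(data.frame(timestamp = hourly_timestamps(24)))
  expect_equal(sum(day1$segment == "day"), 15)
  expect_equal(sum(day1$segment == "night"), 9)
})

test_that("exact curves are recovered with unit correlation", {
  t <- 0:5
  lin <- fit_curve(t, 2 * t + 1, "linear")
  expect_equal(lin$coefficients, c(1, 2), tolerance = 1e-12)
  expect_equal(lin$r, 1, tolerance = 1e-12)
  ex <- fit_curve(t, 2 * exp(0.5 * t), "exponential")
  expect_equal(ex$coefficients, c(2, 0.5), tolerance = 1e-10)
  expect_equal(ex$r, 1, tolerance = 1e-10)
  expect_error(fit_curve(t, c(1, 2, -1, 4, 5, 6), "exponential"), "positive")
  expect_error(fit_curve(rep(1, 5), 1:5, "linear"), "singular")
})

test_that("cubic least squares equals the explicit normal-equations solution", {
  set.seed(19)
  t <- seq(0, 6, by = 1)
  y <- 0.5 - 0.3 * t + 0.08 * t^2 - 0.01 * t^3 + rnorm(7, 0, 0.1)
  fit <- fit_curve(t, y, "cubic")
  X <- cbind(1, t, t^2, t^3)
  a_ne <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fit$coefficients, as.numeric(a_ne), tolerance = 1e-8)
})

test_that("returned fits are local least-squares minima", {
  set.seed(29)
  t <- seq(0, 9, by = 1)
  y <- 3 + 0.4 * t + rnorm(10, 0, 0.2)
  for (type in c("linear", "cubic")) {
    fit <- fit_curve(t, y, type)
    sse0 <- sum((predict(fit, t) - y)^2)
    for (j in seq_along(fit$coefficients)) {
      for (d in c(-1e-4, 1e-4)) {
        pert <- fit
        pert$coefficients[j] <- pert$coefficients[j] + d
        expect_gt(sum((predict(pert, t) - y)^2), sse0)
      }
    }
  }
})

test_that("fit correlation follows the product-moment formula", {
  set.seed(23)
  t <- 1:5
  y <- c(2.1, 2.9, 4.2, 4.8, 6.1)
  fit <- fit_curve(t, y, "linear")
  yh <- predict(fit, t)
  r_direct <- sum((yh - mean(yh)) * (y - mean(y))) /
    sqrt(sum((yh - mean(yh))^2) * sum((y - mean(y))^2))
  expect_equal(curve_correlation(fit, t, y), r_direct)
  flat <- curve_fit("linear", c(mean(y), 0))
  expect_error(curve_correlation(flat, t, y), "undefined")
})

test_that("time-to-critical solves the three curve families", {
  lin <- curve_fit("linear", c(10, -1))             # 10 - t
  cr <- time_to_critical(lin, 5, t_now = 2, horizon = 24)
  expect_equal(cr$t_crit, 5)
  expect_equal(cr$lead, 3)
  ex <- curve_fit("exponential", c(8, -0.1))        # 8 exp(-0.1 t)
  expect_equal(time_to_critical(ex, 4, 0, 24)$t_crit, log(2) / 0.1,
               tolerance = 1e-9)
  rising <- curve_fit("linear", c(10, 1))           # moving away from 5
  expect_null(time_to_critical(rising, 5, 0, 24))
  cub <- curve_fit("cubic", c(9, -0.05, -0.01, -0.002))
  got <- time_to_critical(cub, 6, 0, 24)
  # dense-sampling root bracketing oracle
  grid <- seq(0, 24, by = 1e-4)
  gv <- predict(cub, grid) - 6
  i <- which(gv[-1] * gv[-length(gv)] <= 0)[1]
  expect_equal(got$t_crit, grid[i], tolerance = 1e-3)
  f <- function(tt) predict(cub, tt) - 6
  expect_lt(abs(f(got$t_crit)), 1e-8)
  expect_equal(got$t_crit, uniroot(f, c(grid[i], grid[i + 1]),
                                   tol = 1e-12)$root, tolerance = 1e-6)
})

test_that("the decision procedure reproduces its three branches", {
  set.seed(37)
  t <- 0:9
  # unreliable: scattered data
  noisy <- c(7, 9, 6.5, 8.8, 7.2, 9.1, 6.8, 8.5, 7.4, 8)
  d1 <- make_decision(t, noisy, "linear", critical = 4)
  expect_equal(d1$action, "none")
  expect_equal(d1$reason, "unreliable-fit")
  expect_lt(d1$r, 0.85)
  # reliable and imminent: falling toward the threshold
  fall <- 8 - 0.5 * t + rnorm(10, 0, 0.05)
  d2 <- make_decision(t, fall, "linear", critical = 3)
  expect_equal(d2$action, "initiate")
  expect_equal(d2$reason, "reliable-and-imminent")
  expect_lt(d2$lead, 4)
  # reliable but distant: slow decline
  slow <- 8 - 0.05 * t + rnorm(10, 0, 0.01)
  d3 <- make_decision(t, slow, "linear", critical = 4, horizon = 100)
  expect_equal(d3$action, "none")
  expect_equal(d3$reason, "not-imminent")
  expect_gt(d3$lead, 4)
})

test_that("initiate requires both a reliable fit and an imminent crossing", {
  # decision-table sweep over correlation and lead combinations
  set.seed(43)
  t <- 0:9
  cases <- expand.grid(slope = c(-0.5, -0.05), noise = c(0.02, 1.2))
  for (i in seq_len(nrow(cases))) {
    y <- 8 + cases$slope[i] * t + rnorm(10, 0, cases$noise[i])
    d <- make_decision(t, y, "linear", critical = 3, preset_lead = 4,
                       horizon = 200)
    reliable <- !is.na(d$r) && d$r >= 0.85
    imminent <- !is.na(d$lead) && d$lead < 4
    expect_equal(d$action == "initiate", reliable && imminent)
  }
})

test_that("stage errors collapse to a no-action unreliable-fit decision", {
  d <- make_decision(c(1, 2), c(5, 6), "linear", critical = 4)  # too few
  expect_equal(d$action, "none")
  expect_equal(d$reason, "unreliable-fit")
})

test_that("species thresholds trigger the documented alerts", {
  lim <- species_limits("sterlet")
  al <- check_conditions(c(1, 0.5, 0.3, 3.4), lim)
  expect_true("fish-death" %in% al$rule)
  expect_equal(al$threshold[al$rule == "fish-death"], 3.5)
  expect_true("respiratory-depression" %in% al$rule)
  # pH stratification ratio 8.6 / 8.0 = 1.075 > 1.05
  al2 <- check_conditions(c(1, 0.5, 0.3, 7), species_limits("carp"),
                          ph_surface = 8.6, ph_bottom = 8.0)
  expect_true("ph-stratification" %in% al2$rule)
  expect_true("ph-out-of-range" %in% al2$rule)  # 8.6 > 8.5 as well
  # unmixed-water and bloom and fish-danger rules
  al3 <- check_conditions(c(2.7, 0.5, 0.05, 10.5), species_limits("carp"))
  expect_setequal(al3$rule,
                  c("stratification-mixing", "algal-bloom", "fish-danger"))
  # mid-range state raises nothing
  al4 <- check_conditions(c(1.5, 0.8, 0.3, 7.5), species_limits("carp"),
                          ph_surface = 7.8, ph_bottom = 7.6)
  expect_equal(nrow(al4), 0)
})

test_that("salmonids use the tighter alkaline pH bound", {
  expect_equal(species_limits("peled")$pH_high, 8.0)
  expect_equal(species_limits("carp")$pH_high, 8.5)
  al <- check_conditions(c(1, 0.5, 0.3, 7), species_limits("peled"),
                         ph_surface = 8.2, ph_bottom = 8.1)
  expect_true("ph-out-of-range" %in% al$rule)
})

test_that("event resets truncate the usable history", {
  h <- data.frame(time = 1:100, y = rnorm(100))
  expect_equal(nrow(reset_on_event(h, 1)), 100)     # event at the start
  expect_equal(nrow(reset_on_event(h, 61)), 40)
  post <- reset_on_event(h, 101)                    # event at the end
  expect_equal(nrow(post), 0)
  expect_error(eliminate_outliers(post$time, post$y), "too few")
})
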