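# Operative short-term layer: outlier elimination, least-squares trend
# fitting with correlation gating, time-to-critical estimation, day/night
# segmentation, species threshold rules and the decision procedure.
#
# Time in this layer is the sensor clock, in hours.

#' Distance-based outlier elimination
#'
#' A point is flagged if its value lies outside the absolute band
#' `[abs_low, abs_high]`, or if it is an isolated spike: the absolute
#' difference to *both* adjacent values exceeds `neighbor_delta` (endpoints
#' use their single neighbour). Flagged points are excluded from fitting but
#' kept in the returned mask.
#'
#' @param t,y Time (hours) and measured values, time-sorted, length >= 3.
#' @param abs_low,abs_high Absolute plausibility band for `y`.
#' @param neighbor_delta Neighbour-difference threshold.
#' @return List with `t`, `y` (kept points) and logical `outlier` mask over
#'   the input.
#' @examples
#' eliminate_outliers(1:5, c(5.0, 5.1, 9.9, 5.2, 5.0), neighbor_delta = 2)$outlier
#' @export
eliminate_outliers <- function(t, y, abs_low = -Inf, abs_high = Inf,
                               neighbor_delta = Inf) {
  n <- length(y)
  if (n < 3L) stop("too few points for outlier elimination (need >= 3)")
  if (length(t) != n) stop("t and y lengths differ")
  if (is.unsorted(t)) stop("points must be time-sorted")
  band <- y < abs_low | y > abs_high
  spike <- logical(n)
  dprev <- c(Inf, abs(diff(y)))          # |y_i - y_{i-1}|, Inf for the first
  dnext <- c(abs(diff(y)), Inf)          # |y_i - y_{i+1}|, Inf for the last
  spike[1] <- dnext[1] > neighbor_delta
  spike[n] <- dprev[n] > neighbor_delta
  if (n > 2L) {
    i <- 2:(n - 1L)
    spike[i] <- dprev[i] > neighbor_delta & dnext[i] > neighbor_delta
  }
  out <- band | spike
  list(t = t[!out], y = y[!out], outlier = out)
}

#' Median-filter cleaning of a sensor series
#'
#' Mirrors the field processing pipeline: points deviating from their
#' rolling median by more than `n_dev` times the rolling median absolute
#' deviation are treated as anomalous and replaced by linear interpolation
#' of the surrounding clean points.
#'
#' @param y Numeric series.
#' @param window Odd window length >= 3.
#' @param n_dev Deviation multiple that flags a point.
#' @return The cleaned series (same length).
#' @export
median_filter_clean <- function(y, window = 5L, n_dev = 3) {
  n <- length(y)
  if (window > n) stop("window longer than the series")
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  h <- (window - 1L) %/% 2L
  flag <- logical(n)
  for (i in seq_len(n)) {
    w <- y[max(1L, i - h):min(n, i + h)]
    med <- stats::median(w)
    mad_w <- stats::median(abs(w - med))
    flag[i] <- abs(y[i] - med) > n_dev * mad_w
  }
  if (!any(flag) || all(flag)) return(y)
  keep <- which(!flag)
  y[flag] <- stats::approx(keep, y[keep], xout = which(flag), rule = 2)$y
  y
}

# hour-of-day from either a POSIXct timestamp column or a numeric day clock
.hour_of_day <- function(records) {
  if ("timestamp" %in% names(records)) {
    lt <- as.POSIXlt(records$timestamp)
    lt$hour + lt$min / 60 + lt$sec / 3600
  } else if ("time" %in% names(records)) {
    (records$time %% 1) * 24
  } else stop("records need a 'timestamp' or 'time' column")
}

#' Daily minimum/maximum aggregation
#'
#' Groups records by calendar day and tabulates the minimum and maximum of
#' every numeric channel (DO, temperature, ...) per day.
#'
#' @param records Data frame with a `timestamp` (POSIXct) or `time`
#'   (days, numeric) column plus numeric channels.
#' @return Data frame with one row per day: `day` and `<channel>_min`,
#'   `<channel>_max` columns.
#' @export
daily_stats <- function(records) {
  stopifnot(is.data.frame(records))
  day <- if ("timestamp" %in% names(records)) as.Date(records$timestamp)
         else floor(records$time)
  chans <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                   c("time"))
  res <- data.frame(day = sort(unique(day)))
  for (ch in chans) {
    v <- records[[ch]]
    res[[paste0(ch, "_min")]] <-
      as.numeric(tapply(v, day, function(z) suppressWarnings(min(z, na.rm = TRUE))))
    res[[paste0(ch, "_max")]] <-
      as.numeric(tapply(v, day, function(z) suppressWarnings(max(z, na.rm = TRUE))))
  }
  res
}

#' Day/night segmentation of sensor records
#'
#' Labels each record `day` when its clock time lies in `[06:00, 21:00)`
#' and `night` otherwise (boundary convention: inclusive start). DO and pH
#' change monotonically within each segment, so trend fits are performed
#' per segment.
#'
#' @param records Data frame with a `timestamp` or fractional-day `time`
#'   column.
#' @param day_start,night_start Segment boundaries, hours of day.
#' @return `records` with an added factor column `segment`.
#' @export
segment_day_night <- function(records, day_start = 6, night_start = 21) {
  hod <- .hour_of_day(records)
  records$segment <- factor(ifelse(hod >= day_start & hod < night_start,
                                   "day", "night"),
                            levels = c("day", "night"))
  records
}

#' Construct a trend curve directly from coefficients
#'
#' @param curve_type `"linear"` (`a1 + a2*t`), `"exponential"`
#'   (`a1 * exp(a2*t)`) or `"cubic"` (`a1 + a2*t + a3*t^2 + a4*t^3`).
#' @param coefficients Numeric vector `a1, a2[, a3, a4]`.
#' @param r Correlation coefficient of the fit, if known.
#' @param n_points Number of points the fit used.
#' @return An object of class `curve_fit`.
#' @export
curve_fit <- function(curve_type = c("linear", "exponential", "cubic"),
                      coefficients, r = NA_real_, n_points = NA_integer_) {
  curve_type <- match.arg(curve_type)
  need <- if (curve_type == "cubic") 4L else 2L
  if (length(coefficients) != need)
    stop(curve_type, " curve needs ", need, " coefficients")
  if (!is.na(r) && (r < -1 || r > 1)) stop("r must lie in [-1, 1]")
  structure(list(curve_type = curve_type,
                 coefficients = as.numeric(coefficients),
                 r = r, n_points = n_points),
            class = "curve_fit")
}

#' Evaluate a trend curve
#'
#' @param object A `curve_fit`.
#' @param t Times (hours) at which to evaluate.
#' @param ... Unused.
#' @return Fitted values `f(t)`.
#' @export
predict.curve_fit <- function(object, t, ...) {
  a <- object$coefficients
  switch(object$curve_type,
         linear = a[1] + a[2] * t,
         exponential = a[1] * exp(a[2] * t),
         cubic = a[1] + a[2] * t + a[3] * t^2 + a[4] * t^3)
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(x$curve_type, "trend fit: a = (",
      paste(signif(x$coefficients, 5), collapse = ", "),
      "), r =", signif(x$r, 4), ", n =", x$n_points, "\n")
  invisible(x)
}

#' Correlation between a fitted curve and the measurements
#'
#' Pearson correlation between the fitted values `f(t_i)` and the
#' measurements `y_i`, computed from the explicit product-moment formula.
#' The fit is considered reliable only when `r` exceeds the configured gate
#' (0.8--0.9).
#'
#' @param fit A `curve_fit`.
#' @param t,y The measured points.
#' @return Scalar `r` in `[-1, 1]`.
#' @export
curve_correlation <- function(fit, t, y) {
  if (length(y) < 2L) stop("need at least two points for a correlation")
  yh <- predict(fit, t)
  num <- sum((yh - mean(yh)) * (y - mean(y)))
  den <- sqrt(sum((yh - mean(yh))^2) * sum((y - mean(y))^2))
  if (den == 0)
    stop("correlation undefined: fitted values or measurements are constant")
  num / den
}

#' Least-squares trend fit of sensor data
#'
#' Fits one of the three standard approximation curves by least squares:
#' linear and cubic through the normal equations (via `stats::lm`), the
#' exponential by log-linearization (requires strictly positive values).
#'
#' @param t,y Measured points (time in hours); >= 3 points (>= 5 for the
#'   cubic).
#' @param curve_type `"linear"`, `"exponential"` or `"cubic"`.
#' @return A [curve_fit()] with coefficients and the correlation `r` between
#'   fit and data.
#' @examples
#' fit_curve(0:5, 2 * (0:5) + 1, "linear")
#' @export
fit_curve <- function(t, y, curve_type = c("linear", "exponential", "cubic")) {
  curve_type <- match.arg(curve_type)
  n <- length(y)
  if (length(t) != n) stop("t and y lengths differ")
  min_n <- if (curve_type == "cubic") 5L else 3L
  if (n < min_n) stop("too few points for a ", curve_type, " fit (need >= ",
                      min_n, ")")
  if (length(unique(t)) < 2L) stop("singular design: all times equal")
  if (curve_type == "exponential" && any(y <= 0))
    stop("exponential fit requires strictly positive values")
  a <- switch(curve_type,
    linear = unname(stats::coef(stats::lm(y ~ t))),
    exponential = {
      co <- unname(stats::coef(stats::lm(log(y) ~ t)))
      c(exp(co[1]), co[2])
    },
    cubic = {
      if (length(unique(t)) < 4L) stop("singular design for a cubic fit")
      unname(stats::coef(stats::lm(y ~ t + I(t^2) + I(t^3))))
    })
  fit <- curve_fit(curve_type, a, n_points = n)
  fit$r <- curve_correlation(fit, t, y)
  fit
}

#' Time at which a trend reaches a critical value
#'
#' Finds the earliest `t > t_now` inside the look-ahead window at which the
#' fitted curve crosses `critical`. Linear and exponential curves are solved
#' in closed form; the cubic by sign-change bracketing on a dense grid
#' followed by root polishing.
#'
#' @param fit A `curve_fit`.
#' @param critical Critical parameter value (units of `y`).
#' @param t_now Current time, hours.
#' @param horizon Look-ahead window length, hours.
#' @return List with `t_crit` (absolute, hours) and `lead` (hours), or
#'   `NULL` when the curve does not reach the critical value in the window.
#' @examples
#' f <- curve_fit("linear", c(10, -1))   # 10 - t
#' time_to_critical(f, 5, t_now = 2, horizon = 24)  # crossing at t = 5
#' @export
time_to_critical <- function(fit, critical, t_now = 0, horizon = 24) {
  a <- fit$coefficients
  t_end <- t_now + horizon
  t_crit <- switch(fit$curve_type,
    linear = {
      if (a[2] == 0) NA_real_ else (critical - a[1]) / a[2]
    },
    exponential = {
      if (a[1] <= 0 || critical <= 0 || a[2] == 0) NA_real_
      else log(critical / a[1]) / a[2]
    },
    cubic = {
      grid <- seq(t_now, t_end, length.out = 2001L)
      g <- predict(fit, grid) - critical
      hit <- NA_real_
      if (any(g == 0)) hit <- grid[which(g == 0)[1]]
      sgn <- which(g[-1] * g[-length(g)] < 0)
      if (length(sgn)) {
        br <- stats::uniroot(function(tt) predict(fit, tt) - critical,
                             lower = grid[sgn[1]], upper = grid[sgn[1] + 1L],
                             tol = 1e-10)$root
        hit <- if (is.na(hit)) br else min(hit, br)
      }
      hit
    })
  if (is.na(t_crit) || t_crit <= t_now || t_crit > t_end) return(NULL)
  list(t_crit = t_crit, lead = t_crit - t_now)
}

#' Decision procedure for a predicted water parameter
#'
#' The operative decision rule: eliminate outliers, fit the trend curve,
#' gate on the fit correlation, extrapolate to the critical value and
#' compare the lead time with the preset corrective-action level.
#' Corrective measures are initiated only for a reliable fit (correlation
#' at least `r_min`) whose predicted crossing is imminent
#' (`lead < preset_lead`). Any failure inside the pipeline (too few points,
#' unfittable data, undefined correlation) yields no action with reason
#' `"unreliable-fit"`.
#'
#' @param t,y Measured points, time in hours.
#' @param curve_type One of `"linear"`, `"exponential"`, `"cubic"`, or
#'   `"auto"` to fit all applicable families and keep the highest `r`
#'   (ties broken in favour of the simpler curve: linear, then exponential,
#'   then cubic).
#' @param critical Critical value of the parameter.
#' @param preset_lead Preset corrective-action lead, hours (3--5 h
#'   typically; default 4).
#' @param r_min Correlation gate (default 0.85; the customary range is
#'   0.8--0.9).
#' @param abs_low,abs_high,neighbor_delta Outlier-elimination settings.
#' @param t_now Decision time; defaults to the last measurement time.
#' @param horizon Look-ahead window, hours.
#' @return A `pond_decision`: list with `action` (`"initiate"`/`"none"`),
#'   `reason` (`"reliable-and-imminent"`, `"not-imminent"`,
#'   `"unreliable-fit"`), `r`, `t_crit`, `lead`, `preset_lead`, the chosen
#'   `fit` and the outlier mask.
#' @export
make_decision <- function(t, y, curve_type = "auto", critical,
                          preset_lead = 4, r_min = 0.85,
                          abs_low = -Inf, abs_high = Inf,
                          neighbor_delta = Inf,
                          t_now = NULL, horizon = 24) {
  if (r_min < 0.8 - 1e-12 || r_min > 0.9 + 1e-12)
    warning("r_min outside the customary 0.8-0.9 band", call. = FALSE)
  dec <- function(action, reason, r = NA_real_, t_crit = NA_real_,
                  lead = NA_real_, fit = NULL, outlier = NULL)
    structure(list(action = action, reason = reason, r = r, t_crit = t_crit,
                   lead = lead, preset_lead = preset_lead, fit = fit,
                   outlier = outlier),
              class = "pond_decision")
  res <- tryCatch({
    kept <- eliminate_outliers(t, y, abs_low, abs_high, neighbor_delta)
    fits <- if (identical(curve_type, "auto")) {
      cand <- list()
      cand$linear <- tryCatch(fit_curve(kept$t, kept$y, "linear"),
                              error = function(e) NULL)
      cand$exponential <- tryCatch(fit_curve(kept$t, kept$y, "exponential"),
                                   error = function(e) NULL)
      cand$cubic <- tryCatch(fit_curve(kept$t, kept$y, "cubic"),
                             error = function(e) NULL)
      cand <- Filter(Negate(is.null), cand)
      if (!length(cand)) stop("no curve family could be fitted")
      rs <- vapply(cand, function(f) f$r, numeric(1))
      cand[[which(rs >= max(rs) - 1e-12)[1]]]   # simplicity order on ties
    } else fit_curve(kept$t, kept$y, curve_type)
    if (is.null(t_now)) t_now <- max(kept$t)
    if (fits$r < r_min)
      return(dec("none", "unreliable-fit", r = fits$r, fit = fits,
                 outlier = kept$outlier))
    cross <- time_to_critical(fits, critical, t_now, horizon)
    if (is.null(cross) || cross$lead >= preset_lead)
      dec("none", "not-imminent", r = fits$r,
          t_crit = if (is.null(cross)) NA_real_ else cross$t_crit,
          lead = if (is.null(cross)) NA_real_ else cross$lead,
          fit = fits, outlier = kept$outlier)
    else
      dec("initiate", "reliable-and-imminent", r = fits$r,
          t_crit = cross$t_crit, lead = cross$lead, fit = fits,
          outlier = kept$outlier)
  }, error = function(e) dec("none", "unreliable-fit"))
  res
}

#' @export
print.pond_decision <- function(x, ...) {
  cat("decision:", x$action, "(", x$reason, ")")
  if (!is.na(x$r)) cat("  r =", signif(x$r, 4))
  if (!is.na(x$lead))
    cat("  crossing in", signif(x$lead, 4), "h (preset", x$preset_lead, "h)")
  cat("\n")
  invisible(x)
}

# DO tolerance limits by species: respiratory-depression range (upper/lower
# endpoint, mg/L), death level (upper endpoint of the published range), and
# whether the pH rules use the salmonid upper bound.
.SPECIES_TABLE <- data.frame(
  species = c("nelma", "sterlet", "muksun", "peled", "common dace",
              "european perch", "ide", "roach", "northern pike",
              "crucian carp", "carp"),
  resp_high = c(7.5, 7.5, 4.5, 4.5, 4.5, 4.5, 4.5, 3.0, 3.0, 2.0, 3.0),
  resp_low  = c(6.0, 6.0, 3.0, 3.0, 3.0, 3.0, 3.0, 2.0, 2.0, 1.0, 3.0),
  death_do  = c(4.5, 3.5, 2.0, 1.5, 1.2, 1.1, 0.5, 0.7, 0.6, 0.1, 0.5),
  salmonid  = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' Species-specific water-quality limits
#'
#' DO levels at which respiratory depression and death occur for the common
#' pond species, plus the pH tolerance band (upper bound 8.5 for carp-type
#' fish, 8.0 for salmonids) and the surface/bottom pH ratio limit above
#' which fish kill is probable.
#'
#' @param species Species name (case-insensitive; see
#'   `species_limits_table()`), or `"custom"` with explicit limits.
#' @param resp_high,resp_low,death_do Custom DO limits, mg/L.
#' @param pH_low,pH_high,pH_ratio_limit Custom pH rules.
#' @return An object of class `species_limits`.
#' @examples
#' species_limits("sterlet")$death_do  # 3.5
#' @export
species_limits <- function(species = "carp", resp_high = NULL,
                           resp_low = NULL, death_do = NULL,
                           pH_low = 6.5, pH_high = NULL,
                           pH_ratio_limit = 1.05) {
  species <- tolower(species)
  if (species != "custom") {
    row <- .SPECIES_TABLE[.SPECIES_TABLE$species == species, ]
    if (nrow(row) != 1L)
      stop("unknown species '", species, "'; see species_limits_table()")
    resp_high <- row$resp_high; resp_low <- row$resp_low
    death_do <- row$death_do
    if (is.null(pH_high)) pH_high <- if (row$salmonid) 8.0 else 8.5
  } else {
    if (is.null(resp_high) || is.null(resp_low) || is.null(death_do))
      stop("custom species limits need resp_high, resp_low and death_do")
    if (is.null(pH_high)) pH_high <- 8.5
  }
  if (!(death_do < resp_low))
    stop("death level must lie below the respiratory-depression range")
  if (!(pH_low < pH_high)) stop("pH_low must be below pH_high")
  structure(list(species = species, resp_high = resp_high,
                 resp_low = resp_low, death_do = death_do,
                 pH_low = pH_low, pH_high = pH_high,
                 pH_ratio_limit = pH_ratio_limit),
            class = "species_limits")
}

#' Published species DO-limit table
#'
#' @return Data frame of the built-in species limits.
#' @export
species_limits_table <- function() .SPECIES_TABLE

#' Critical-condition checks on an estimated pond state
#'
#' Evaluates the monitoring rules against a state estimate (and optional pH
#' readings): DO below the species respiratory-depression range or death
#' level, surface DO of 10 mg/L or more (unmixed water column;
#' stratification risk), phytoplankton above the 2.5 g/m^3 bloom threshold,
#' fish biomass below 0.1 g/m^3, pH outside the tolerance band, and a
#' surface/bottom pH ratio above the limit.
#'
#' @param state State vector `[P, Z, F, O]` (estimated or forecast).
#' @param limits A [species_limits()] object.
#' @param ph_surface,ph_bottom Optional pH readings.
#' @param do_surface Optional surface-layer DO, mg/L (for the mixing rule;
#'   defaults to the state's O).
#' @return Data frame of alerts with columns `rule`, `message`, `value`,
#'   `threshold`; zero rows when all checks pass.
#' @export
check_conditions <- function(state, limits = species_limits(),
                             ph_surface = NULL, ph_bottom = NULL,
                             do_surface = NULL) {
  stopifnot(inherits(limits, "species_limits"))
  P <- state[[1]]; F_ <- state[[3]]; O <- state[[4]]
  if (is.null(do_surface)) do_surface <- O
  alerts <- list()
  add <- function(rule, message, value, threshold)
    alerts[[length(alerts) + 1L]] <<-
      data.frame(rule = rule, message = message, value = value,
                 threshold = threshold, stringsAsFactors = FALSE)
  if (O < limits$death_do)
    add("fish-death", paste0("DO below the ", limits$species,
                             " death level"), O, limits$death_do)
  if (O < limits$resp_low)
    add("respiratory-depression",
        paste0("DO below the ", limits$species,
               " respiratory-depression range"), O, limits$resp_low)
  if (do_surface >= 10)
    add("stratification-mixing",
        "surface DO at or above 10 mg/L: water column likely unmixed; break stratification",
        do_surface, 10)
  if (P > 2.5)
    add("algal-bloom", "phytoplankton biomass above the bloom threshold",
        P, 2.5)
  if (F_ < 0.1)
    add("fish-danger", "fish biomass below the danger level", F_, 0.1)
  for (ph in c(ph_surface, ph_bottom)) {
    if (!is.null(ph) && (ph < limits$pH_low || ph > limits$pH_high)) {
      add("ph-out-of-range", "pH outside the species tolerance band",
          ph, if (ph < limits$pH_low) limits$pH_low else limits$pH_high)
      break
    }
  }
  if (!is.null(ph_surface) && !is.null(ph_bottom) && ph_bottom > 0) {
    ratio <- ph_surface / ph_bottom
    if (ratio > limits$pH_ratio_limit)
      add("ph-stratification",
          "surface/bottom pH ratio above the fish-kill limit",
          ratio, limits$pH_ratio_limit)
  }
  if (!length(alerts))
    return(data.frame(rule = character(0), message = character(0),
                      value = numeric(0), threshold = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, alerts)
}

#' Discard pre-event history after a pond intervention
#'
#' After an event that changes the water condition abruptly (chemical
#' treatment, aeration start, heavy rain, fish transfer), earlier
#' measurements are no longer predictive; trend fits must use post-event
#' data only.
#'
#' @param history Data frame with a `time` (or `timestamp`) column.
#' @param event_time Event time in the same units; records strictly before
#'   it are discarded.
#' @return The truncated history.
#' @export
reset_on_event <- function(history, event_time) {
  stopifnot(is.data.frame(history))
  tm <- if ("time" %in% names(history)) history$time
        else if ("timestamp" %in% names(history)) history$timestamp
        else stop("history needs a 'time' or 'timestamp' column")
  history[tm >= event_time, , drop = FALSE]
}
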