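#' Construct a growth series from samples and dilution events
#'
#' A growth series is one replicate's chlorophyll-fluorescence time series
#' from a semi-continuous (turbidostat-like) culture: samples at strictly
#' increasing times, punctuated by instantaneous dilution events with factors
#' >= 1. Cell density N is obtained from chlorophyll through a monotone
#' conversion curve (see [linear_conversion()]).
#'
#' @param times_days Strictly increasing numeric vector of sampling times
#'   (days).
#' @param chl_ug_L Positive chlorophyll-a concentrations (ug/L), same length.
#' @param dilution_times_days Times of dilution events (days), within the
#'   observation window; may be empty.
#' @param dilution_factors Dilution factors (>= 1), same length as
#'   `dilution_times_days`.
#' @param conversion A conversion curve from [linear_conversion()] or
#'   [piecewise_conversion()]; default is the identity (slope 1).
#' @return An object of class `growth_series`: a list with a `samples`
#'   tibble, a `dilutions` tibble and the conversion.
#' @export
growth_series <- function(times_days, chl_ug_L, dilution_times_days = numeric(0),
                          dilution_factors = numeric(0),
                          conversion = linear_conversion(1)) {
  stopifnot(length(times_days) == length(chl_ug_L))
  if (any(is.na(times_days)) || any(is.na(chl_ug_L))) {
    stop("NA/NaN in series", call. = FALSE)
  }
  if (any(diff(times_days) <= 0)) {
    stop("`times_days` must be strictly increasing", call. = FALSE)
  }
  if (any(chl_ug_L <= 0)) stop("chlorophyll values must be positive",
                               call. = FALSE)
  if (length(dilution_times_days) != length(dilution_factors)) {
    stop("dilution times and factors must have equal length", call. = FALSE)
  }
  if (length(dilution_times_days)) {
    if (any(dilution_factors < 1)) stop("dilution factors must be >= 1",
                                        call. = FALSE)
    if (any(dilution_times_days < min(times_days) |
            dilution_times_days > max(times_days))) {
      stop("dilution times must lie within the observation window",
           call. = FALSE)
    }
  }
  structure(
    list(
      samples = tibble::tibble(time_days = as.numeric(times_days),
                               chl_ug_L = as.numeric(chl_ug_L)),
      dilutions = tibble::tibble(time_days = as.numeric(dilution_times_days),
                                 factor = as.numeric(dilution_factors)),
      conversion = conversion
    ),
    class = "growth_series"
  )
}

#' @export
print.growth_series <- function(x, ...) {
  cat("<growth_series> ", nrow(x$samples), " samples over ",
      signif(diff(range(x$samples$time_days)), 4), " days, ",
      nrow(x$dilutions), " dilution(s)\n", sep = "")
  invisible(x)
}

#' Linear chlorophyll-to-density conversion curve
#'
#' Density is proportional to chlorophyll: `N = slope * chl`. The specific
#' growth rate is provably invariant to the slope (it cancels in the log
#' ratio), so the default slope of 1 is as good as any calibrated value.
#'
#' @param slope Positive cells-per-(ug/L) proportionality constant.
#' @export
linear_conversion <- function(slope = 1) {
  stopifnot(is.numeric(slope), slope > 0)
  structure(list(type = "linear", slope = slope), class = "chl_conversion")
}

#' Piecewise-linear chlorophyll-to-density conversion curve
#'
#' Interpolates a calibrated conversion curve; must be strictly increasing.
#' Extrapolation beyond the calibrated range is linear from the end segments.
#'
#' @param chl_ug_L,density Strictly increasing knots of the curve.
#' @export
piecewise_conversion <- function(chl_ug_L, density) {
  stopifnot(length(chl_ug_L) == length(density), length(chl_ug_L) >= 2)
  if (any(diff(chl_ug_L) <= 0) || any(diff(density) <= 0)) {
    stop("conversion curve must be strictly increasing (monotone)",
         call. = FALSE)
  }
  structure(list(type = "piecewise", chl = as.numeric(chl_ug_L),
                 density = as.numeric(density)),
            class = "chl_conversion")
}

#' Convert chlorophyll concentration to cell density
#'
#' @param chl_ug_L Positive chlorophyll values (ug/L).
#' @param conversion A conversion curve ([linear_conversion()] or
#'   [piecewise_conversion()]).
#' @return Cell densities on the curve's scale.
#' @export
chl_to_density <- function(chl_ug_L, conversion = linear_conversion(1)) {
  stopifnot(inherits(conversion, "chl_conversion"), all(chl_ug_L > 0))
  if (conversion$type == "linear") {
    conversion$slope * chl_ug_L
  } else {
    stats::approx(conversion$chl, conversion$density, xout = chl_ug_L,
                  rule = 2)$y
  }
}

#' Simulate a dilution-punctuated exponential growth series
#'
#' Between dilutions the expected density follows `N(t) = N0 * exp(mu * t)`.
#' Dilution events are evenly spaced (`n_dilutions` of them inside the
#' observation window) and each returns the culture to the chlorophyll
#' target, emulating semi-continuous turbidostat operation; for declining
#' cultures (`mu < 0`) no dilution is applied (factor 1). Observation noise
#' is multiplicative log-normal with the given coefficient of variation.
#'
#' @param mu_per_day Specific growth rate (day^-1); may be negative.
#' @param chl_target_ug_L Chlorophyll level the culture is kept near (ug/L).
#' @param n_dilutions Number of dilution events (>= 0).
#' @param duration_days Observation span (days), > 0.
#' @param sampling_interval_days Spacing of samples (days), > 0.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   observation noise; 0 disables noise.
#' @param seed Integer seed; same seed, same series.
#' @return A [growth_series()]. A sample taken exactly at a dilution time is
#'   post-dilution.
#' @examples
#' s <- generate_growth_series(0.17, seed = 1)
#' growth_rate(s)
#' @export
generate_growth_series <- function(mu_per_day, chl_target_ug_L = 10,
                                   n_dilutions = 3, duration_days = 21,
                                   sampling_interval_days = 0.5,
                                   noise_cv = 0, seed) {
  if (any(is.na(c(mu_per_day, chl_target_ug_L, duration_days,
                  sampling_interval_days, noise_cv)))) {
    stop("NaN/NA inputs are not allowed", call. = FALSE)
  }
  stopifnot(duration_days > 0, n_dilutions >= 0,
            sampling_interval_days > 0, chl_target_ug_L > 0, noise_cv >= 0)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)

  times <- seq(0, duration_days, by = sampling_interval_days)
  # evenly spaced events strictly inside the window
  dil_times <- duration_days * seq_len(n_dilutions) / (n_dilutions + 1)
  seg_span <- duration_days / (n_dilutions + 1)
  dil_factor <- rep(max(1, exp(mu_per_day * seg_span)), n_dilutions)

  # expected chlorophyll: exponential growth, divided at each event that
  # has occurred at or before t
  expected <- vapply(times, function(t) {
    n_done <- sum(dil_times <= t)
    chl_target_ug_L * exp(mu_per_day * t) /
      prod(dil_factor[seq_len(n_done)])
  }, numeric(1))

  chl <- withr::with_seed(seed, {
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      expected * stats::rlnorm(length(expected), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
    } else {
      expected
    }
  })
  growth_series(times, chl, dil_times, dil_factor)
}

#' Specific growth rate from a dilution-punctuated series
#'
#' Computes the specific growth rate
#' \eqn{\mu = (\ln N_f - \ln N_i) / (t_f - t_i)} (per day) over a window that
#' contains no dilution event. The default window spans the period between
#' the second and third dilutions, from the first sample strictly after the
#' opening dilution to the last sample strictly before the closing one.
#' Because any linear chlorophyll-to-density conversion cancels in the log
#' ratio, the estimate does not depend on the calibration slope.
#'
#' @param series A [growth_series()].
#' @param between_dilutions Length-2 integer, indices `(i, j = i + 1)` of the
#'   dilution events bounding the window; ignored when `window_times` is
#'   given. A series with fewer events uses the window after the last event.
#' @param window_times Optional explicit `(t_i, t_f)` window (days); must not
#'   contain a dilution strictly inside.
#' @param method `"endpoints"` uses the first and last sample of the window
#'   (the two-point log-ratio estimator); `"regression"` fits
#'   `lm(log(N) ~ t)` over all samples in the window.
#' @return The estimated growth rate (day^-1), as a single number.
#' @examples
#' s <- generate_growth_series(0.17, seed = 1)
#' growth_rate(s)                       # 0.17
#' growth_rate(s, window_times = c(16, 20), method = "regression")
#' @export
growth_rate <- function(series, between_dilutions = c(2L, 3L),
                        window_times = NULL,
                        method = c("endpoints", "regression")) {
  stopifnot(inherits(series, "growth_series"))
  method <- match.arg(method)
  s <- series$samples
  dt <- series$dilutions$time_days

  if (is.null(window_times)) {
    stopifnot(length(between_dilutions) == 2,
              between_dilutions[2] == between_dilutions[1] + 1)
    i <- between_dilutions[1]
    lo <- if (i >= 1 && i <= length(dt)) dt[i] else min(s$time_days) - 1
    hi <- if (between_dilutions[2] <= length(dt)) dt[between_dilutions[2]]
          else max(s$time_days) + 1
    keep <- s$time_days > lo & s$time_days < hi
  } else {
    stopifnot(length(window_times) == 2, window_times[2] > window_times[1])
    inside <- dt > window_times[1] & dt < window_times[2]
    if (any(inside)) {
      stop("dilution event(s) at ",
           paste(signif(dt[inside], 4), collapse = ", "),
           " days lie inside the window; estimate per inter-dilution ",
           "window instead (see `between_dilutions`)", call. = FALSE)
    }
    keep <- s$time_days >= window_times[1] & s$time_days <= window_times[2]
  }
  w <- s[keep, ]
  if (nrow(w) < 2) stop("window contains fewer than 2 samples", call. = FALSE)
  dens <- chl_to_density(w$chl_ug_L, series$conversion)
  if (any(dens <= 0)) stop("nonpositive density in window", call. = FALSE)

  if (method == "endpoints") {
    n <- nrow(w)
    (log(dens[n]) - log(dens[1])) / (w$time_days[n] - w$time_days[1])
  } else {
    unname(stats::coef(stats::lm(log(dens) ~ w$time_days))[2])
  }
}

#' Tidy table of a growth series
#'
#' One row per sample with an `event` column (`"none"` or
#' `"dilution:<factor>"` for samples at or just after an event), matching the
#' on-disk CSV layout of [write_growth_series()].
#'
#' @param x A [growth_series()].
#' @param ... Unused.
#' @method tidy growth_series
#' @export
tidy.growth_series <- function(x, ...) {
  s <- x$samples
  ev <- rep("none", nrow(s))
  for (k in seq_len(nrow(x$dilutions))) {
    # tag the first sample at/after each event
    idx <- which(s$time_days >= x$dilutions$time_days[k])[1]
    if (!is.na(idx)) {
      ev[idx] <- sprintf("dilution:%.15g", x$dilutions$factor[k])
    }
  }
  dplyr::mutate(s, event = ev)
}
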