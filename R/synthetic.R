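#' True distributed-lag exposure-response surface
#'
#' Ground-truth generative surface for the synthetic count model: the
#' log-rate on day t rises linearly in the exposure excess over a threshold,
#' distributed over lags 0..L with fixed non-negative weights summing to 1,
#' \deqn{\log \mu_t = \log(\mathrm{baseline}) +
#'   \beta \sum_{l=0}^{L} w_l \max(0, x_{t-l} - \tau).}
#' With weights summing to one, the true cumulative relative risk of
#' sustained exposure x (vs any reference at or below the threshold) is
#' `exp(slope * (x - threshold))`, which downstream model-recovery checks
#' compare against.
#'
#' @param exposure_name Which series drives the counts: one of
#'   `"heat_index"`, `"dew_point"`, `"tmax"`, `"rh"`, `"tmean"`.
#' @param threshold Exposure threshold (units of the exposure).
#' @param slope Log relative risk per exposure unit above the threshold.
#' @param lag_weights Non-negative weights over lags `0..L`; normalised to
#'   sum to 1.
#' @return An object of class `true_lag_surface`.
#' @export
true_lag_surface <- function(exposure_name = "tmax", threshold = 30,
                             slope = 0.05,
                             lag_weights = 0.5^(0:5)) {
  exposure_name <- match.arg(exposure_name,
                             c("heat_index", "dew_point", "tmax", "rh", "tmean"))
  lag_weights <- as.numeric(lag_weights)
  if (any(!is.finite(lag_weights)) || any(lag_weights < 0) ||
      sum(lag_weights) <= 0)
    stop("lag weights must be finite, non-negative, not all zero",
         call. = FALSE)
  if (!is.finite(threshold) || !is.finite(slope))
    stop("threshold and slope must be finite", call. = FALSE)
  structure(list(exposure_name = exposure_name, threshold = threshold,
                 slope = slope,
                 lag_weights = lag_weights / sum(lag_weights),
                 max_lag = length(lag_weights) - 1L),
            class = "true_lag_surface")
}

#' Synthetic-series configuration
#'
#' Parameters of the synthetic May-September weather generator. Daily mean
#' temperature follows a seasonal sinusoid peaking in late July plus AR(1)
#' Gaussian noise; daily maximum adds a positive offset; relative humidity
#' is linearly anti-coupled to the mean temperature with its own noise and
#' is clipped to \[5, 100\] percent.
#'
#' Defaults describe a humid subtropical summer: seasonal mean 26 C with
#' 4 C amplitude peaking around 26 July, 2 C day-to-day noise with AR(1)
#' coefficient 0.6, humidity base 75 percent coupled at -1.5 percent per
#' degree C.
#'
#' @param years Integer vector of calendar years (non-empty).
#' @param season_span Character pair of month-day strings, start and end of
#'   the in-season window.
#' @param temp_mean Seasonal mean of daily mean temperature, degrees C.
#' @param temp_amplitude Amplitude of the seasonal sinusoid, degrees C.
#' @param temp_peak_doy Day-of-year at which the sinusoid peaks.
#' @param temp_noise_sd Innovation standard deviation of the AR(1)
#'   temperature noise, degrees C.
#' @param temp_ar_coef AR(1) coefficient in (-1, 1).
#' @param tmax_offset_mean,tmax_offset_sd Mean and sd of the (truncated
#'   positive) daily Tmax - Tmean offset, degrees C.
#' @param rh_base Humidity level (percent) at the seasonal mean temperature.
#' @param rh_temp_coupling Humidity change per degree C of Tmean (percent
#'   per degree, typically negative).
#' @param rh_noise_sd Humidity noise sd, percent.
#' @param count_baseline Expected daily cases at reference (sub-threshold)
#'   conditions.
#' @param lag_effect A [true_lag_surface()].
#' @param seed Mandatory integer seed; all draws flow from one generator.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(years = 2014:2019,
                             season_span = c("05-01", "09-30"),
                             temp_mean = 26, temp_amplitude = 4,
                             temp_peak_doy = 207,
                             temp_noise_sd = 2, temp_ar_coef = 0.6,
                             tmax_offset_mean = 5, tmax_offset_sd = 1.5,
                             rh_base = 75, rh_temp_coupling = -1.5,
                             rh_noise_sd = 6,
                             count_baseline = 2,
                             lag_effect = true_lag_surface(),
                             seed) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is mandatory for the synthetic generator", call. = FALSE)
  years <- as.integer(years)
  if (length(years) == 0L || anyNA(years))
    stop("'years' must be a non-empty vector of calendar years", call. = FALSE)
  if (abs(temp_ar_coef) >= 1)
    stop("'temp_ar_coef' must lie in (-1, 1)", call. = FALSE)
  stopifnot(inherits(lag_effect, "true_lag_surface"))
  structure(list(years = years, season_span = season_span,
                 temp_mean = temp_mean, temp_amplitude = temp_amplitude,
                 temp_peak_doy = temp_peak_doy,
                 temp_noise_sd = temp_noise_sd, temp_ar_coef = temp_ar_coef,
                 tmax_offset_mean = tmax_offset_mean,
                 tmax_offset_sd = tmax_offset_sd,
                 rh_base = rh_base, rh_temp_coupling = rh_temp_coupling,
                 rh_noise_sd = rh_noise_sd,
                 count_baseline = count_baseline, lag_effect = lag_effect,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

season_dates <- function(year, span) {
  seq(as.Date(sprintf("%d-%s", year, span[1])),
      as.Date(sprintf("%d-%s", year, span[2])), by = "day")
}

#' Deterministic seasonal temperature curve
#'
#' The noise-free sinusoidal component of the synthetic daily mean
#' temperature; exposed so tests and users can compare generated series
#' against the deterministic limit.
#'
#' @param dates `Date` vector.
#' @param config A [synthetic_config()].
#' @return Numeric vector of degrees C.
#' @export
seasonal_tmean <- function(dates, config) {
  doy <- as.integer(format(as.Date(dates), "%j"))
  config$temp_mean + config$temp_amplitude *
    cos(2 * pi * (doy - config$temp_peak_doy) / 365.25)
}

#' Generate synthetic daily weather
#'
#' Simulates the in-season (May-September by default) weather table:
#' `tmean_c` = seasonal sinusoid + AR(1) noise (noise restarts each season,
#' seasons being separated by winter gaps), `tmax_c` = `tmean_c` plus a
#' positive offset, `rh_pct` = base + coupling x (tmean - seasonal mean
#' level) + noise, clipped to \[5, 100\].
#'
#' @param config A [synthetic_config()].
#' @return A data frame with columns `date`, `tmean_c`, `tmax_c`, `rh_pct`.
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- globalenv()$.Random.seed
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  out <- do.call(rbind, lapply(config$years, function(y) {
    dates <- season_dates(y, config$season_span)
    n <- length(dates)
    base <- seasonal_tmean(dates, config)
    innov <- stats::rnorm(n, 0, config$temp_noise_sd)
    noise <- as.numeric(stats::filter(innov, config$temp_ar_coef,
                                      method = "recursive"))
    tmean <- base + noise
    offset <- abs(stats::rnorm(n, config$tmax_offset_mean,
                               config$tmax_offset_sd))
    rh <- config$rh_base + config$rh_temp_coupling * (tmean - config$temp_mean) +
      stats::rnorm(n, 0, config$rh_noise_sd)
    data.frame(date = dates, tmean_c = tmean, tmax_c = tmean + offset,
               rh_pct = pmin(100, pmax(5, rh)))
  }))
  rownames(out) <- NULL
  out
}

#' Generate Poisson heatstroke counts from a known lag surface
#'
#' Adds a `count` column to a weather table, drawing
#' `count_t ~ Poisson(mu_t)` with
#' `log mu_t = log(baseline) + slope * sum_l w_l * max(0, x_(t-l) - threshold)`
#' where x is the configured exposure series. Lags do not cross season
#' boundaries: within each contiguous date block the first `max_lag` days
#' are flagged `burn_in = 1` and should be excluded from model fitting.
#'
#' @param weather Data frame from [generate_weather()] (columns `date`,
#'   `tmean_c`, `tmax_c`, `rh_pct`; derived exposures are computed on the
#'   fly if requested by the surface).
#' @param surface A [true_lag_surface()].
#' @param baseline Expected daily count at sub-threshold exposure.
#' @param seed Integer seed for the count draws.
#' @return `weather` with integer `count` and 0/1 `burn_in` columns added.
#' @export
generate_counts <- function(weather, surface, baseline = 2, seed) {
  stopifnot(inherits(surface, "true_lag_surface"))
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  x <- switch(surface$exposure_name,
              tmax = weather$tmax_c,
              tmean = weather$tmean_c,
              rh = weather$rh_pct,
              heat_index = heat_index(weather$tmean_c, weather$rh_pct),
              dew_point = dew_point(weather$tmean_c, weather$rh_pct))
  L <- surface$max_lag
  dates <- as.Date(weather$date)
  block <- cumsum(c(1L, as.integer(diff(dates) != 1L)))
  if (min(table(block)) <= L)
    stop(sprintf("each contiguous block needs more than max_lag = %d days", L),
         call. = FALSE)
  excess <- pmax(0, x - surface$threshold)
  # lag sums computed per contiguous block so lags never cross a season gap
  eta <- rep(NA_real_, length(x))
  burn <- integer(length(x))
  for (b in unique(block)) {
    idx <- which(block == b)
    e <- excess[idx]
    lagged <- vapply(seq_along(idx), function(t) {
      ls <- 0:min(L, t - 1L)
      sum(surface$lag_weights[ls + 1L] * e[t - ls])
    }, numeric(1))
    eta[idx] <- log(baseline) + surface$slope * lagged
    burn[idx[seq_len(min(L, length(idx)))]] <- 1L
  }
  mu <- exp(eta)
  if (any(!is.finite(mu)))
    stop(sprintf("non-finite Poisson rate on %s",
                 paste(format(dates[!is.finite(mu)])[1], collapse = ", ")),
         call. = FALSE)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  weather$count <- stats::rpois(length(mu), mu)
  weather$burn_in <- burn
  weather
}

#' Generate a full synthetic daily series
#'
#' Convenience wrapper: weather plus counts from one configuration. The
#' count seed is derived deterministically from the configuration seed.
#'
#' @param config A [synthetic_config()].
#' @return Daily series with weather, `count` and `burn_in` columns.
#' @export
generate_daily_series <- function(config) {
  weather <- generate_weather(config)
  generate_counts(weather, config$lag_effect, config$count_baseline,
                  seed = config$seed + 1L)
}
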