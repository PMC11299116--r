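#' Magnus formula parameters
#'
#' Constants of the Magnus dew-point approximation. The defaults
#' (`a = 17.27`, `b = 237.7` degrees C) are the classical
#' Magnus-Tetens values used throughout applied meteorology.
#'
#' @param a Dimensionless Magnus coefficient, must be positive.
#' @param b Magnus temperature constant in degrees C, must be positive.
#' @return An object of class `magnus_params`.
#' @export
magnus_params <- function(a = 17.27, b = 237.7) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("'b' must be a single positive finite number", call. = FALSE)
  structure(list(a = a, b = b), class = "magnus_params")
}

#' Dew-point temperature (Magnus formula)
#'
#' Computes the dew-point temperature Td from air temperature and relative
#' humidity using the Magnus approximation
#' \deqn{T_d = \frac{b\,\gamma(T, RH)}{a - \gamma(T, RH)}, \qquad
#'       \gamma(T, RH) = \frac{aT}{b + T} + \ln(RH/100).}
#' At saturation (`rh = 100`) the identity `dew_point(t, 100) == t` holds to
#' machine precision; for `rh < 100` the dew point lies strictly below the
#' air temperature.
#'
#' @param t Air temperature in degrees C (vectorised). Must exceed `-b`.
#' @param rh Relative humidity in percent, in (0, 100].
#' @param params A [magnus_params()] object.
#' @return Dew-point temperature in degrees C, same length as the inputs.
#' @examples
#' dew_point(30, 70)  # ~23.9 C
#' @export
dew_point <- function(t, rh, params = magnus_params()) {
  stopifnot(inherits(params, "magnus_params"))
  n <- max(length(t), length(rh))
  t <- rep_len(as.numeric(t), n)
  rh <- rep_len(as.numeric(rh), n)
  if (any(!is.finite(t)) || any(!is.finite(rh)))
    stop("non-finite temperature or humidity", call. = FALSE)
  if (any(rh <= 0) || any(rh > 100))
    stop("relative humidity must lie in (0, 100]", call. = FALSE)
  if (any(t <= -params$b))
    stop(sprintf("temperature must exceed -b = %g C", -params$b), call. = FALSE)
  gamma <- params$a * t / (params$b + t) + log(rh / 100)
  params$b * gamma / (params$a - gamma)
}

#' Heat-index regression coefficients
#'
#' The apparent-temperature ("heat index") polynomial
#' \deqn{HI = c_1 + c_2 T + c_3 RH + c_4 T\,RH + c_5 T^2 + c_6 RH^2
#'       + c_7 T^2 RH + c_8 T\,RH^2 + c_9 T^2 RH^2}
#' needs a concrete coefficient set. The default is the NOAA/NWS Rothfusz
#' regression, which is Fahrenheit-native; [heat_index()] converts from and
#' to Celsius around it. `valid_from_f` is the temperature (deg F) above
#' which the full regression applies; below it the NWS simple formula
#' (Steadman-style average) is used instead.
#'
#' @param coefs Numeric vector of exactly 9 finite coefficients, in the
#'   order c1..c9 of the polynomial above.
#' @param valid_from_f Lower temperature bound (deg F) of the regression's
#'   applicability range.
#' @return An object of class `heat_index_coefs`.
#' @export
heat_index_coefs <- function(coefs = c(-42.379, 2.04901523, 10.14333127,
                                       -0.22475541, -6.83783e-3, -5.481717e-2,
                                       1.22874e-3, 8.5282e-4, -1.99e-6),
                             valid_from_f = 80) {
  coefs <- as.numeric(coefs)
  if (length(coefs) != 9L || any(!is.finite(coefs)))
    stop("exactly 9 finite coefficients are required", call. = FALSE)
  structure(list(coefs = coefs, valid_from_f = as.numeric(valid_from_f)),
            class = "heat_index_coefs")
}

c_to_f <- function(c) c * 9 / 5 + 32
f_to_c <- function(f) (f - 32) * 5 / 9

#' Heat index (apparent temperature)
#'
#' Computes the heat index from air temperature and relative humidity with
#' the NWS algorithm: the simple low-range formula
#' `0.5 * (T + 61 + 1.2 * (T - 68) + 0.094 * RH)` (deg F) everywhere, and
#' when its average with the temperature reaches the applicability bound
#' (80 deg F by default) the full 9-term Rothfusz regression with the
#' standard low-humidity and high-humidity adjustments. Inputs and output
#' are in degrees C; the regression itself runs on the Fahrenheit scale its
#' coefficients were fitted on.
#'
#' @param t Air temperature in degrees C (vectorised).
#' @param rh Relative humidity in percent, in \[0, 100\].
#' @param coefs A [heat_index_coefs()] object.
#' @return Heat index in degrees C.
#' @examples
#' heat_index(32.2, 70)  # about 40.6 C (105 F)
#' @export
heat_index <- function(t, rh, coefs = heat_index_coefs()) {
  stopifnot(inherits(coefs, "heat_index_coefs"))
  n <- max(length(t), length(rh))
  t <- rep_len(as.numeric(t), n)
  rh <- rep_len(as.numeric(rh), n)
  if (any(!is.finite(t)) || any(!is.finite(rh)))
    stop("non-finite temperature or humidity", call. = FALSE)
  if (any(rh < 0) || any(rh > 100))
    stop("relative humidity must lie in [0, 100]", call. = FALSE)
  tf <- c_to_f(t)
  simple <- 0.5 * (tf + 61 + (tf - 68) * 1.2 + rh * 0.094)
  hi <- simple
  full <- (simple + tf) / 2 >= coefs$valid_from_f
  if (any(full)) {
    tff <- tf[full]; rhf <- rh[full]
    cc <- coefs$coefs
    reg <- cc[1] + cc[2] * tff + cc[3] * rhf + cc[4] * tff * rhf +
      cc[5] * tff^2 + cc[6] * rhf^2 + cc[7] * tff^2 * rhf +
      cc[8] * tff * rhf^2 + cc[9] * tff^2 * rhf^2
    low <- rhf < 13 & tff > 80 & tff < 112
    reg[low] <- reg[low] -
      ((13 - rhf[low]) / 4) * sqrt((17 - abs(tff[low] - 95)) / 17)
    high <- rhf > 85 & tff > 80 & tff < 87
    reg[high] <- reg[high] + ((rhf[high] - 85) / 10) * ((87 - tff[high]) / 5)
    hi[full] <- reg
  }
  f_to_c(hi)
}

#' Detect high-temperature heatwave days
#'
#' Flags every day belonging to a heatwave under the China Meteorological
#' Administration rule: a run of three or more consecutive calendar days
#' whose daily maximum temperature is at or above the high-temperature
#' threshold (35 C). A gap in the date sequence breaks a run, so seasons
#' separated by winter months never join into one run.
#'
#' @param dates `Date` vector, strictly increasing, no duplicates.
#' @param tmax Daily maximum temperature in degrees C, same length.
#' @param threshold High-temperature-day threshold in degrees C.
#' @param min_run Minimum run length that constitutes a heatwave.
#' @return Integer vector of 0/1 flags aligned with `dates`.
#' @export
detect_heatwaves <- function(dates, tmax, threshold = 35, min_run = 3L) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable dates", call. = FALSE)
  if (anyDuplicated(dates)) stop("duplicate dates in series", call. = FALSE)
  if (is.unsorted(dates, strictly = TRUE))
    stop("dates must be strictly increasing", call. = FALSE)
  if (length(tmax) != length(dates))
    stop("'tmax' and 'dates' lengths differ", call. = FALSE)
  n <- length(dates)
  flag <- integer(n)
  if (n == 0L) return(flag)
  hot <- tmax >= threshold
  # split runs on calendar gaps as well as on cool days
  consec <- c(TRUE, diff(dates) == 1L)
  run_id <- cumsum(!(hot & consec))  # new run at every cool day or gap
  for (id in unique(run_id[hot])) {
    idx <- which(run_id == id & hot)
    if (length(idx) >= min_run) flag[idx] <- 1L
  }
  flag
}

#' Sanfu calendar
#'
#' Container for the traditional Chinese sanfu ("dog days") periods. Each
#' year carries three closed date intervals: toufu and mofu last exactly 10
#' days, zhongfu lasts 10 or 20 days; the three periods must be ordered and
#' non-overlapping. Intervals are validated on construction.
#'
#' @param years A named list; each element (named by calendar year) is a
#'   list with components `toufu`, `zhongfu`, `mofu`, each a length-2 vector
#'   of dates (start, end) coercible with `as.Date`.
#' @return An object of class `sanfu_calendar`.
#' @export
sanfu_calendar <- function(years) {
  if (!is.list(years) || is.null(names(years)) || any(names(years) == ""))
    stop("'years' must be a named list keyed by calendar year", call. = FALSE)
  periods <- c("toufu", "zhongfu", "mofu")
  out <- lapply(names(years), function(y) {
    entry <- years[[y]]
    if (!all(periods %in% names(entry)))
      stop(sprintf("year %s is missing one of %s", y,
                   paste(periods, collapse = ", ")), call. = FALSE)
    iv <- lapply(periods, function(p) {
      d <- as.Date(entry[[p]])
      if (length(d) != 2L || anyNA(d) || d[2] < d[1])
        stop(sprintf("year %s: '%s' must be a valid (start, end) pair", y, p),
             call. = FALSE)
      d
    })
    names(iv) <- periods
    len <- vapply(iv, function(d) as.integer(d[2] - d[1]) + 1L, integer(1))
    if (len[["toufu"]] != 10L || len[["mofu"]] != 10L)
      stop(sprintf("year %s: toufu and mofu must each span exactly 10 days", y),
           call. = FALSE)
    if (!len[["zhongfu"]] %in% c(10L, 20L))
      stop(sprintf("year %s: zhongfu must span 10 or 20 days", y),
           call. = FALSE)
    if (!(iv$toufu[2] < iv$zhongfu[1] && iv$zhongfu[2] < iv$mofu[1]))
      stop(sprintf("year %s: periods must be ordered and non-overlapping", y),
           call. = FALSE)
    iv
  })
  names(out) <- names(years)
  structure(out, class = "sanfu_calendar")
}

#' Encode sanfu period flags
#'
#' For each date, emits three 0/1 indicators saying whether the date falls
#' in the toufu, zhongfu or mofu interval of its year. Because the periods
#' are non-overlapping, at most one flag is 1 on any date.
#'
#' @param dates `Date` vector (or coercible).
#' @param calendar A [sanfu_calendar()].
#' @return A data frame with integer columns `toufu`, `zhongfu`, `mofu`.
#' @export
encode_sanfu <- function(dates, calendar) {
  stopifnot(inherits(calendar, "sanfu_calendar"))
  dates <- as.Date(dates)
  yrs <- format(dates, "%Y")
  missing <- setdiff(unique(yrs), names(calendar))
  if (length(missing))
    stop(sprintf("sanfu calendar is missing year(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  flag_one <- function(period) {
    vapply(seq_along(dates), function(i) {
      iv <- calendar[[yrs[i]]][[period]]
      as.integer(dates[i] >= iv[1] && dates[i] <= iv[2])
    }, integer(1))
  }
  data.frame(toufu = flag_one("toufu"),
             zhongfu = flag_one("zhongfu"),
             mofu = flag_one("mofu"))
}

#' Calendar features
#'
#' Extracts the temporal covariates used to control confounding in the
#' count models: weekday index (Monday = 0 .. Sunday = 6), holiday flag,
#' and the year/month/day components.
#'
#' @param dates `Date` vector (or coercible).
#' @param holidays A vector of holiday dates (possibly empty).
#' @return A data frame with columns `weekday`, `holiday`, `year`, `month`,
#'   `day`.
#' @export
calendar_features <- function(dates, holidays = as.Date(character())) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable dates", call. = FALSE)
  holidays <- as.Date(holidays)
  data.frame(
    weekday = (as.integer(format(dates, "%u")) - 1L),  # Monday = 0
    holiday = as.integer(dates %in% holidays),
    year = as.integer(format(dates, "%Y")),
    month = as.integer(format(dates, "%m")),
    day = as.integer(format(dates, "%d"))
  )
}

#' Add all derived meteorological and calendar features to a daily series
#'
#' Convenience wrapper applying [heat_index()], [dew_point()],
#' [detect_heatwaves()], [encode_sanfu()] and [calendar_features()] to a
#' daily table with columns `date`, `tmean_c`, `tmax_c`, `rh_pct`.
#'
#' @param daily A daily series data frame (see [read_daily_csv()]).
#' @param calendar A [sanfu_calendar()], or `NULL` to skip sanfu flags.
#' @param holidays Holiday dates for the holiday indicator.
#' @return `daily` with columns `heat_index`, `dew_point`, `is_heatwave`,
#'   sanfu flags (if a calendar was given), `weekday`, `holiday`, `year`,
#'   `month`, `day` appended.
#' @export
add_met_features <- function(daily, calendar = NULL,
                             holidays = as.Date(character())) {
  required <- c("date", "tmean_c", "tmax_c", "rh_pct")
  miss <- setdiff(required, names(daily))
  if (length(miss))
    stop(sprintf("daily series is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  daily$heat_index <- heat_index(daily$tmean_c, daily$rh_pct)
  daily$dew_point <- dew_point(daily$tmean_c, daily$rh_pct)
  daily$is_heatwave <- detect_heatwaves(daily$date, daily$tmax_c)
  if (!is.null(calendar)) {
    daily <- cbind(daily, encode_sanfu(daily$date, calendar))
  }
  cbind(daily, calendar_features(daily$date, holidays))
}
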