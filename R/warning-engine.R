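#' Early-warning rules
#'
#' Thresholds and windows of the composite heat-health warning mechanism:
#' a predicted-count trigger; same-day driver thresholds (heat index above
#' 30 C, dew point above 23 C, daily maximum above 35 C) that escalate a
#' warning into a reinforced run of at least five consecutive days; and
#' humidity-band rules issuing delayed warnings 20-25 days after a
#' low-humidity day (below 65 percent) and 22-28 days after a very humid
#' day (above 85 percent). Both delayed windows are inclusive.
#'
#' @param count_threshold Predicted daily cases above which a warning is
#'   issued. No universal value exists; a data-adaptive choice such as the
#'   90th percentile of training-period counts is recommended (see
#'   [suggest_count_threshold()]).
#' @param hi_threshold Heat-index driver threshold, degrees C. Default 30.
#' @param td_threshold Dew-point driver threshold, degrees C. Default 23.
#' @param tmax_threshold Daily-maximum driver threshold, degrees C.
#'   Default 35.
#' @param reinforced_days Length of a reinforced run. Default 5.
#' @param rh_low_cut Low-humidity cut, percent. Default 65.
#' @param rh_high_cut High-humidity cut, percent. Default 85.
#' @param rh_low_window Inclusive day-offset window of the low-humidity
#'   delayed warning. Default `c(20, 25)`.
#' @param rh_high_window Inclusive day-offset window of the high-humidity
#'   delayed warning. Default `c(22, 28)`.
#' @return An object of class `warning_rules`.
#' @export
warning_rules <- function(count_threshold, hi_threshold = 30,
                          td_threshold = 23, tmax_threshold = 35,
                          reinforced_days = 5, rh_low_cut = 65,
                          rh_high_cut = 85, rh_low_window = c(20, 25),
                          rh_high_window = c(22, 28)) {
  vals <- c(count_threshold, hi_threshold, td_threshold, tmax_threshold,
            rh_low_cut, rh_high_cut, rh_low_window, rh_high_window)
  if (any(!is.finite(vals))) stop("thresholds must be finite", call. = FALSE)
  if (rh_low_window[1] > rh_low_window[2] ||
      rh_high_window[1] > rh_high_window[2])
    stop("delayed-warning windows must be ordered", call. = FALSE)
  if (reinforced_days < 1) stop("'reinforced_days' must be >= 1", call. = FALSE)
  structure(list(count_threshold = count_threshold,
                 hi_threshold = hi_threshold, td_threshold = td_threshold,
                 tmax_threshold = tmax_threshold,
                 reinforced_days = as.integer(reinforced_days),
                 rh_low_cut = rh_low_cut, rh_high_cut = rh_high_cut,
                 rh_low_window = as.integer(rh_low_window),
                 rh_high_window = as.integer(rh_high_window)),
            class = "warning_rules")
}

#' Data-adaptive predicted-count warning threshold
#'
#' @param train_counts Daily counts from the training period.
#' @param prob Quantile used as the trigger (default 0.9).
#' @return A single numeric threshold.
#' @export
suggest_count_threshold <- function(train_counts, prob = 0.9) {
  stats::quantile(as.numeric(train_counts), probs = prob, names = FALSE)
}

#' Generate the early-warning schedule
#'
#' Applies the composite rules to date-aligned predictions and driver
#' features:
#' 1. predicted count above `count_threshold` issues a warning that day;
#' 2. if additionally any driver exceeds its threshold (HI, dew point or
#'    Tmax), reinforced warnings cover that day and the following
#'    `reinforced_days - 1` days;
#' 3. relative humidity below `rh_low_cut` issues delayed warnings on the
#'    origin day + 20..25;
#' 4. relative humidity above `rh_high_cut` issues delayed warnings on the
#'    origin day + 22..28.
#' Rules 3 and 4 act independently of the count trigger. Overlapping
#' directives merge to the highest level (reinforced > warning); delayed
#' warnings beyond the end of the input series are emitted as future-dated
#' entries. Every entry records the rules that produced it and, for delayed
#' warnings, the origin date(s).
#'
#' @param predictions Data frame with columns `date` and `predicted`.
#' @param features Data frame with columns `date`, `heat_index`,
#'   `dew_point`, `tmax_c`, `rh_pct`, covering exactly the same dates.
#' @param rules A [warning_rules()] object.
#' @return An object of class `warning_schedule`: a data frame with one row
#'   per warned date — `date`, `level` (`"warning"` or `"reinforced"`),
#'   `rules` (semicolon-joined rule tags) and `origins` (semicolon-joined
#'   origin dates).
#' @export
generate_warnings <- function(predictions, features, rules) {
  stopifnot(inherits(rules, "warning_rules"))
  pd <- as.Date(predictions$date); fd <- as.Date(features$date)
  if (length(pd) != length(fd) || any(pd != fd)) {
    bad <- unique(c(setdiff(format(pd), format(fd)),
                    setdiff(format(fd), format(pd))))
    stop(sprintf("prediction/feature dates misaligned: %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  need <- c("heat_index", "dew_point", "tmax_c", "rh_pct")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop(sprintf("features missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)

  entries <- list()
  add <- function(date, level, rule, origin) {
    entries[[length(entries) + 1L]] <<- data.frame(
      date = date, level = level, rule = rule, origin = origin)
  }
  for (i in seq_along(pd)) {
    d <- pd[i]
    count_hit <- predictions$predicted[i] > rules$count_threshold
    if (count_hit) {
      driver <- c(
        if (features$heat_index[i] > rules$hi_threshold) "heat_index",
        if (features$dew_point[i] > rules$td_threshold) "dew_point",
        if (features$tmax_c[i] > rules$tmax_threshold) "tmax")
      if (length(driver)) {
        span <- d + 0:(rules$reinforced_days - 1L)
        add(span, "reinforced",
            paste0("count+", paste(driver, collapse = "+")), d)
      } else {
        add(d, "warning", "count", d)
      }
    }
    if (features$rh_pct[i] < rules$rh_low_cut) {
      span <- d + rules$rh_low_window[1]:rules$rh_low_window[2]
      add(span, "warning", "rh_low_delayed", d)
    }
    if (features$rh_pct[i] > rules$rh_high_cut) {
      span <- d + rules$rh_high_window[1]:rules$rh_high_window[2]
      add(span, "warning", "rh_high_delayed", d)
    }
  }
  if (!length(entries)) {
    out <- data.frame(date = as.Date(character()), level = character(),
                      rules = character(), origins = character())
    return(structure(out, class = c("warning_schedule", "data.frame")))
  }
  all_e <- do.call(rbind, entries)
  merged <- do.call(rbind, lapply(split(all_e, all_e$date), function(g) {
    lvl <- if (any(g$level == "reinforced")) "reinforced" else "warning"
    data.frame(date = g$date[1], level = lvl,
               rules = paste(unique(g$rule), collapse = ";"),
               origins = paste(unique(format(g$origin)), collapse = ";"))
  }))
  merged <- merged[order(merged$date), ]
  rownames(merged) <- NULL
  structure(merged, class = c("warning_schedule", "data.frame"))
}

#' @export
print.warning_schedule <- function(x, ...) {
  cat(sprintf("warning_schedule: %d warned date(s) (%d reinforced)\n",
              nrow(x), sum(x$level == "reinforced")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}
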