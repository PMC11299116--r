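#' Regression evaluation metrics
#'
#' Mean squared error, root mean squared error and the coefficient of
#' determination:
#' \deqn{MSE = \frac{1}{n}\sum (y_i - \hat y_i)^2, \quad RMSE = \sqrt{MSE},
#'   \quad R^2 = 1 - \frac{\sum (y_i - \hat y_i)^2}{\sum (y_i - \bar y)^2}.}
#' For a constant observed series `r2` is undefined and returned as `NA`
#' with a warning rather than a division by zero.
#'
#' @param y Observed values (length >= 2).
#' @param yhat Predicted values, same length.
#' @return Named list with `mse`, `rmse`, `r2`.
#' @export
evaluate <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(yhat)))
    stop("non-finite values", call. = FALSE)
  mse <- mean((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    warning("constant observed series: r2 is undefined")
    NA_real_
  } else 1 - sum((y - yhat)^2) / ss_tot
  list(mse = mse, rmse = sqrt(mse), r2 = r2)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), the convention used
#' for reporting percentage shares; base R's `round` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Group totals and percentage shares
#'
#' Sums counts within groups and reports each group's percentage of the
#' overall total, rounded half-up to two decimals. With a zero overall
#' total the shares are undefined and returned as `NA` with a warning.
#'
#' @param counts Non-negative numeric counts.
#' @param groups Grouping vector (factor or character), same length.
#' @return Data frame with columns `group`, `total`, `share_pct`, ordered
#'   by first appearance of each group.
#' @export
descriptive_shares <- function(counts, groups) {
  counts <- as.numeric(counts)
  if (length(counts) != length(groups)) stop("length mismatch", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  groups <- factor(groups, levels = unique(as.character(groups)))
  totals <- tapply(counts, groups, sum)
  overall <- sum(totals)
  share <- if (overall == 0) {
    warning("zero overall total: shares are undefined")
    rep(NA_real_, length(totals))
  } else round_half_up(100 * totals / overall, 2)
  data.frame(group = names(totals), total = as.numeric(totals),
             share_pct = as.numeric(share), row.names = NULL)
}

#' Monthly and sanfu-period occurrence shares
#'
#' Descriptive summaries of a daily count series: per-month totals/shares,
#' and per sanfu-period totals/shares (toufu, zhongfu, mofu, non-sanfu) if
#' the sanfu flags are present.
#'
#' @param daily Daily series with `count` and `month` columns; sanfu flags
#'   `toufu`, `zhongfu`, `mofu` optional.
#' @return List with elements `monthly` and (when flags exist) `sanfu`,
#'   each a [descriptive_shares()] table.
#' @export
occurrence_shares <- function(daily) {
  if (!all(c("count", "month") %in% names(daily)))
    stop("'daily' needs 'count' and 'month' columns", call. = FALSE)
  out <- list(monthly = descriptive_shares(daily$count,
                                           month.name[daily$month]))
  if (all(c("toufu", "zhongfu", "mofu") %in% names(daily))) {
    period <- ifelse(daily$toufu == 1, "toufu",
                     ifelse(daily$zhongfu == 1, "zhongfu",
                            ifelse(daily$mofu == 1, "mofu", "non-sanfu")))
    out$sanfu <- descriptive_shares(daily$count, period)
  }
  out
}

#' Pairwise Pearson correlation table
#'
#' Convenience helper returning the Pearson correlation matrix of the
#' numeric columns of a daily table (for correlation heat maps).
#'
#' @param daily Data frame.
#' @return Correlation matrix of its numeric columns.
#' @export
correlation_table <- function(daily) {
  num <- daily[vapply(daily, is.numeric, logical(1))]
  stats::cor(as.matrix(num), method = "pearson")
}
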