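# shared fixtures built in code

consecutive_dates <- function(n, from = "2019-07-01") {
  seq(as.Date(from), by = "day", length.out = n)
}

# brute-force cross-basis oracle: the defining triple loop, no vectorisation
oracle_cross_basis <- function(x, espec, lspec) {
  espec <- heatwarn:::freeze_exposure_spec(espec, x)
  L <- lspec$max_lag
  W <- exposure_basis(espec, x)
  C <- lag_basis(lspec, 0:L)
  Je <- ncol(W); Jl <- ncol(C)
  n <- length(x)
  M <- matrix(NA_real_, n, Je * Jl)
  for (t in (L + 1):n) {
    for (j in seq_len(Je)) {
      for (k in seq_len(Jl)) {
        acc <- 0
        for (l in 0:L) acc <- acc + W[t - l, j] * C[l + 1, k]
        M[t, (j - 1) * Jl + k] <- acc
      }
    }
  }
  M
}

# brute-force heatwave oracle: enumerate every window of >= min_run days
oracle_heatwaves <- function(dates, tmax, threshold = 35, min_run = 3) {
  n <- length(dates)
  flag <- integer(n)
  for (start in seq_len(n)) {
    for (end in start:n) {
      span <- start:end
      if (length(span) < min_run) next
      consecutive <- all(diff(dates[span]) == 1)
      if (consecutive && all(tmax[span] >= threshold)) flag[span] <- 1L
    }
  }
  flag
}

example_sanfu <- function() {
  # synthetic example calendar (not historical dates)
  sanfu_calendar(list(
    `2019` = list(toufu = c("2019-07-12", "2019-07-21"),
                  zhongfu = c("2019-07-22", "2019-08-10"),
                  mofu = c("2019-08-11", "2019-08-20")),
    `2018` = list(toufu = c("2018-07-17", "2018-07-26"),
                  zhongfu = c("2018-07-27", "2018-08-15"),
                  mofu = c("2018-08-16", "2018-08-25"))
  ))
}

quiet_boruta <- function(...) suppressMessages(boruta_select(...))
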