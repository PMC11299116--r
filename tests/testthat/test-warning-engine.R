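mk_inputs <- function(n = 30, from = "2019-07-01",
                      predicted = 0, hi = 25, td = 15, tmax = 30, rh = 70) {
  dates <- consecutive_dates(n, from)
  list(pred = data.frame(date = dates, predicted = rep_len(predicted, n)),
       feat = data.frame(date = dates,
                         heat_index = rep_len(hi, n),
                         dew_point = rep_len(td, n),
                         tmax_c = rep_len(tmax, n),
                         rh_pct = rep_len(rh, n)))
}

default_rules <- function(count_threshold = 10)
  warning_rules(count_threshold = count_threshold)

test_that("quiet conditions produce an empty schedule", {
  d <- mk_inputs()
  sch <- generate_warnings(d$pred, d$feat, default_rules())
  expect_identical(nrow(sch), 0L)
})

test_that("a hot driver escalates the count trigger to a 5-day reinforced run", {
  d <- mk_inputs()
  d$pred$predicted[5] <- 20        # above threshold on day 5
  d$feat$heat_index[5] <- 32       # HI > 30 C driver
  sch <- generate_warnings(d$pred, d$feat, default_rules())
  span <- d$pred$date[5] + 0:4
  expect_identical(sch$date, span)
  expect_identical(sch$level, rep("reinforced", 5))
  expect_true(all(grepl("heat_index", sch$rules)))
  expect_true(all(sch$origins == format(d$pred$date[5])))
})

test_that("count trigger without a driver stays a plain one-day warning", {
  d <- mk_inputs()
  d$pred$predicted[5] <- 20
  sch <- generate_warnings(d$pred, d$feat, default_rules())
  expect_identical(nrow(sch), 1L)
  expect_identical(sch$level, "warning")
  expect_identical(sch$rules, "count")
})

test_that("humidity bands issue the delayed windows, inclusive on both ends", {
  d <- mk_inputs(n = 40)
  d$feat$rh_pct[3] <- 60           # < 65 %: warnings on d+20..d+25
  sch <- generate_warnings(d$pred, d$feat, default_rules())
  expect_identical(sch$date, d$pred$date[3] + 20:25)
  expect_identical(sch$level, rep("warning", 6))
  expect_identical(unique(sch$rules), "rh_low_delayed")
  expect_identical(unique(sch$origins), format(d$pred$date[3]))

  d2 <- mk_inputs(n = 10)
  d2$feat$rh_pct[2] <- 90          # > 85 %: d+22..d+28, beyond the horizon
  sch2 <- generate_warnings(d2$pred, d2$feat, default_rules())
  expect_identical(sch2$date, d2$pred$date[2] + 22:28)  # future-dated
  expect_identical(unique(sch2$rules), "rh_high_delayed")
})

test_that("overlapping directives merge to the highest level with provenance", {
  d <- mk_inputs(n = 40)
  d$feat$rh_pct[1] <- 60                   # delayed warnings on days 21..26
  d$pred$predicted[22] <- 20               # reinforced run 22..26
  d$feat$tmax_c[22] <- 36
  sch <- generate_warnings(d$pred, d$feat, default_rules())
  day22 <- sch[sch$date == d$pred$date[22], ]
  expect_identical(day22$level, "reinforced")
  expect_true(grepl("tmax", day22$rules) && grepl("rh_low_delayed", day22$rules))
  expect_true(grepl(format(d$pred$date[1]), day22$origins))
})

test_that("tightening thresholds never adds warnings; output is deterministic", {
  s <- generate_daily_series(synthetic_config(years = 2019, seed = 17))
  s <- add_met_features(s)
  pred <- data.frame(date = s$date, predicted = s$count)
  feat <- s[c("date", "heat_index", "dew_point", "tmax_c", "rh_pct")]
  base <- warning_rules(count_threshold = 3)
  sch <- generate_warnings(pred, feat, base)
  expect_identical(sch, generate_warnings(pred, feat, base))
  tighter <- list(
    warning_rules(count_threshold = 6),
    warning_rules(count_threshold = 3, hi_threshold = 33),
    warning_rules(count_threshold = 3, tmax_threshold = 38),
    warning_rules(count_threshold = 3, rh_low_cut = 55),
    warning_rules(count_threshold = 3, rh_high_cut = 95))
  for (rules in tighter) {
    sch_t <- generate_warnings(pred, feat, rules)
    expect_true(all(sch_t$date %in% sch$date))
    # no date escalates when rules are tightened
    common <- intersect(format(sch_t$date), format(sch$date))
    lv <- function(x) c(warning = 1, reinforced = 2)[x]
    expect_true(all(
      lv(sch_t$level[match(common, format(sch_t$date))]) <=
        lv(sch$level[match(common, format(sch$date))])))
  }
  # every warning is traceable to at least one rule and origin
  expect_true(all(nchar(sch$rules) > 0) && all(nchar(sch$origins) > 0))
})

test_that("misaligned inputs are rejected with the mismatching dates", {
  d <- mk_inputs(n = 5)
  feat_bad <- d$feat[-3, ]
  expect_error(generate_warnings(d$pred, feat_bad, default_rules()),
               "misaligned")
})
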