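test_that("noise-free limit reproduces the deterministic sinusoid", {
  cfg <- synthetic_config(years = 2019, temp_noise_sd = 0, temp_ar_coef = 0,
                          rh_noise_sd = 0, seed = 1)
  w <- generate_weather(cfg)
  expect_equal(w$tmean_c, seasonal_tmean(w$date, cfg), tolerance = 1e-12)
  expect_true(all(w$tmax_c >= w$tmean_c))
  expect_true(all(w$rh_pct >= 5 & w$rh_pct <= 100))
})

test_that("generation is deterministic and does not disturb the global RNG", {
  cfg <- synthetic_config(years = 2014:2015, seed = 99)
  w1 <- generate_weather(cfg)
  set.seed(123); before <- runif(1)
  set.seed(123)
  w2 <- generate_weather(cfg)
  after <- runif(1)
  expect_identical(w1, w2)
  expect_identical(before, after)  # generator restores the RNG state
  s1 <- generate_counts(w1, true_lag_surface(), 2, seed = 7)
  s2 <- generate_counts(w2, true_lag_surface(), 2, seed = 7)
  expect_identical(s1, s2)
})

test_that("temperature-humidity coupling matches the analytic correlation", {
  # with AR disabled the model is linear-Gaussian:
  # corr = c*sd(T) / sqrt(c^2 var(T) + sd_rh^2),
  # var(T) = var(seasonal curve over sampled dates) + noise variance
  cfg <- synthetic_config(years = 1950:2015, temp_ar_coef = 0,
                          temp_noise_sd = 2, rh_base = 70,
                          rh_temp_coupling = -1.5, rh_noise_sd = 6,
                          seed = 4)
  w <- generate_weather(cfg)
  expect_gt(nrow(w), 10000 - 153)
  vs <- mean((seasonal_tmean(w$date, cfg) - mean(seasonal_tmean(w$date, cfg)))^2)
  var_t <- vs + cfg$temp_noise_sd^2
  rho <- cfg$rh_temp_coupling * sqrt(var_t) /
    sqrt(cfg$rh_temp_coupling^2 * var_t + cfg$rh_noise_sd^2)
  expect_lt(mean(w$rh_pct == 100 | w$rh_pct == 5), 0.001)  # clipping negligible
  expect_equal(cor(w$tmean_c, w$rh_pct), rho, tolerance = 0.05)
  expect_lt(cor(w$tmean_c, w$rh_pct), 0)
})

test_that("null surfaces reproduce the baseline rate", {
  cfg <- synthetic_config(years = 2014:2016, seed = 5)
  w <- generate_weather(cfg)
  # slope 0: mean count within 3 SE of baseline
  s0 <- generate_counts(w, true_lag_surface(slope = 0), 2, seed = 11)
  keep <- s0$burn_in == 0
  se <- sqrt(2 / sum(keep))
  expect_lt(abs(mean(s0$count[keep]) - 2), 3 * se)
  # threshold never exceeded: identical to the slope-0 draw
  s_hi <- generate_counts(w, true_lag_surface(threshold = 1000), 2, seed = 11)
  expect_identical(s_hi$count, s0$count)
  expect_true(all(s0$count >= 0 & s0$count == round(s0$count)))
})

test_that("sustained exposure above threshold yields the closed-form rate ratio", {
  # hand-built weather: long alternating blocks at exposure 30 (excess 0)
  # and 35, so after lag burn-in the Poisson rate is baseline vs
  # baseline * exp(slope * 5)
  n_block <- 40; n_pairs <- 24
  tmax <- rep(rep(c(30, 35), each = n_block), n_pairs)
  n <- length(tmax)
  w <- data.frame(date = consecutive_dates(n, "1980-01-01"),
                  tmean_c = tmax - 5, tmax_c = tmax, rh_pct = 70)
  surf <- true_lag_surface("tmax", threshold = 30, slope = 0.05,
                           lag_weights = 0.5^(0:5))
  s <- generate_counts(w, surf, baseline = 2, seed = 21)
  settle <- rep(rep(c(1, 2), each = n_block), n_pairs)
  in_steady <- rep(c(rep(FALSE, 10), rep(TRUE, n_block - 10)), 2 * n_pairs)
  lo <- s$count[in_steady & settle == 1]
  hi <- s$count[in_steady & settle == 2]
  ratio <- mean(hi) / mean(lo)
  truth <- exp(0.05 * 5)
  se_log <- sqrt(1 / sum(hi) + 1 / sum(lo))
  expect_lt(abs(log(ratio) - log(truth)), 3 * se_log)
})

test_that("mean counts increase with the slope", {
  cfg <- synthetic_config(years = 2014:2015, seed = 3)
  w <- generate_weather(cfg)
  means <- vapply(c(0, 0.03, 0.06, 0.09), function(sl) {
    s <- generate_counts(w, true_lag_surface(slope = sl), 2, seed = 13)
    mean(s$count[s$burn_in == 0])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("generator rejects bad configurations", {
  expect_error(synthetic_config(years = integer(0), seed = 1), "non-empty")
  expect_error(synthetic_config(years = 2019, seed = 1, temp_ar_coef = 1),
               "temp_ar_coef")
  expect_error(synthetic_config(years = 2019), "seed")
  w <- generate_weather(synthetic_config(years = 2019, seed = 1))
  expect_error(generate_counts(w[1:4, ], true_lag_surface(), 2, seed = 1),
               "max_lag")
})
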