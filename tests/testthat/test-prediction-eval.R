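test_that("evaluation metrics match hand arithmetic and definitions", {
  ev <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(ev), c(mse = 0, rmse = 0, r2 = 1))
  ev2 <- evaluate(c(1, 2, 3), c(1, 2, 4))
  expect_equal(ev2$mse, 1 / 3, tolerance = 1e-12)
  expect_equal(ev2$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(ev2$r2, 0.5, tolerance = 1e-12)
  set.seed(1)
  y <- rnorm(50); yh <- rnorm(50)
  ev3 <- evaluate(y, yh)
  expect_equal(ev3$rmse^2, ev3$mse, tolerance = 1e-9)
  expect_lte(ev3$r2, 1)
  expect_warning(evaluate(rep(2, 10), rnorm(10)), "constant")
})

test_that("percentage shares use round-half-up and sum to 100", {
  expect_equal(round_half_up(0.005, 2), 0.01)
  expect_equal(round_half_up(2.675, 2), 2.68)
  sh <- descriptive_shares(c(24, 178, 1753, 966, 43),
                           c("May", "Jun", "Jul", "Aug", "Sep"))
  expect_equal(sh$share_pct[sh$group == "Jul"], 59.14)
  expect_lt(abs(sum(sh$share_pct) - 100), 0.02)
  one <- descriptive_shares(c(0, 5, 0), c("a", "b", "c"))
  expect_equal(one$share_pct[one$group == "b"], 100.00)
  expect_warning(descriptive_shares(c(0, 0), c("a", "b")), "zero")
})

test_that("model suite trains, predicts and reports coherent metrics", {
  surf <- true_lag_surface("tmax", threshold = 28, slope = 0.08,
                           lag_weights = c(0.6, 0.4))
  s <- generate_daily_series(synthetic_config(years = 2014:2019,
                                              lag_effect = surf, seed = 21))
  s <- add_met_features(s)
  parts <- split_by_year(s, split_spec(2014:2018, 2019))
  feats <- c("tmax_c", "tmean_c", "rh_pct", "heat_index", "dew_point", "day")
  suite <- fit_predict_suite(parts$train, parts$validation, feats,
                             models = c("tree", "random_forest", "gbdt",
                                        "linear_svr"),
                             rf = rf_spec(seed = 2), seed = 2)
  expect_setequal(suite$report$model,
                  c("tree", "random_forest", "gbdt", "linear_svr"))
  expect_true(all(suite$report$rmse^2 - suite$report$mse < 1e-9))
  # with a strong exposure signal the forest beats the mean predictor
  expect_gt(suite$report$r2[suite$report$model == "random_forest"], 0)
  expect_identical(nrow(suite$predictions), nrow(parts$validation))
})

test_that("a one-tree forest equals its constituent tree", {
  set.seed(3)
  x <- data.frame(a = rnorm(120), b = rnorm(120))
  y <- 2 * x$a + rnorm(120, 0, 0.3)
  f1 <- fit_random_forest(x, y, rf_spec(n_trees = 1, seed = 5))
  expect_length(f1$trees, 1)
  expect_equal(predict(f1, x),
               unname(predict(f1$trees[[1]], newdata = x)),
               tolerance = 1e-12)
  # B-tree forest prediction is the mean of the trees
  f13 <- fit_random_forest(x, y, rf_spec(seed = 5))
  per_tree <- sapply(f13$trees, predict, newdata = x)
  expect_equal(predict(f13, x), unname(rowMeans(per_tree)), tolerance = 1e-12)
})

test_that("rolling ARIMA tracks a deterministic linear trend", {
  y <- 1:140 * 0.5 + 3
  preds <- heatwarn:::rolling_arima(y[1:100], y[101:140], c(0, 2, 0))
  err <- abs(preds - y[101:140])
  expect_lt(max(tail(err, 30)), 0.01)
})

test_that("grid search is exhaustive, deterministic and tie-stable", {
  grid <- expand.grid(a = 1:3, b = c(10, 20))
  res <- grid_search(grid, function(row) row$a + row$b / 100)
  expect_equal(res$best$a, 1)
  expect_equal(res$best$b, 10)
  one <- grid_search(data.frame(a = 7), function(row) 0)
  expect_equal(one$best$a, 7)
  # ties broken by first-in-grid order
  tie <- grid_search(data.frame(a = c(5, 6)), function(row) 1)
  expect_equal(tie$best$a, 5)
  expect_error(grid_search(data.frame(), function(row) 1), "empty")
})

test_that("sensitivity analysis isolates the perturbed feature", {
  surf <- true_lag_surface("tmax", threshold = 28, slope = 0.1,
                           lag_weights = 1)
  s <- generate_daily_series(synthetic_config(years = 2014:2019,
                                              lag_effect = surf, seed = 31))
  s$pure_noise <- rnorm(nrow(s))
  parts <- split_by_year(s, split_spec(2014:2018, 2019))
  feats <- c("tmax_c", "pure_noise")
  rf <- fit_random_forest(parts$train[feats], parts$train$count,
                          rf_spec(seed = 4))
  # zero perturbation changes nothing
  z <- sensitivity_analysis(rf, parts$validation, "count",
                            c(tmax_c = 0, pure_noise = 0))
  expect_equal(z$d_rmse, c(0, 0), tolerance = 1e-12)
  # shifting the dominant driver moves the score more than shifting noise
  d <- sensitivity_analysis(rf, parts$validation, "count",
                            c(tmax_c = 5, pure_noise = 5))
  expect_gt(abs(d$d_rmse[d$feature == "tmax_c"]),
            abs(d$d_rmse[d$feature == "pure_noise"]))
  expect_error(sensitivity_analysis(rf, parts$validation, "count",
                                    c(nope = 1)), "unknown")
})
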