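#' Train/validation split by calendar year
#'
#' @param train_years Years forming the training set (default 2014-2018).
#' @param validation_years Years forming the validation set (default 2019).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_years = 2014:2018, validation_years = 2019) {
  train_years <- as.integer(train_years)
  validation_years <- as.integer(validation_years)
  if (!length(train_years) || !length(validation_years))
    stop("both year sets must be non-empty", call. = FALSE)
  if (length(intersect(train_years, validation_years)))
    stop("train and validation years must be disjoint", call. = FALSE)
  structure(list(train_years = train_years,
                 validation_years = validation_years),
            class = "split_spec")
}

#' Split a daily series into train and validation tables
#'
#' @param daily Daily series with a `date` column; burn-in rows
#'   (`burn_in == 1`) are dropped if present.
#' @param spec A [split_spec()].
#' @return List with data frames `train` and `validation`.
#' @export
split_by_year <- function(daily, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  yr <- as.integer(format(as.Date(daily$date), "%Y"))
  if ("burn_in" %in% names(daily)) daily <- daily[daily$burn_in == 0, ]
  yr <- as.integer(format(as.Date(daily$date), "%Y"))
  if (!any(yr %in% spec$validation_years))
    stop("validation year(s) absent from the series", call. = FALSE)
  if (!any(yr %in% spec$train_years))
    stop("training year(s) absent from the series", call. = FALSE)
  list(train = daily[yr %in% spec$train_years, , drop = FALSE],
       validation = daily[yr %in% spec$validation_years, , drop = FALSE])
}

#' Random-forest specification
#'
#' Hyper-parameters of the bagged-tree random-forest regressor: tree depth,
#' leaf and split minima, and the number of bootstrap trees. Each tree is a
#' CART regression tree grown on a bootstrap resample with all features
#' available at every split (the scikit-learn regression default), so the
#' forest is exactly bootstrap aggregation of depth-limited trees; the
#' forest prediction is the mean over the trees.
#'
#' @param max_depth Maximum tree depth. Default 4.
#' @param min_samples_leaf Minimum observations per leaf. Default 1.
#' @param min_samples_split Minimum observations to attempt a split.
#'   Default 4.
#' @param n_trees Number of bootstrap trees. Default 13.
#' @param seed Integer seed.
#' @return An object of class `rf_spec`.
#' @export
rf_spec <- function(max_depth = 4, min_samples_leaf = 1,
                    min_samples_split = 4, n_trees = 13, seed = 1L) {
  vals <- c(max_depth, min_samples_leaf, min_samples_split, n_trees)
  if (any(vals < 1)) stop("all hyper-parameters must be positive", call. = FALSE)
  structure(list(max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 min_samples_split = as.integer(min_samples_split),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "rf_spec")
}

rpart_control_for <- function(spec) {
  rpart::rpart.control(maxdepth = spec$max_depth,
                       minbucket = spec$min_samples_leaf,
                       minsplit = spec$min_samples_split,
                       cp = 0, xval = 0)
}

#' Fit a bagged random forest of regression trees
#'
#' @param x Data frame of predictors.
#' @param y Numeric response.
#' @param spec An [rf_spec()].
#' @return An object of class `hw_rf` holding the trees.
#' @export
fit_random_forest <- function(x, y, spec = rf_spec()) {
  stopifnot(inherits(spec, "rf_spec"))
  x <- as.data.frame(x)
  old <- globalenv()$.Random.seed
  set.seed(spec$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  n <- nrow(x)
  dat <- cbind(x, .y = as.numeric(y))
  trees <- lapply(seq_len(spec$n_trees), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    rpart::rpart(.y ~ ., data = dat[idx, , drop = FALSE],
                 method = "anova", control = rpart_control_for(spec))
  })
  structure(list(trees = trees, spec = spec, features = colnames(x)),
            class = "hw_rf")
}

#' @export
predict.hw_rf <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  preds <- vapply(object$trees, function(tr) {
    unname(stats::predict(tr, newdata = newdata))
  }, numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

# one-step-ahead rolling ARIMA: refit on the history up to t-1 for each
# validation day t
rolling_arima <- function(train_y, valid_y, order) {
  history <- as.numeric(train_y)
  preds <- numeric(length(valid_y))
  for (t in seq_along(valid_y)) {
    # optimiser chatter from repeated short-history refits is expected;
    # only hard failures propagate
    fit <- suppressWarnings(tryCatch(
      stats::arima(history, order = order, method = "CSS-ML"),
      error = function(e) stats::arima(history, order = order,
                                       method = "CSS")))
    preds[t] <- as.numeric(suppressWarnings(
      stats::predict(fit, n.ahead = 1)$pred))
    history <- c(history, valid_y[t])
  }
  preds
}

#' Exhaustive grid search
#'
#' Evaluates a scoring function at every point of a finite grid and returns
#' the best point; ties are broken by first-in-grid order. Lower scores are
#' better.
#'
#' @param grid A data frame, one row per candidate configuration.
#' @param score_fun Function taking one grid row (as a list) and returning
#'   a single numeric score.
#' @return List with `best` (the winning row as a list), `best_score`, and
#'   the full `scores` vector.
#' @export
grid_search <- function(grid, score_fun) {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) stop("empty grid", call. = FALSE)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    as.numeric(score_fun(as.list(grid[i, , drop = FALSE])))
  }, numeric(1))
  best <- which.min(scores)  # which.min returns the first minimum
  list(best = as.list(grid[best, , drop = FALSE]), best_score = scores[best],
       scores = scores)
}

select_arima_order <- function(train_y,
                               grid = expand.grid(p = 0:2, d = 0:1, q = 0:2)) {
  res <- grid_search(grid, function(row) {
    fit <- suppressWarnings(tryCatch(
      stats::arima(train_y, order = c(row$p, row$d, row$q),
                   method = "CSS-ML"),
      error = function(e) NULL))
    if (is.null(fit)) Inf else stats::AIC(fit)
  })
  c(res$best$p, res$best$d, res$best$q)
}

#' Fit the model suite and evaluate on a held-out season
#'
#' Trains the count-prediction model families on the training years and
#' scores them on the validation years with [evaluate()]. Tabular models
#' (decision tree, random forest, gradient-boosted trees, linear SVR) are
#' trained once on the features and predicted statically; ARIMA ignores the
#' features and produces rolling one-step-ahead forecasts, refitting on the
#' count history extended day by day through the validation period (order
#' chosen by AIC grid search over p,q <= 2, d <= 1 unless supplied).
#'
#' @param train,validation Data frames from [split_by_year()].
#' @param features Character vector of feature column names.
#' @param target Name of the count column. Default `"count"`.
#' @param models Subset of `c("tree", "random_forest", "gbdt",
#'   "linear_svr", "arima")`.
#' @param rf A [rf_spec()] for the random forest.
#' @param arima_order Optional fixed `c(p, d, q)`.
#' @param seed Integer seed for the stochastic learners.
#' @return List with `report` (data frame of mse/rmse/r2 per model),
#'   `predictions` (date, observed, one column per model) and the fitted
#'   `models`.
#' @export
fit_predict_suite <- function(train, validation, features, target = "count",
                              models = c("tree", "random_forest", "gbdt",
                                         "linear_svr", "arima"),
                              rf = rf_spec(), arima_order = NULL, seed = 1L) {
  if ("lstm" %in% models)
    stop("LSTM is an optional plugin and is not bundled", call. = FALSE)
  models <- match.arg(models, several.ok = TRUE)
  miss <- setdiff(c(features, target), names(train))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  xtr <- train[features]; ytr <- train[[target]]
  xva <- validation[features]; yva <- validation[[target]]
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  fits <- list(); preds <- list()
  if ("tree" %in% models) {
    dat <- cbind(xtr, .y = ytr)
    fits$tree <- rpart::rpart(.y ~ ., data = dat, method = "anova",
                              control = rpart::rpart.control(
                                maxdepth = rf$max_depth, cp = 0, xval = 0))
    preds$tree <- unname(stats::predict(fits$tree, newdata = xva))
  }
  if ("random_forest" %in% models) {
    fits$random_forest <- fit_random_forest(xtr, ytr, rf)
    preds$random_forest <- predict(fits$random_forest, xva)
  }
  if ("gbdt" %in% models) {
    dtr <- xgboost::xgb.DMatrix(as.matrix(xtr), label = ytr)
    fits$gbdt <- xgboost::xgb.train(
      params = list(max_depth = rf$max_depth, eta = 0.1,
                    objective = "reg:squarederror", nthread = 1,
                    seed = seed),
      data = dtr, nrounds = 100, verbose = 0)
    preds$gbdt <- as.numeric(stats::predict(fits$gbdt,
                                            as.matrix(xva)))
  }
  if ("linear_svr" %in% models) {
    fits$linear_svr <- e1071::svm(x = as.matrix(xtr), y = ytr,
                                  type = "eps-regression",
                                  kernel = "linear", scale = TRUE)
    preds$linear_svr <- as.numeric(stats::predict(fits$linear_svr,
                                                  as.matrix(xva)))
  }
  if ("arima" %in% models) {
    ord <- if (is.null(arima_order)) select_arima_order(ytr) else arima_order
    fits$arima <- list(order = ord)
    preds$arima <- rolling_arima(ytr, yva, ord)
  }
  report <- do.call(rbind, lapply(names(preds), function(m) {
    ev <- evaluate(yva, preds[[m]])
    data.frame(model = m, mse = ev$mse, rmse = ev$rmse, r2 = ev$r2,
               n_validation = length(yva))
  }))
  prediction_table <- data.frame(date = validation$date, observed = yva,
                                 as.data.frame(preds))
  list(report = report, predictions = prediction_table, models = fits)
}

#' Feature-perturbation sensitivity analysis
#'
#' Shifts one feature at a time by a configured delta across the validation
#' table, re-scores the fitted model, and reports the change in each metric
#' relative to the unperturbed baseline.
#'
#' @param model A fitted model with a `predict` method over data frames
#'   (e.g. an [fit_random_forest()] forest).
#' @param validation Validation data frame containing the feature columns
#'   and the target.
#' @param target Name of the observed count column.
#' @param deltas Named numeric vector: feature name -> additive shift.
#' @return Data frame with one row per perturbed feature: the shifted
#'   metrics and their deltas (`d_mse`, `d_rmse`, `d_r2`).
#' @export
sensitivity_analysis <- function(model, validation, target = "count",
                                 deltas) {
  if (is.null(names(deltas)) || any(names(deltas) == ""))
    stop("'deltas' must be a named vector", call. = FALSE)
  unknown <- setdiff(names(deltas), names(validation))
  if (length(unknown))
    stop(sprintf("unknown feature(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  y <- validation[[target]]
  base <- evaluate(y, predict(model, validation))
  out <- do.call(rbind, lapply(names(deltas), function(f) {
    pert <- validation
    pert[[f]] <- pert[[f]] + deltas[[f]]
    ev <- evaluate(y, predict(model, pert))
    data.frame(feature = f, delta = deltas[[f]],
               mse = ev$mse, rmse = ev$rmse, r2 = ev$r2,
               d_mse = ev$mse - base$mse, d_rmse = ev$rmse - base$rmse,
               d_r2 = ev$r2 - base$r2)
  }))
  rownames(out) <- NULL
  out
}
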