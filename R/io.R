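#' Read a daily series CSV
#'
#' Loads and validates the pipeline's flat daily table. Required columns:
#' `date` (ISO-8601), `tmean_c`, `tmax_c`, `rh_pct`; optional `count`
#' (non-negative integer), `burn_in`, and any derived feature columns.
#' Violations are reported with the offending row numbers.
#'
#' @param path Path to a CSV file.
#' @param require_count Demand a `count` column. Default `FALSE`.
#' @return A validated data frame with `date` parsed as `Date`.
#' @export
read_daily_csv <- function(path, require_count = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("date", "tmean_c", "tmax_c", "rh_pct")
  if (require_count) required <- c(required, "count")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  d <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(d))
    stop(sprintf("unparseable date(s) at row(s): %s",
                 paste(utils::head(which(is.na(d)), 5), collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(d))
    stop(sprintf("duplicate date(s) at row(s): %s",
                 paste(utils::head(which(duplicated(d)), 5), collapse = ", ")),
         call. = FALSE)
  raw$date <- d
  bad_rh <- which(raw$rh_pct < 0 | raw$rh_pct > 100 | !is.finite(raw$rh_pct))
  if (length(bad_rh))
    stop(sprintf("relative humidity out of [0, 100] at row(s): %s",
                 paste(utils::head(bad_rh, 5), collapse = ", ")),
         call. = FALSE)
  if ("count" %in% names(raw)) {
    bad_n <- which(!is.finite(raw$count) | raw$count < 0 |
                     raw$count != round(raw$count))
    if (length(bad_n))
      stop(sprintf("negative or non-integer count at row(s): %s",
                   paste(utils::head(bad_n, 5), collapse = ", ")),
           call. = FALSE)
    raw$count <- as.integer(raw$count)
  }
  raw[order(raw$date), , drop = FALSE]
}

#' Write a daily series CSV
#'
#' Inverse of [read_daily_csv()]: dates are serialised as ISO-8601 so the
#' table round-trips bit-identically.
#'
#' @param daily Daily series data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(daily, path) {
  daily$date <- format(as.Date(daily$date), "%Y-%m-%d")
  utils::write.csv(daily, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# stable polynomial hash over the serialised configuration, for stamping
# artifacts (not cryptographic)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration describing a full run: the seed, the
#' synthetic-generator settings or an input CSV path, the split years, the
#' basis and selection settings, the random-forest hyper-parameters, the
#' warning rules, the sanfu calendar and the holiday list. Unknown top-level
#' keys are rejected with a message so typos never silently fall back to
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated named list of class `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "input_csv", "synthetic", "split", "exposure",
             "boruta", "random_forest", "warning", "sanfu_calendar",
             "holidays", "dlnm")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (is.null(cfg$seed)) stop("configuration must set 'seed'", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

build_sanfu_from_config <- function(cfg) {
  if (is.null(cfg$sanfu_calendar)) return(NULL)
  sanfu_calendar(cfg$sanfu_calendar)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (or ingest) -> derived features
#' -> Boruta selection -> DLNM relative-risk surfaces -> model suite ->
#' warning schedule — and writes each stage's artifact as CSV into
#' `out_dir`, together with a run log stamped with the configuration hash
#' and seed. Any stage failure aborts with the stage name and cause.
#'
#' @param config A [load_pipeline_config()] list (or an equivalent list).
#' @param out_dir Output directory, created if absent.
#' @param verbose Print stage progress.
#' @return Invisibly, a named list of artifact paths plus the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  log_lines <- c(sprintf("heatwarn pipeline run, seed %d, config hash %s",
                         seed, config_hash(unclass(config))))
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- simulate / ingest ----------------------------------------------
  daily <- stage("simulate", {
    if (!is.null(config$input_csv)) {
      read_daily_csv(config$input_csv, require_count = TRUE)
    } else {
      syn <- config$synthetic
      lag_w <- if (!is.null(syn$lag_weights)) as.numeric(syn$lag_weights)
               else 0.5^(0:5)
      surf <- true_lag_surface(
        exposure_name = if (is.null(syn$exposure)) "tmax" else syn$exposure,
        threshold = if (is.null(syn$threshold)) 30 else syn$threshold,
        slope = if (is.null(syn$slope)) 0.05 else syn$slope,
        lag_weights = lag_w)
      sc <- synthetic_config(
        years = if (is.null(syn$years)) 2014:2019 else syn$years,
        count_baseline = if (is.null(syn$baseline)) 2 else syn$baseline,
        lag_effect = surf, seed = seed)
      generate_daily_series(sc)
    }
  })

  # --- features --------------------------------------------------------
  calendar <- stage("features", build_sanfu_from_config(config))
  if (isTRUE(config$boruta$use_sanfu) && is.null(calendar))
    stop("pipeline stage 'features' failed: sanfu features requested but no sanfu_calendar configured",
         call. = FALSE)
  holidays <- if (is.null(config$holidays)) as.Date(character())
              else as.Date(unlist(config$holidays))
  daily <- stage("features", add_met_features(daily, calendar, holidays))
  features_path <- file.path(out_dir, "features.csv")
  write_daily_csv(daily, features_path)
  say("stage features: wrote %s", features_path)

  # --- selection -------------------------------------------------------
  base_feats <- intersect(c("day", "tmax_c", "tmean_c", "rh_pct", "zhongfu",
                            "toufu", "mofu", "is_heatwave", "heat_index",
                            "dew_point", "weekday"), names(daily))
  fitting <- if ("burn_in" %in% names(daily)) daily[daily$burn_in == 0, ]
             else daily
  sel <- stage("select", boruta_select(
    fitting[base_feats], fitting$count,
    boruta_config(seed = seed,
                  max_iter = if (is.null(config$boruta$max_iter)) 100
                             else config$boruta$max_iter)))
  selected <- sel$confirmed
  if (!length(selected)) {
    selected <- base_feats
    say("stage select: nothing confirmed, falling back to all features")
  }
  say("stage select: confirmed %s", paste(sel$confirmed, collapse = ", "))

  # --- dlnm ------------------------------------------------------------
  expo_name <- if (is.null(config$dlnm$exposure)) "tmax_c"
               else config$dlnm$exposure
  max_lag <- if (is.null(config$dlnm$max_lag)) 10 else config$dlnm$max_lag
  degree <- if (is.null(config$dlnm$lag_degree)) 4 else config$dlnm$lag_degree
  rr_tab <- stage("dlnm", {
    cb <- build_cross_basis(daily[[expo_name]],
                            exposure_basis_spec("ns", df = 4),
                            lag_basis_spec(max_lag = max_lag,
                                           degree = degree),
                            dates = daily$date)
    fit <- fit_dlnm(cb, daily$count, dates = daily$date,
                    holidays = holidays)
    grid <- seq(min(daily[[expo_name]]), max(daily[[expo_name]]),
                length.out = 30)
    rr_surface_table(predict_rr(fit, grid))
  })
  rr_path <- file.path(out_dir, "rr_surface.csv")
  utils::write.csv(rr_tab, rr_path, row.names = FALSE)
  say("stage dlnm: wrote %s", rr_path)

  # --- predict ---------------------------------------------------------
  sp <- split_spec(
    train_years = if (is.null(config$split$train_years))
      utils::head(sort(unique(as.integer(format(daily$date, "%Y")))), -1)
      else as.integer(config$split$train_years),
    validation_years = if (is.null(config$split$validation_years))
      utils::tail(sort(unique(as.integer(format(daily$date, "%Y")))), 1)
      else as.integer(config$split$validation_years))
  suite <- stage("predict", {
    parts <- split_by_year(daily, sp)
    fit_predict_suite(parts$train, parts$validation, selected,
                      rf = rf_spec(seed = seed), seed = seed)
  })
  eval_path <- file.path(out_dir, "eval_report.csv")
  utils::write.csv(suite$report, eval_path, row.names = FALSE)
  say("stage predict: wrote %s", eval_path)

  # --- warn ------------------------------------------------------------
  schedule <- stage("warn", {
    parts <- split_by_year(daily, sp)
    thr <- if (!is.null(config$warning$count_threshold))
      config$warning$count_threshold
      else suggest_count_threshold(parts$train$count)
    say("stage warn: count threshold %.2f", thr)
    rules <- warning_rules(count_threshold = thr)
    preds <- data.frame(date = parts$validation$date,
                        predicted = suite$predictions$random_forest)
    generate_warnings(preds, parts$validation[c("date", "heat_index",
                                                "dew_point", "tmax_c",
                                                "rh_pct")], rules)
  })
  warn_path <- file.path(out_dir, "warnings.csv")
  utils::write.csv(as.data.frame(schedule), warn_path, row.names = FALSE)
  say("stage warn: wrote %s", warn_path)

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  invisible(list(paths = list(features = features_path, rr = rr_path,
                              eval = eval_path, warnings = warn_path,
                              log = log_path),
                 daily = daily, selection = sel, rr = rr_tab,
                 suite = suite, schedule = schedule))
}
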