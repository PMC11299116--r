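#' Boruta configuration
#'
#' Settings of the shadow-feature all-relevant selection loop. The defaults
#' follow common practice for regression targets: shallow trees (depth 4),
#' an automatically scaled number of trees, the shadow-importance maximum
#' (100th percentile) as the hit bar, alpha 0.05, the two-step multiple-
#' testing scheme, and at most 100 iterations.
#'
#' When `n_estimators = "auto"` the tree count is
#' `round(100 * 2p / (sqrt(2p) * depth))` with `p` the number of real
#' features — the reference heuristic that keeps the expected number of
#' times each of the `2p` (real + shadow) columns is inspected roughly
#' constant as the matrix grows.
#'
#' @param tree_depth Maximum tree depth in the forest. Default 4.
#' @param n_estimators `"auto"` or a positive integer.
#' @param perc Percentile of the shadow importances used as the hit
#'   threshold, in (0, 100]. Default 100 (the shadow maximum).
#' @param alpha Significance level of the binomial tests, in (0, 1).
#' @param two_step Use the two-step correction (FDR pass plus a Bonferroni
#'   pass over iterations) rather than a single Bonferroni over features.
#' @param max_iter Maximum number of iterations (>= 1). Default 100.
#' @param seed Integer seed.
#' @return An object of class `boruta_config`.
#' @export
boruta_config <- function(tree_depth = 4, n_estimators = "auto", perc = 100,
                          alpha = 0.05, two_step = TRUE, max_iter = 100,
                          seed = 1L) {
  if (!(identical(n_estimators, "auto") ||
        (is.numeric(n_estimators) && n_estimators >= 1)))
    stop("'n_estimators' must be \"auto\" or a positive integer",
         call. = FALSE)
  if (perc <= 0 || perc > 100) stop("'perc' must be in (0, 100]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (max_iter < 1) stop("'max_iter' must be >= 1", call. = FALSE)
  structure(list(tree_depth = as.integer(tree_depth),
                 n_estimators = n_estimators, perc = perc, alpha = alpha,
                 two_step = isTRUE(two_step), max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "boruta_config")
}

boruta_tree_count <- function(config, n_feat) {
  if (identical(config$n_estimators, "auto")) {
    p2 <- 2 * n_feat
    max(10L, as.integer(round(100 * p2 / (sqrt(p2) * config$tree_depth))))
  } else {
    as.integer(config$n_estimators)
  }
}

#' Boruta shadow-feature selection
#'
#' All-relevant feature selection for a numeric target. Each iteration
#' permutes every feature into a "shadow" copy (padded to at least five
#' shadow columns by resampling), fits a depth-limited random-forest
#' regressor on the combined real + shadow matrix, and records a "hit" for
#' every real feature whose impurity importance exceeds the `perc`
#' percentile of the shadow importances. After each iteration two-sided
#' binomial bookkeeping at level `alpha` promotes features to confirmed or
#' demotes them to rejected: with `two_step = TRUE`, a Benjamini-Hochberg
#' pass is combined with a Bonferroni correction over the iterations run so
#' far; otherwise a single Bonferroni over the feature count is applied.
#' The loop stops when no tentative features remain or `max_iter` is
#' reached.
#'
#' Constant features cannot carry importance and are rejected up front
#' (with a message); a constant target is an error.
#'
#' @param features Data frame or matrix of numeric predictors (>= 2
#'   columns, no missing values).
#' @param target Numeric response, same length, not constant.
#' @param config A [boruta_config()].
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @return An object of class `boruta_result`: character vectors
#'   `confirmed`, `rejected`, `tentative` (a partition of the feature
#'   names), integer `hit_counts`, and `n_iterations_run`.
#' @export
boruta_select <- function(features, target, config = boruta_config(),
                          importance = c("impurity", "permutation")) {
  stopifnot(inherits(config, "boruta_config"))
  importance <- match.arg(importance)
  features <- as.data.frame(features)
  if (ncol(features) < 2) stop("need at least 2 features", call. = FALSE)
  if (anyNA(features) || anyNA(target))
    stop("missing values are not supported", call. = FALSE)
  target <- as.numeric(target)
  if (length(target) != nrow(features))
    stop("'target' length mismatch", call. = FALSE)
  if (stats::var(target) == 0)
    stop("constant target: importances are undefined", call. = FALSE)

  feat_names <- colnames(features)
  const <- vapply(features, function(col) stats::var(as.numeric(col)) == 0,
                  logical(1))
  pre_rejected <- feat_names[const]
  if (length(pre_rejected)) {
    message("auto-rejecting constant feature(s): ",
            paste(pre_rejected, collapse = ", "))
    features <- features[!const]
    feat_names <- colnames(features)
  }
  p <- ncol(features)
  if (p < 1) stop("no non-constant features left", call. = FALSE)

  old <- globalenv()$.Random.seed
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  # decision: 0 tentative, 1 confirmed, -1 rejected
  decision <- stats::setNames(integer(p), feat_names)
  hits <- stats::setNames(integer(p), feat_names)
  n <- nrow(features)
  iter <- 0L
  while (iter < config$max_iter && any(decision == 0L)) {
    iter <- iter + 1L
    active <- decision >= 0L  # confirmed features stay in the matrix
    real <- features[, active, drop = FALSE]
    shadow_src <- real
    # pad shadows to >= 5 columns so the shadow percentile is stable
    while (ncol(shadow_src) < 5L)
      shadow_src <- cbind(shadow_src,
                          real[, sample.int(ncol(real), 1L), drop = FALSE])
    shadow <- as.data.frame(lapply(shadow_src, sample))
    colnames(shadow) <- paste0("shadow_", seq_len(ncol(shadow)))
    dat <- cbind(real, shadow)
    dat$.y <- target
    ntree <- boruta_tree_count(config, ncol(real))
    rf <- ranger::ranger(
      dependent.variable.name = ".y", data = dat,
      num.trees = ntree, max.depth = config$tree_depth,
      importance = if (importance == "impurity") "impurity" else "permutation",
      seed = sample.int(.Machine$integer.max, 1L),
      num.threads = 1L, verbose = FALSE)
    imp <- rf$variable.importance
    shadow_imp <- imp[colnames(shadow)]
    bar <- stats::quantile(shadow_imp, probs = config$perc / 100,
                           names = FALSE, type = 7)
    real_imp <- imp[colnames(real)]
    hit_now <- names(real_imp)[real_imp > bar]
    hits[hit_now] <- hits[hit_now] + 1L
    decision <- boruta_tests(decision, hits, iter, config)
  }
  structure(list(confirmed = names(decision)[decision == 1L],
                 rejected = c(pre_rejected, names(decision)[decision == -1L]),
                 tentative = names(decision)[decision == 0L],
                 hit_counts = hits, n_iterations_run = iter,
                 config = config),
            class = "boruta_result")
}

# Binomial bookkeeping applied after each iteration; only tentative
# features can change state.
boruta_tests <- function(decision, hits, iter, config) {
  tent <- which(decision == 0L)
  if (!length(tent)) return(decision)
  h <- hits[tent]
  # P(X >= h) and P(X <= h) under Binomial(iter, 1/2)
  p_accept <- stats::pbinom(h - 1, iter, 0.5, lower.tail = FALSE)
  p_reject <- stats::pbinom(h, iter, 0.5)
  if (config$two_step) {
    acc_fdr <- stats::p.adjust(p_accept, method = "BH") <= config$alpha
    rej_fdr <- stats::p.adjust(p_reject, method = "BH") <= config$alpha
    acc <- acc_fdr & (p_accept <= config$alpha / iter)
    rej <- rej_fdr & (p_reject <= config$alpha / iter)
  } else {
    acc <- p_accept <= config$alpha / length(decision)
    rej <- p_reject <= config$alpha / length(decision)
  }
  decision[tent[acc]] <- 1L
  decision[tent[rej & !acc]] <- -1L
  decision
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("boruta_result after %d iteration(s):\n", x$n_iterations_run))
  cat("  confirmed:", if (length(x$confirmed)) paste(x$confirmed, collapse = ", ") else "(none)", "\n")
  cat("  tentative:", if (length(x$tentative)) paste(x$tentative, collapse = ", ") else "(none)", "\n")
  cat("  rejected: ", if (length(x$rejected)) paste(x$rejected, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
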