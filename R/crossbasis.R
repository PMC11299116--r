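#' Build a DLNM cross-basis
#'
#' Constructs the bidimensional exposure-lag design matrix of a distributed
#' lag non-linear model. Row t, column (j, k) holds
#' \deqn{cb_{t,(j,k)} = \sum_{l=0}^{L} w_j(x_{t-l})\, C_k(l)}
#' where \eqn{w_j} is the j-th exposure basis function and \eqn{C_k} the
#' k-th lag basis function; columns are ordered with the lag index varying
#' fastest. The first `max_lag` rows of each contiguous date block lack a
#' complete lag history and are masked out (`valid_mask = FALSE`), never
#' imputed; rows whose lag window contains a missing exposure are likewise
#' masked with a warning.
#'
#' @param x Exposure series (numeric), in time order.
#' @param espec An [exposure_basis_spec()]; data-dependent knots are frozen
#'   from `x` here.
#' @param lspec A [lag_basis_spec()].
#' @param dates Optional `Date` vector aligned with `x`; gaps in the dates
#'   split the series into blocks whose lag histories are independent.
#' @return An object of class `cross_basis`: list with the `n x (df_e *
#'   df_l)` `matrix`, the frozen `espec`, `lspec`, the original `exposure`
#'   series and the logical `valid_mask`.
#' @export
build_cross_basis <- function(x, espec = exposure_basis_spec(),
                              lspec = lag_basis_spec(), dates = NULL) {
  stopifnot(inherits(espec, "exposure_basis_spec"),
            inherits(lspec, "lag_basis_spec"))
  x <- as.numeric(x)
  n <- length(x)
  L <- lspec$max_lag
  if (n <= L)
    stop(sprintf("series length (%d) must exceed max_lag (%d)", n, L),
         call. = FALSE)
  if (is.null(dates)) {
    block <- rep(1L, n)
  } else {
    dates <- as.Date(dates)
    if (length(dates) != n) stop("'dates' length mismatch", call. = FALSE)
    block <- cumsum(c(1L, as.integer(diff(dates) != 1L)))
  }
  espec <- freeze_exposure_spec(espec, x[is.finite(x)])
  W <- exposure_basis(espec, ifelse(is.finite(x), x, 0))
  C <- lag_basis(lspec, 0:L)
  Je <- ncol(W); Jl <- ncol(C)
  M <- matrix(0, n, Je * Jl)
  valid <- rep(TRUE, n)
  new_block <- c(TRUE, diff(block) != 0L)
  pos_in_block <- stats::ave(seq_len(n), block, FUN = seq_along)
  valid[pos_in_block <= L] <- FALSE
  for (l in 0:L) {
    shift <- c(rep(NA, l), utils::head(seq_len(n), n - l))
    ok <- !is.na(shift)
    Wl <- matrix(0, n, Je)
    Wl[ok, ] <- W[shift[ok], , drop = FALSE]
    # same-block requirement is already enforced by the position mask
    contrib <- Wl[, rep(seq_len(Je), each = Jl), drop = FALSE] *
      matrix(rep(C[l + 1L, ], Je), n, Je * Jl, byrow = TRUE)
    M <- M + contrib
  }
  bad <- valid & vapply(seq_len(n), function(t) {
    any(!is.finite(x[max(1, t - L):t]))
  }, logical(1))
  if (any(bad)) {
    warning(sprintf("%d row(s) masked: missing exposure inside lag window",
                    sum(bad)))
    valid[bad] <- FALSE
  }
  colnames(M) <- paste0("cb", seq_len(Je * Jl))
  structure(list(matrix = M, espec = espec, lspec = lspec, exposure = x,
                 valid_mask = valid, block = block),
            class = "cross_basis")
}

#' @export
print.cross_basis <- function(x, ...) {
  cat(sprintf("cross_basis: %d days x %d columns (%s exposure df %d, lag 0..%d poly deg %d), %d valid rows\n",
              nrow(x$matrix), ncol(x$matrix), x$espec$kind, x$espec$df,
              x$lspec$max_lag, x$lspec$degree, sum(x$valid_mask)))
  invisible(x)
}

#' Fit a distributed lag non-linear count model
#'
#' Fits the quasi-Poisson (or Poisson) time-series regression
#' \deqn{\log E[Y_t] = \alpha + cb(x_t, \mathrm{lag}) +
#'   ns(\mathrm{date}, df) + \mathrm{dow} + \mathrm{holiday}}
#' by iteratively reweighted least squares (via [stats::glm()]). Seasonal
#' and long-term trends are absorbed by a natural spline on the within-study
#' date index; weekday enters as six indicator contrasts (Monday reference)
#' and holiday as one indicator. Under the quasi-Poisson family the
#' coefficient covariance is scaled by the Pearson dispersion.
#'
#' Only rows with a complete lag history (the cross-basis `valid_mask`) are
#' used. Non-convergence and rank deficiency are reported, never silent.
#'
#' @param cb A [build_cross_basis()] object.
#' @param counts Non-negative integer counts aligned with the cross-basis.
#' @param dates Optional `Date` vector for the seasonal spline and weekday
#'   term; if `NULL`, a linear index replaces the date and no weekday or
#'   holiday terms enter.
#' @param seasonal_df Degrees of freedom of the seasonal natural spline
#'   (default 10).
#' @param holidays Holiday dates (ignored when `dates` is `NULL`).
#' @param family `"quasipoisson"` (default) or `"poisson"`.
#' @param centering Reference exposure for relative-risk computation;
#'   default is the sample median of the exposure over valid rows.
#' @return An object of class `dlnm_fit`: coefficients, covariance,
#'   dispersion, deviance, the centering value and fitted metadata.
#' @export
fit_dlnm <- function(cb, counts, dates = NULL, seasonal_df = 10,
                     holidays = as.Date(character()),
                     family = c("quasipoisson", "poisson"),
                     centering = NULL) {
  stopifnot(inherits(cb, "cross_basis"))
  family <- match.arg(family)
  counts <- as.numeric(counts)
  if (length(counts) != nrow(cb$matrix))
    stop("'counts' must align with the cross-basis rows", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  keep <- cb$valid_mask
  design <- cb$matrix
  df_terms <- data.frame(row.names = seq_len(nrow(design)))
  if (!is.null(dates)) {
    dates <- as.Date(dates)
    idx <- as.numeric(dates - min(dates))
    seas <- natural_spline_basis(idx, df = seasonal_df)
    colnames(seas) <- paste0("seas", seq_len(ncol(seas)))
    wk <- factor((as.integer(format(dates, "%u")) - 1L), levels = 0:6)
    wk_mat <- stats::model.matrix(~wk)[, -1, drop = FALSE]
    hol <- as.integer(dates %in% as.Date(holidays))
    extra <- cbind(seas, wk_mat)
    if (any(hol > 0)) extra <- cbind(extra, holiday = hol)
    design <- cbind(design, extra)
  } else {
    idx <- seq_len(nrow(design))
    if (seasonal_df > 0) {
      seas <- natural_spline_basis(idx, df = seasonal_df)
      colnames(seas) <- paste0("seas", seq_len(ncol(seas)))
      design <- cbind(design, seas)
    }
  }
  y <- counts[keep]
  Xk <- design[keep, , drop = FALSE]
  n_par <- ncol(Xk) + 1L
  if (length(y) < n_par + 10L)
    stop("too few valid rows for the number of parameters", call. = FALSE)
  qrX <- qr(cbind(1, Xk))
  if (qrX$rank < n_par) {
    dropped <- colnames(cbind(`(Intercept)` = 1, Xk))[qrX$pivot[-seq_len(qrX$rank)]]
    stop(sprintf("singular design; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  dat <- data.frame(y = y, Xk, check.names = FALSE)
  fam <- if (family == "poisson") stats::poisson() else stats::quasipoisson()
  fit <- stats::glm(y ~ ., data = dat, family = fam)
  if (!fit$converged)
    warning("IRLS did not converge; estimates may be unreliable")
  sm <- summary(fit)
  dispersion <- if (family == "poisson") 1 else sm$dispersion
  cb_cols <- paste0("`", colnames(cb$matrix), "`")
  nm <- names(stats::coef(fit))
  cb_idx <- match(c(colnames(cb$matrix), cb_cols), nm)
  cb_idx <- cb_idx[!is.na(cb_idx)]
  if (length(cb_idx) != ncol(cb$matrix))
    stop("internal error: cross-basis columns lost in fit", call. = FALSE)
  if (is.null(centering))
    centering <- stats::median(cb$exposure[keep], na.rm = TRUE)
  structure(list(coefficients = stats::coef(fit),
                 covariance = stats::vcov(fit),
                 dispersion = dispersion,
                 deviance = fit$deviance,
                 converged = fit$converged,
                 family = family,
                 cb_index = cb_idx,
                 design_labels = nm,
                 centering = centering,
                 espec = cb$espec, lspec = cb$lspec,
                 n_used = length(y)),
            class = "dlnm_fit")
}

#' @export
print.dlnm_fit <- function(x, ...) {
  cat(sprintf("dlnm_fit (%s): %d coefficients, dispersion %.3f, centred at %.2f, %s\n",
              x$family, length(x$coefficients), x$dispersion, x$centering,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Relative-risk surface from a fitted DLNM
#'
#' Computes lag-specific and cumulative relative risks over a grid of
#' exposure values, centred at the reference exposure: for exposure x and
#' lag l, \eqn{RR(x,l) = \exp(\Delta\eta)} with
#' \eqn{\Delta\eta = [(w(x) - w(x_{ref})) \otimes C(l)]^\top \beta_{cb}},
#' and the cumulative RR sums \eqn{\Delta\eta} over the lag grid before
#' exponentiating. 95 percent Wald intervals use the fitted covariance
#' (dispersion-scaled under quasi-Poisson).
#'
#' @param fit A [fit_dlnm()] object.
#' @param exposure_grid Exposure values at which to evaluate the surface.
#' @param lag_grid Integer lags (default the full `0..max_lag`).
#' @param reference Reference exposure; defaults to the fit's centering
#'   value. A reference outside the observed exposure range triggers a
#'   warning.
#' @param conf_level Confidence level of the Wald intervals.
#' @return An object of class `rr_surface`: matrices `rr`, `rr_low`,
#'   `rr_high` (exposure x lag), vectors `cum_rr`, `cum_low`, `cum_high`,
#'   and the grids and reference used.
#' @export
predict_rr <- function(fit, exposure_grid, lag_grid = NULL, reference = NULL,
                       conf_level = 0.95) {
  stopifnot(inherits(fit, "dlnm_fit"))
  if (!fit$converged)
    stop("cannot compute relative risks from a non-converged fit",
         call. = FALSE)
  if (is.null(lag_grid)) lag_grid <- 0:fit$lspec$max_lag
  if (is.null(reference)) reference <- fit$centering
  rng <- fit$espec$boundary_knots
  if (!is.null(rng) && (reference < rng[1] || reference > rng[2]))
    warning("reference exposure lies outside the observed exposure range")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- fit$coefficients[fit$cb_index]
  Sigma <- fit$covariance[fit$cb_index, fit$cb_index, drop = FALSE]
  W <- exposure_basis(fit$espec, exposure_grid)
  Wref <- exposure_basis(fit$espec, reference)
  C <- lag_basis(fit$lspec, lag_grid)
  Je <- ncol(W); Jl0 <- ncol(C)
  nx <- length(exposure_grid); nl <- length(lag_grid)
  dW <- W - matrix(Wref, nx, Je, byrow = TRUE)
  rr <- lo <- hi <- matrix(NA_real_, nx, nl,
                           dimnames = list(NULL, paste0("lag", lag_grid)))
  cum_eta <- numeric(nx); cum_var <- numeric(nx)
  for (i in seq_len(nx)) {
    # v for (x_i, lag l): kron(dW[i,], C[l,]) with lag index fastest
    V <- matrix(0, nl, Je * Jl0)
    for (j in seq_len(Je)) {
      V[, (j - 1) * Jl0 + seq_len(Jl0)] <- dW[i, j] * C
    }
    eta <- drop(V %*% beta)
    se <- sqrt(pmax(0, rowSums((V %*% Sigma) * V)))
    rr[i, ] <- exp(eta)
    lo[i, ] <- exp(eta - z * se)
    hi[i, ] <- exp(eta + z * se)
    vc <- colSums(V)
    cum_eta[i] <- sum(vc * beta)
    cum_var[i] <- drop(t(vc) %*% Sigma %*% vc)
  }
  structure(list(exposure_grid = exposure_grid, lag_grid = lag_grid,
                 rr = rr, rr_low = lo, rr_high = hi,
                 cum_rr = exp(cum_eta),
                 cum_low = exp(cum_eta - z * sqrt(pmax(0, cum_var))),
                 cum_high = exp(cum_eta + z * sqrt(pmax(0, cum_var))),
                 reference = reference, conf_level = conf_level),
            class = "rr_surface")
}

#' @export
print.rr_surface <- function(x, ...) {
  cat(sprintf("rr_surface: %d exposure values x %d lags, reference %.2f\n",
              length(x$exposure_grid), length(x$lag_grid), x$reference))
  invisible(x)
}

#' Export an RR surface as a long-format grid table
#'
#' One row per (exposure, lag) cell plus the cumulative curve, suitable for
#' contour plotting with any tool.
#'
#' @param surface An [predict_rr()] result.
#' @return Data frame with columns `exposure`, `lag`, `rr`, `rr_low`,
#'   `rr_high`; cumulative rows carry `lag = NA`.
#' @export
rr_surface_table <- function(surface) {
  stopifnot(inherits(surface, "rr_surface"))
  grid <- expand.grid(lag = surface$lag_grid,
                      exposure = surface$exposure_grid)
  long <- data.frame(exposure = grid$exposure, lag = grid$lag,
                     rr = as.vector(t(surface$rr)),
                     rr_low = as.vector(t(surface$rr_low)),
                     rr_high = as.vector(t(surface$rr_high)))
  cum <- data.frame(exposure = surface$exposure_grid, lag = NA_integer_,
                    rr = surface$cum_rr, rr_low = surface$cum_low,
                    rr_high = surface$cum_high)
  rbind(long, cum)
}
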