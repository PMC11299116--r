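#' Natural cubic spline basis
#'
#' Builds a natural cubic regression spline basis (linear beyond the
#' boundary knots) using the truncated-power construction: with knots
#' \eqn{\xi_1 < \dots < \xi_K} the columns are x and
#' \eqn{d_k(x) - d_{K-1}(x)} for \eqn{k = 1..K-2}, where
#' \eqn{d_k(x) = [(x-\xi_k)_+^3 - (x-\xi_K)_+^3] / (\xi_K - \xi_k)}.
#' The span equals that of `splines::ns` with the same knots (the two bases
#' differ by an invertible linear map); this direct form keeps the basis
#' functions explicit for cross-basis assembly and prediction.
#'
#' Interior knots default to the `(1:(df-1))/df` quantiles of `x`, boundary
#' knots to the range, matching common practice.
#'
#' @param x Numeric vector of evaluation points.
#' @param df Number of basis columns (>= 1). `df = 1` is the linear basis.
#' @param knots Optional interior knots (strictly increasing).
#' @param boundary_knots Optional length-2 boundary knots.
#' @return Matrix with `length(x)` rows and `df` columns; attributes
#'   `knots` and `boundary_knots` record the frozen knot set.
#' @export
natural_spline_basis <- function(x, df = 4, knots = NULL,
                                 boundary_knots = NULL) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("'x' must be finite", call. = FALSE)
  if (df < 1) stop("'df' must be >= 1", call. = FALSE)
  n_distinct <- length(unique(x))
  if (is.null(boundary_knots)) boundary_knots <- range(x)
  if (is.null(knots)) {
    if (df > 1) {
      if (n_distinct <= df)
        stop(sprintf(
          "df = %d requires more than %d distinct values (got %d)",
          df, df, n_distinct), call. = FALSE)
      knots <- unname(stats::quantile(x, probs = (1:(df - 1)) / df))
    } else {
      knots <- numeric(0)
    }
  }
  if (length(knots) && is.unsorted(knots, strictly = TRUE))
    stop("'knots' must be strictly increasing", call. = FALSE)
  if (length(knots) != df - 1)
    stop("need exactly df - 1 interior knots", call. = FALSE)
  all_knots <- c(boundary_knots[1], knots, boundary_knots[2])
  if (is.unsorted(all_knots, strictly = TRUE))
    stop("interior knots must lie strictly inside the boundary knots",
         call. = FALSE)
  K <- length(all_knots)
  basis <- matrix(0, length(x), df)
  basis[, 1] <- x
  if (df > 1) {
    dk <- function(k) {
      (pmax(0, x - all_knots[k])^3 - pmax(0, x - all_knots[K])^3) /
        (all_knots[K] - all_knots[k])
    }
    dlast <- dk(K - 1)
    for (k in seq_len(K - 2)) basis[, k + 1] <- dk(k) - dlast
  }
  colnames(basis) <- paste0("ns", seq_len(df))
  structure(basis, knots = knots, boundary_knots = boundary_knots)
}

#' Lag basis specification
#'
#' Polynomial basis over the lag dimension 0..`max_lag`. Lags are scaled to
#' \[0, 1\] before taking powers and the resulting columns are
#' orthonormalised (QR over the full lag grid) for conditioning; the
#' transform is frozen in the spec so evaluation at any subset of lags is
#' consistent. Predictions are invariant to this reparameterisation.
#'
#' @param max_lag Maximum lag in days (>= 1). Default 30.
#' @param degree Polynomial degree (>= 1). Default 4.
#' @param intercept Include the constant lag term (default `TRUE`), giving
#'   `degree + 1` columns.
#' @return An object of class `lag_basis_spec`.
#' @export
lag_basis_spec <- function(max_lag = 30, degree = 4, intercept = TRUE) {
  max_lag <- as.integer(max_lag)
  if (max_lag < 1) stop("'max_lag' must be >= 1", call. = FALSE)
  if (degree < 1) stop("'degree' must be >= 1", call. = FALSE)
  if (degree > max_lag)
    stop("'degree' cannot exceed 'max_lag': only max_lag + 1 lag points exist",
         call. = FALSE)
  powers <- if (intercept) 0:degree else 1:degree
  raw <- outer((0:max_lag) / max_lag, powers, `^`)
  qr_ <- qr(raw)
  # map raw scaled powers -> orthonormal columns over the full lag grid
  transform <- backsolve(qr.R(qr_), diag(length(powers)))
  structure(list(max_lag = max_lag, degree = as.integer(degree),
                 intercept = intercept, powers = powers,
                 transform = transform),
            class = "lag_basis_spec")
}

#' Evaluate a lag basis at given lags
#'
#' @param spec A [lag_basis_spec()].
#' @param lags Integer lags in `0..max_lag`.
#' @return Matrix of `length(lags)` rows, one column per basis function.
#' @export
lag_basis <- function(spec, lags = 0:spec$max_lag) {
  stopifnot(inherits(spec, "lag_basis_spec"))
  if (any(lags < 0 | lags > spec$max_lag))
    stop("lags outside 0..max_lag", call. = FALSE)
  raw <- outer(lags / spec$max_lag, spec$powers, `^`)
  out <- raw %*% spec$transform
  colnames(out) <- paste0("l", seq_len(ncol(out)))
  out
}

#' Exposure basis specification
#'
#' The transform of the exposure value inside the cross-basis. Three kinds
#' are supported:
#' * `"ns"` — natural cubic spline with `df` columns (default; knots are
#'   placed at quantiles of the data when the basis is first built and then
#'   frozen for prediction);
#' * `"poly"` — raw polynomial of degree `df` on the exposure scaled by its
#'   observed range;
#' * `"lin_thr"` — single hinge column `max(0, x - threshold)`, for
#'   threshold-linear dose-response surfaces (supply the threshold via
#'   `knots`).
#'
#' @param kind One of `"ns"`, `"poly"`, `"lin_thr"`.
#' @param df Basis dimension (for `"lin_thr"` forced to 1).
#' @param knots Interior knots (`"ns"`), or the hinge threshold
#'   (`"lin_thr"`).
#' @param boundary_knots Boundary knots for `"ns"`.
#' @return An object of class `exposure_basis_spec`.
#' @export
exposure_basis_spec <- function(kind = c("ns", "poly", "lin_thr"), df = 4,
                                knots = NULL, boundary_knots = NULL) {
  kind <- match.arg(kind)
  if (kind == "lin_thr") {
    if (is.null(knots) || length(knots) != 1L)
      stop("'lin_thr' needs a single threshold in 'knots'", call. = FALSE)
    df <- 1L
  }
  if (df < 1) stop("'df' must be >= 1", call. = FALSE)
  if (!is.null(knots) && length(knots) > 1 &&
      is.unsorted(knots, strictly = TRUE))
    stop("'knots' must be strictly increasing", call. = FALSE)
  structure(list(kind = kind, df = as.integer(df), knots = knots,
                 boundary_knots = boundary_knots, scale = NULL),
            class = "exposure_basis_spec")
}

# Freeze data-dependent components (knots, scaling) of an exposure spec so
# that prediction uses exactly the basis the model was built with.
freeze_exposure_spec <- function(spec, x) {
  if (spec$kind == "ns") {
    if (is.null(spec$boundary_knots)) spec$boundary_knots <- range(x)
    if (is.null(spec$knots) && spec$df > 1)
      spec$knots <- unname(stats::quantile(x, probs = (1:(spec$df - 1)) /
                                             spec$df))
    if (is.null(spec$knots)) spec$knots <- numeric(0)
  } else if (spec$kind == "poly" && is.null(spec$scale)) {
    spec$scale <- range(x)
  }
  spec
}

#' Evaluate an exposure basis
#'
#' @param spec A frozen [exposure_basis_spec()] (see
#'   [build_cross_basis()], which freezes knots from the data).
#' @param x Exposure values.
#' @return Matrix with `length(x)` rows and `df` columns.
#' @export
exposure_basis <- function(spec, x) {
  stopifnot(inherits(spec, "exposure_basis_spec"))
  x <- as.numeric(x)
  out <- switch(spec$kind,
    ns = {
      if (is.null(spec$boundary_knots))
        stop("spec not frozen: build a cross-basis first or supply knots",
             call. = FALSE)
      unclass(natural_spline_basis(x, df = spec$df, knots = spec$knots,
                                   boundary_knots = spec$boundary_knots))
    },
    poly = {
      sc <- if (is.null(spec$scale)) c(0, 1) else spec$scale
      xs <- (x - sc[1]) / max(sc[2] - sc[1], .Machine$double.eps)
      outer(xs, seq_len(spec$df), `^`)
    },
    lin_thr = matrix(pmax(0, x - spec$knots[1]), ncol = 1)
  )
  colnames(out) <- paste0("e", seq_len(ncol(out)))
  out
}
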