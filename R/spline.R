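# Quartic (degree-4) penalized regression spline.
#
# The titration readout is the curvature of the E2-vs-T_Low relation, so the
# fitted curve must have a smooth (non-piecewise-linear) second derivative:
# a cubic spline's second derivative is piecewise linear with maxima only at
# the knots, whereas a quartic spline's is piecewise quadratic and can peak
# anywhere. The basis is a full B-spline basis of order 5 with interior
# knots at the interior data sites; smoothness is imposed by a penalty on
# the integrated squared second derivative, with the penalty weight chosen
# to match the residual sum of squares to a replicate-noise estimate.

# Knot vector giving a basis of dimension exactly length(x): boundary knots
# repeated to full multiplicity and interior knots at running means of four
# consecutive data sites (the de Boor averaging rule), which satisfies the
# Schoenberg-Whitney conditions so the interpolation problem is nonsingular.
.quartic_knots <- function(x) {
  n <- length(x)
  interior <- if (n > 5L) {
    vapply(seq_len(n - 5L), function(j) mean(x[(j + 1L):(j + 4L)]), numeric(1))
  } else numeric(0)
  c(rep(x[1], 5L), interior, rep(x[n], 5L))
}

.quartic_basis <- function(knots, x, deriv = 0L) {
  # splineDesign refuses x outside the knot span; clamp boundary round-off
  x <- pmin(pmax(x, knots[1]), knots[length(knots)])
  splines::splineDesign(knots, x, ord = 5L,
                        derivs = rep(as.integer(deriv), length(x)),
                        outer.ok = FALSE)
}

# Gram matrix of the basis second derivatives: integral of f'' g'' over the
# span. Second derivatives of a quartic spline are piecewise quadratic, so
# 3-point Gauss-Legendre per knot interval is exact.
.curvature_penalty <- function(knots) {
  uk <- unique(knots)
  gx <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5 / 9, 8 / 9, 5 / 9)
  p <- length(knots) - 5L
  P <- matrix(0, p, p)
  for (i in seq_len(length(uk) - 1L)) {
    a <- uk[i]; b <- uk[i + 1L]
    h <- (b - a) / 2
    xs <- a + h * (gx + 1)
    B2 <- .quartic_basis(knots, xs, deriv = 2L) * sqrt(gw * h)
    P <- P + crossprod(B2)
  }
  (P + t(P)) / 2
}

# Penalized (optionally weighted) least squares via a stacked QR
# (numerically stable down to lambda = 0, where it reduces to plain
# interpolation on the square basis): minimizes
#   sum_i w_i (y_i - f(x_i))^2 + lambda ||L a||^2,  L'L = P.
.pen_fit <- function(B, y, L, lambda, w = NULL) {
  if (!is.null(w)) {
    B <- sqrt(w) * B
    y <- sqrt(w) * y
  }
  if (lambda <= 0) return(qr.coef(qr(B, LAPACK = TRUE), y))
  A <- rbind(B, sqrt(lambda) * L)
  rhs <- c(y, numeric(nrow(L)))
  qr.coef(qr(A, LAPACK = TRUE), rhs)
}

#' Fit a quartic smoothing spline to an E2-vs-T_Low curve
#'
#' Fits a degree-4 (order-5) penalized B-spline through the titration
#' points, with a curvature (integrated squared second derivative) penalty
#' whose weight is selected by generalized cross-validation. A
#' replicate-noise scale `sigma` — taken from the supplied precisions when
#' available, otherwise estimated robustly from local second differences of
#' the E2 values — decides between smoothing and interpolation: when
#' `sigma` is ~0 (noiseless data) the spline interpolates exactly.
#'
#' When per-point precisions are supplied (`weights`, typically the inverse
#' squared regression standard errors of the E2 estimates), the fit is
#' weighted: steps whose E2 is poorly identified — short T_Low gives a small
#' volume excursion, so the quadratic elastance term is weakly excited —
#' then pull the curve far less than well-identified steps. Weights are
#' normalised to median 1 so the residual target `m * sigma^2` keeps its
#' meaning for a typical point.
#'
#' @param t_low T_Low grid values, s, strictly increasing (>= 7 points).
#' @param e2 Volume-dependent elastance estimates, cmH2O/L^2, same length.
#' @param weights Optional non-negative per-point precisions — inverse
#'   variances on the absolute E2 scale, e.g. `1 / se^2` from the
#'   mechanics regression; `NULL` (default) for an unweighted fit. When
#'   supplied they also set the replicate-noise scale for smoothing.
#' @return An object of class `e2_spline` supporting
#'   `predict(object, t, deriv = 0:2)`.
#' @examples
#' tl <- seq(0.2, 1, by = 0.05)
#' sp <- fit_e2_spline(tl, 10 + 5 / (1 + exp(-(tl - 0.6) / 0.05)))
#' predict(sp, 0.6, deriv = 2)
#' @export
fit_e2_spline <- function(t_low, e2, weights = NULL) {
  ok <- is.finite(t_low) & is.finite(e2)
  if (!is.null(weights)) {
    if (length(weights) != length(e2) || any(weights[ok] < 0)) {
      aprv_error("weights must be non-negative and match e2 in length",
                 "aprv_invalid_input")
    }
    weights <- weights[ok]
  }
  t_low <- t_low[ok]; e2 <- e2[ok]
  m <- length(t_low)
  if (m < 7L) {
    aprv_error("need at least 7 non-missing titration points for the quartic spline",
               "aprv_too_few_points")
  }
  if (any(diff(t_low) <= 0)) {
    aprv_error("t_low values must be strictly increasing", "aprv_invalid_input")
  }
  knots <- .quartic_knots(t_low)
  B <- .quartic_basis(knots, t_low)
  P <- .curvature_penalty(knots)
  eg <- eigen(P, symmetric = TRUE)
  L <- sqrt(pmax(eg$values, 0)) * t(eg$vectors)

  # Relative weights are clipped to [0.05, 10]: a point 4-5 standard-error
  # ratios noisier than typical still anchors the local shape of the curve
  # (an unanchored span lets the quartic develop spurious boundary
  # curvature), it just cannot drag the fit.
  w <- if (!is.null(weights)) {
    wn <- weights / stats::median(weights[weights > 0])
    pmin(pmax(wn, 0.05), 10)
  }

  basis_scale <- mean(colSums(B^2))
  lambda_min <- 1e-12 * basis_scale / max(mean(diag(P)), 1e-300)

  # Replicate-noise scale of a typical (unit-weight) point. When absolute
  # precisions are supplied (weights = inverse variances of the E2
  # estimates), the scale comes straight from them: the median standard
  # error. Otherwise it is estimated from second differences — for iid
  # N(0, s^2) noise the second difference is N(0, 6 s^2) — using a low
  # (20th-percentile) quantile of |d2| with its half-normal consistency
  # constant, so that the localized curvature of a smooth noiseless curve,
  # which inflates the upper tail of |d2|, stays out of the estimate and
  # such curves are interpolated rather than flattened.
  if (!is.null(weights)) {
    sigma <- 1 / sqrt(stats::median(weights[weights > 0]))
    interp_tol <- 1e-8 * max(abs(e2), 1e-12)
  } else {
    d2 <- diff(e2, differences = 2L)
    sigma <- stats::quantile(abs(d2), 0.2, names = FALSE) /
      (stats::qnorm(0.6) * sqrt(6))
    # noise below ~1% of the curve's range is immaterial for curvature
    # localisation, and the quantile estimator never reads exactly zero on
    # a smooth noiseless curve: treat such data as noiseless
    interp_tol <- max(1e-8 * max(abs(e2), 1e-12), 1e-2 * diff(range(e2)))
  }

  # Smoothing level by (weighted) generalized cross-validation,
  #   GCV(lambda) = (RSS_w / m) / (1 - df(lambda) / m)^2,
  # minimized over a log-spaced lambda grid with one local refinement pass.
  # Residual-matching rules (RSS = m sigma^2 and its df-corrected variants)
  # proved fragile here: they are degenerate at the interpolation limit of
  # the square basis and collapse to interpolation whenever the chi-square
  # fluctuation of a draw's RSS exceeds its expectation at every lambda.
  # The search is restricted to fits spending at most about half the data's
  # degrees of freedom (df <= m/2 + 2): a titration curve has a single
  # transition, so higher flexibility is noise-chasing — and GCV's known
  # small-sample failure mode is exactly an occasional spurious minimum at
  # the interpolation end. Noiseless curves (sigma ~ 0) are interpolated
  # exactly instead.
  # Smoothing level by (weighted) generalized cross-validation,
  #   GCV(lambda) = (RSS_w / m) / (1 - df(lambda) / m)^2,
  # minimized over a log-spaced lambda grid with one local refinement pass.
  # Residual-matching rules (RSS = m sigma^2 and df-corrected variants)
  # proved fragile here: they are degenerate at the interpolation limit of
  # the square basis and collapse to interpolation whenever the chi-square
  # fluctuation of a draw's RSS exceeds its expectation at every lambda.
  # The search is restricted to low-flexibility fits (df <= 6): the
  # titration curve has a single transition, so higher flexibility is
  # noise-chasing — and GCV's known small-sample failure mode is exactly an
  # occasional spurious minimum at the interpolation end. Noiseless curves
  # (sigma ~ 0) are interpolated exactly instead.
  wv <- if (is.null(w)) rep(1, m) else w
  df_max <- min(m - 1, 4)
  gcv_at <- function(lambda) {
    a <- .pen_fit(B, e2, L, lambda, w)
    rss <- sum(wv * (e2 - drop(B %*% a))^2)
    A <- crossprod(sqrt(wv) * B) + lambda * P
    df <- sum(B * t(solve(A, t(B * wv))))
    if (df > df_max) return(Inf)
    (rss / m) / (1 - df / m)^2
  }

  if (sigma <= interp_tol) {
    lambda <- 0  # noiseless: interpolate
  } else {
    lgrid <- log(lambda_min) + seq(0, 60, length.out = 121L)
    gvals <- vapply(exp(lgrid), gcv_at, numeric(1))
    j <- which.min(gvals)
    lo <- lgrid[max(1L, j - 1L)]; hi <- lgrid[min(length(lgrid), j + 1L)]
    fine <- seq(lo, hi, length.out = 41L)
    gfine <- vapply(exp(fine), gcv_at, numeric(1))
    lambda <- exp(fine[which.min(gfine)])
  }
  coef <- drop(.pen_fit(B, e2, L, lambda, w))
  structure(list(knots = knots, coef = coef, degree = 4L,
                 lambda = lambda, sigma_hat = sigma,
                 t_range = range(t_low),
                 t_low = t_low, e2 = e2, weights = w,
                 rss = sum((e2 - drop(B %*% coef))^2)),
            class = "e2_spline")
}

#' @rdname fit_e2_spline
#' @param object An `e2_spline`.
#' @param t Evaluation points, s (clamped to the fitted range).
#' @param deriv Derivative order: 0 (value), 1, or 2.
#' @param ... Unused.
#' @export
predict.e2_spline <- function(object, t, deriv = 0L, ...) {
  drop(.quartic_basis(object$knots, t, deriv = deriv) %*% object$coef)
}

#' @export
print.e2_spline <- function(x, ...) {
  cat(sprintf(
    "<e2_spline> degree 4, %d points on [%.3g, %.3g] s, lambda %.3g, sigma_hat %.3g\n",
    length(x$t_low), x$t_range[1], x$t_range[2], x$lambda, x$sigma_hat))
  invisible(x)
}

#' Recommend T_Low from the spline's curvature maximum
#'
#' Evaluates the second derivative of the fitted E2 spline on a dense grid
#' (step 0.001 s) across the titration range and recommends the T_Low at its
#' maximum — the point of maximum change in slope of the E2-vs-T_Low curve,
#' i.e. where derecruitment starts to accelerate. Ties break toward the
#' smallest T_Low (shorter release, less derecruitment risk). When the curve
#' carries no appreciable curvature (flat or linear E2), no recommendation
#' is made and `no_optimum_flag` is set.
#'
#' @param spline An `e2_spline` from [fit_e2_spline()].
#' @param protocol A [titration_protocol()]; the search covers
#'   `[t_low_start, t_low_stop]`.
#' @param grid_step Dense evaluation step, s.
#' @return A list with `recommended_t_low` (s; `NA` when flagged),
#'   `max_curvature` (cmH2O/L^2/s^2), `no_optimum_flag`, and
#'   `curvature_profile` — a data frame of `t` and `d2e2` over the dense grid.
#' @export
optimal_tlow <- function(spline, protocol, grid_step = 0.001) {
  t0 <- protocol$t_low_start; t1 <- protocol$t_low_stop
  ngrid <- floor((t1 - t0) / grid_step + 1e-9)
  tg <- t0 + (0:ngrid) * grid_step
  if (tg[length(tg)] < t1 - 1e-12) tg <- c(tg, t1)
  d2 <- predict(spline, tg, deriv = 2L)
  span <- t1 - t0
  e2_range <- diff(range(spline$e2))
  tol <- 1e-6 * max(e2_range, 1e-3 * max(abs(spline$e2), 1)) / span^2
  i <- which.max(d2)  # first index wins ties -> smallest T_Low
  if (!is.finite(d2[i]) || d2[i] < tol) {
    return(list(recommended_t_low = NA_real_, max_curvature = max(d2),
                no_optimum_flag = TRUE,
                curvature_profile = data.frame(t = tg, d2e2 = d2)))
  }
  list(recommended_t_low = tg[i], max_curvature = d2[i],
       no_optimum_flag = FALSE,
       curvature_profile = data.frame(t = tg, d2e2 = d2))
}
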