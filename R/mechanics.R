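#' Design matrix for the nonlinear equation of motion
#'
#' The single-compartment model relating airway pressure to flow and volume,
#'
#'   P = R1 * V' + R2 * V' * |V'| + E1 * V + E2 * V^2 + P0,
#'
#' is linear in its five coefficients. This builds the corresponding
#' regressor matrix with columns, in order: flow, flow * |flow|, volume,
#' volume^2, and a constant.
#'
#' @param flow Flow series, L/s.
#' @param volume Volume series, L, same length.
#' @return An `n x 5` numeric matrix with columns
#'   `flow`, `flow_abs_flow`, `volume`, `volume_sq`, `intercept`.
#' @examples
#' build_design_matrix(flow = c(1, -2), volume = c(1, 0.5))
#' @export
build_design_matrix <- function(flow, volume) {
  if (length(flow) != length(volume)) {
    aprv_error("flow and volume must have equal length", "aprv_invalid_input")
  }
  if (length(flow) < 5L) {
    aprv_error("need at least 5 samples to identify 5 coefficients",
               "aprv_invalid_input")
  }
  cbind(flow = flow,
        flow_abs_flow = flow * abs(flow),
        volume = volume,
        volume_sq = volume^2,
        intercept = rep(1, length(flow)))
}

.coef_names <- c("r1", "r2", "e1", "e2", "p0")

# 1-based sample index range(s) covered by segments (0-based half-open)
.segment_sample_index <- function(segments) {
  idx <- integer(0)
  for (k in seq_len(nrow(segments))) {
    idx <- c(idx, (segments$start_index[k] + 1L):segments$end_index[k])
  }
  sort(unique(idx))
}

#' Fit respiratory mechanics by multiple linear regression
#'
#' Ordinary least squares of airway pressure on the equation-of-motion
#' regressors over all samples in the selected breath segments. Columns are
#' rescaled internally for conditioning; reported coefficients are in
#' original units (R1 cmH2O.s/L, R2 cmH2O.s^2/L^2, E1 cmH2O/L,
#' E2 cmH2O/L^2, P0 cmH2O).
#'
#' @param record A [waveform_record()] with the volume channel populated
#'   (see [integrate_volume()]).
#' @param segments A [breath_segments()] data frame selecting the samples to
#'   fit; all samples of every listed cycle enter the regression.
#' @return An object of class `mechanics_estimate`: list with elements
#'   `r1`, `r2`, `e1`, `e2`, `p0`, `se` (named vector of coefficient
#'   standard errors), `rmse`, `r_squared`, `n_samples`,
#'   `condition_number`, `warnings` (character vector).
#' @examples
#' cfg <- simulation_config(
#'   settings = ventilator_settings(23, 4, 0, 0.5, rise_time_constant = 0),
#'   lung = lung_model(r1 = 8, r2 = 4, e1 = 25, e2 = 10, p0 = 5),
#'   n_cycles = 2, dt = 0.005)
#' rec <- simulate_aprv(cfg)
#' rec <- integrate_volume(rec, reset_indices = 1)
#' seg <- segment_breaths(rec, cfg$settings)
#' fit_mechanics(rec, seg)
#' @export
fit_mechanics <- function(record, segments) {
  validate_waveform_record(record)
  if (is.null(record$volume)) {
    aprv_error("volume channel missing: call integrate_volume() first",
               "aprv_invalid_input")
  }
  if (is.null(segments) || nrow(segments) == 0L) {
    aprv_error("no breath segments selected", "aprv_invalid_input")
  }
  idx <- .segment_sample_index(segments)
  y <- record$pressure[idx]
  X <- build_design_matrix(record$flow[idx], record$volume[idx])
  warnings <- character(0)
  n <- length(y)
  if (n < 25L) {
    aprv_warn(sprintf("only %d samples in regression; estimates may be unstable", n),
              "aprv_few_samples")
    warnings <- c(warnings, "few_samples")
  }

  # scale columns to unit 2-norm for conditioning; keep original units on output
  scales <- sqrt(colSums(X^2))
  sv <- svd(sweep(X, 2, pmax(scales, .Machine$double.xmin), "/"), nu = 0, nv = 0)$d
  rank_tol <- max(sv) * 1e-10
  if (any(scales == 0) || sum(sv > rank_tol) < 5L) {
    bad <- colnames(X)[scales < rank_tol * max(scales) | scales == 0]
    if (length(bad) == 0L) {
      # collinearity without an outright zero column: name the most dependent ones
      bad <- "(collinear combination of columns)"
    }
    aprv_error(paste0(
      "design matrix is rank deficient; unidentifiable column(s): ",
      paste(bad, collapse = ", ")), "aprv_rank_deficiency")
  }
  condition_number <- max(sv) / min(sv)

  Xs <- sweep(X, 2, scales, "/")
  qr_fit <- qr(Xs)
  beta <- qr.coef(qr_fit, y) / scales
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r_squared <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 1

  # coefficient standard errors: sigma^2 (X'X)^-1 via the scaled-QR factor
  sigma2 <- rss / max(n - 5L, 1L)
  dxx <- diag(chol2inv(qr.R(qr_fit)))
  dxx[qr_fit$pivot] <- dxx
  se <- sqrt(sigma2 * dxx) / scales
  names(se) <- .coef_names

  est <- structure(list(
    r1 = beta[[1]], r2 = beta[[2]], e1 = beta[[3]], e2 = beta[[4]],
    p0 = beta[[5]], se = se,
    rmse = sqrt(rss / n), r_squared = r_squared, n_samples = n,
    condition_number = condition_number, warnings = warnings
  ), class = "mechanics_estimate")
  if (est$r1 < 0 || est$r2 < 0 || est$e1 < 0 || est$e2 < 0) {
    aprv_warn("negative resistance/elastance estimate; check data quality",
              "aprv_negative_coefficient")
    est$warnings <- c(est$warnings, "negative_coefficient")
  }
  est
}

#' @export
print.mechanics_estimate <- function(x, ...) {
  cat("<mechanics_estimate>\n")
  cat(sprintf("  R1 %.4g cmH2O.s/L   R2 %.4g cmH2O.s2/L2\n", x$r1, x$r2))
  cat(sprintf("  E1 %.4g cmH2O/L     E2 %.4g cmH2O/L2   P0 %.4g cmH2O\n",
              x$e1, x$e2, x$p0))
  cat(sprintf("  rmse %.4g cmH2O, R2 %.6g, n %d, cond %.3g\n",
              x$rmse, x$r_squared, x$n_samples, x$condition_number))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}

#' Residual diagnostics for a mechanics fit
#'
#' @param estimate A `mechanics_estimate` produced by [fit_mechanics()].
#' @param record,segments The same data the estimate was fitted from.
#' @return A list with `residuals` (per fitted sample, cmH2O),
#'   `max_abs_residual`, and `orthogonality` — the inner product of the
#'   residuals with each regressor column, which is ~0 for a valid
#'   least-squares fit.
#' @export
fit_diagnostics <- function(estimate, record, segments) {
  idx <- .segment_sample_index(segments)
  y <- record$pressure[idx]
  X <- build_design_matrix(record$flow[idx], record$volume[idx])
  beta <- c(estimate$r1, estimate$r2, estimate$e1, estimate$e2, estimate$p0)
  resid <- y - drop(X %*% beta)
  list(residuals = resid,
       max_abs_residual = max(abs(resid)),
       orthogonality = drop(crossprod(X, resid)))
}

#' Write a mechanics report as JSON
#'
#' @param estimate A `mechanics_estimate`.
#' @param path Output file path (written atomically).
#' @return `path`, invisibly.
#' @export
write_mechanics_report <- function(estimate, path) {
  payload <- unclass(estimate)
  payload$se <- as.list(payload$se)
  payload$warnings <- as.list(payload$warnings)
  atomic_write_lines(
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    path)
  invisible(path)
}
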