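#' T_Low titration protocol
#'
#' The candidate expiratory-duration grid and the number of ventilatory
#' cycles delivered at each candidate. Defaults follow the computationally
#' directed protocol: T_Low stepped from 0.2 s to 1.0 s in 0.05 s
#' increments, three cycles per step.
#'
#' @param t_low_start,t_low_stop Grid endpoints, s (start < stop).
#' @param t_low_step Grid increment, s (> 0; must divide the span).
#' @param cycles_per_step Ventilatory cycles delivered per grid value (>= 1).
#' @return An object of class `titration_protocol`.
#' @export
titration_protocol <- function(t_low_start = 0.2, t_low_stop = 1.0,
                               t_low_step = 0.05, cycles_per_step = 3L) {
  p <- structure(list(t_low_start = t_low_start, t_low_stop = t_low_stop,
                      t_low_step = t_low_step,
                      cycles_per_step = as.integer(cycles_per_step)),
                 class = "titration_protocol")
  if (!is_scalar_num(p$t_low_start) || !is_scalar_num(p$t_low_stop) ||
      p$t_low_start >= p$t_low_stop) {
    aprv_error("require t_low_start < t_low_stop", "aprv_invalid_parameter")
  }
  if (!is_scalar_num(p$t_low_step) || p$t_low_step <= 0) {
    aprv_error("t_low_step must be positive", "aprv_invalid_parameter")
  }
  span_steps <- (p$t_low_stop - p$t_low_start) / p$t_low_step
  if (abs(span_steps - round(span_steps)) > 1e-9) {
    aprv_error("(t_low_stop - t_low_start) must be an integer multiple of t_low_step",
               "aprv_invalid_parameter")
  }
  if (!is_count(p$cycles_per_step)) {
    aprv_error("cycles_per_step must be a positive integer",
               "aprv_invalid_parameter")
  }
  p
}

#' @export
print.titration_protocol <- function(x, ...) {
  cat(sprintf(
    "<titration_protocol> T_Low %.3g..%.3g s by %.3g s, %d cycle(s)/step\n",
    x$t_low_start, x$t_low_stop, x$t_low_step, x$cycles_per_step))
  invisible(x)
}

#' Build the T_Low candidate grid
#'
#' @param protocol A [titration_protocol()].
#' @return Numeric vector of T_Low values, s (inclusive arithmetic grid;
#'   the default protocol yields 17 values 0.20, 0.25, ..., 1.00).
#' @examples
#' build_titration_grid(titration_protocol())
#' @export
build_titration_grid <- function(protocol) {
  k <- round((protocol$t_low_stop - protocol$t_low_start) / protocol$t_low_step)
  protocol$t_low_start + (0:k) * protocol$t_low_step
}

#' Run a T_Low titration
#'
#' Fits respiratory mechanics at every grid value and collects the
#' volume-dependent elastance E2 per step. At each step the first cycle is
#' discarded as a transient and the remaining cycles are fitted jointly.
#' Steps whose regression is rank deficient are marked missing (excluded
#' from the later spline fit) with a warning; if more than 25% of steps are
#' missing the titration aborts as unreliable.
#'
#' @param inputs Either a list of [waveform_record()]s, one per grid value
#'   in order, or a function `f(t_low)` returning the record acquired at
#'   that T_Low (e.g. a simulator wrapper, see [titrate_scenario()]).
#' @param protocol A [titration_protocol()].
#' @param discard_first Drop each step's first cycle as a settling
#'   transient and fit the remaining `cycles_per_step - 1` jointly.
#' @return An object of class `titration_curve` with `t_low_values`,
#'   `e2_values` (NA where missing), `estimates`, `missing`; the spline and
#'   recommendation slots are filled by [recommend_tlow()].
#' @export
run_titration <- function(inputs, protocol, discard_first = TRUE) {
  grid <- build_titration_grid(protocol)
  n_step <- length(grid)
  get_record <- if (is.function(inputs)) {
    inputs
  } else {
    if (length(inputs) != n_step) {
      aprv_error(sprintf("need one waveform per grid value (%d), got %d",
                         n_step, length(inputs)), "aprv_invalid_input")
    }
    function(t_low) inputs[[which(abs(grid - t_low) < 1e-9)[1]]]
  }

  e2 <- rep(NA_real_, n_step)
  e2_se <- rep(NA_real_, n_step)
  estimates <- vector("list", n_step)
  missing <- logical(n_step)
  for (i in seq_len(n_step)) {
    rec <- get_record(grid[i])
    est <- tryCatch({
      seg <- .titration_segments(rec, grid[i], protocol, discard_first)
      recv <- integrate_volume(rec, reset_indices = 1L)
      fit_mechanics(recv, seg)
    }, aprv_error = function(e) e)
    if (inherits(est, "condition")) {
      missing[i] <- TRUE
      aprv_warn(sprintf("titration step T_Low = %.3g s failed (%s); marked missing",
                        grid[i], conditionMessage(est)), "aprv_step_missing")
    } else {
      estimates[[i]] <- est
      e2[i] <- est$e2
      e2_se[i] <- est$se[["e2"]]
    }
  }
  if (sum(missing) > 0.25 * n_step) {
    aprv_error(sprintf(
      "%d of %d titration steps failed (> 25%%); E2 curve unreliable, aborting",
      sum(missing), n_step), "aprv_titration_unreliable")
  }
  structure(list(t_low_values = grid, e2_values = e2, e2_se = e2_se,
                 estimates = estimates,
                 missing = missing, protocol = protocol,
                 spline = NULL, recommended_t_low = NA_real_,
                 max_curvature = NA_real_, curvature_profile = NULL,
                 no_optimum_flag = NA),
            class = "titration_curve")
}

# Segments entering the per-step fit: discard the first cycle as transient,
# fit the remaining cycles_per_step - 1 jointly (all remaining if only one).
.titration_segments <- function(rec, t_low, protocol, discard_first = TRUE) {
  settings_guess <- rec$meta$settings
  settings <- if (!is.null(settings_guess)) {
    ventilator_settings(settings_guess$p_high, settings_guess$t_high,
                        settings_guess$p_low, t_low,
                        settings_guess$rise_time_constant)
  } else {
    ventilator_settings(p_high = stats::quantile(rec$pressure, 0.95),
                        t_high = 1, p_low = max(0, stats::quantile(rec$pressure, 0.05)),
                        t_low = t_low)
  }
  seg <- segment_breaths(rec, settings)
  if (nrow(seg) == 0L) {
    aprv_error("no complete cycles found in titration step", "aprv_invalid_input")
  }
  if (discard_first && nrow(seg) > 1L) {
    keep <- max(2L, nrow(seg) - (protocol$cycles_per_step - 1L) + 1L)
    seg <- seg[keep:nrow(seg), , drop = FALSE]
  }
  seg
}

#' Fit the E2 spline and recommend a T_Low
#'
#' Completes a [run_titration()] curve: fits the quartic smoothing spline to
#' the non-missing (T_Low, E2) points and locates the maximum of its second
#' derivative (see [optimal_tlow()]).
#'
#' @param curve A `titration_curve` from [run_titration()].
#' @return The curve with `spline`, `recommended_t_low`, `max_curvature`,
#'   `curvature_profile` and `no_optimum_flag` filled in.
#' @export
recommend_tlow <- function(curve) {
  if (!inherits(curve, "titration_curve")) {
    aprv_error("curve must be a titration_curve", "aprv_invalid_input")
  }
  keep <- !curve$missing
  weights <- if (!is.null(curve$e2_se) && all(is.finite(curve$e2_se[keep])) &&
                 all(curve$e2_se[keep] > 0)) {
    1 / curve$e2_se[keep]^2
  }
  sp <- fit_e2_spline(curve$t_low_values[keep], curve$e2_values[keep],
                      weights = weights)
  opt <- optimal_tlow(sp, curve$protocol)
  curve$spline <- sp
  curve$recommended_t_low <- opt$recommended_t_low
  curve$max_curvature <- opt$max_curvature
  curve$curvature_profile <- opt$curvature_profile
  curve$no_optimum_flag <- opt$no_optimum_flag
  curve
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve> %d steps on [%.3g, %.3g] s, %d missing\n",
              length(x$t_low_values), min(x$t_low_values),
              max(x$t_low_values), sum(x$missing)))
  if (!is.null(x$spline)) {
    if (isTRUE(x$no_optimum_flag)) {
      cat("  no optimum: E2 curve carries no appreciable curvature\n")
    } else {
      cat(sprintf("  recommended T_Low %.3f s (max curvature %.4g cmH2O/L2/s2)\n",
                  x$recommended_t_low, x$max_curvature))
    }
  }
  invisible(x)
}

#' Titrate a simulated scenario end to end
#'
#' Simulates `cycles_per_step` APRV cycles at every T_Low on the protocol
#' grid as one continuous ventilation session: the subject is first
#' ventilated for `warmup_cycles` cycles at the starting T_Low so the
#' recruitment state reaches its working point, then the lung state (volume
#' and recruited fraction) carries over from each grid step to the next, as
#' it does in an animal whose T_Low is stepped while ventilation continues.
#' Recruitment therefore equilibrates cumulatively over the sweep and is
#' nearly constant within any one step's fitted cycles. Per-step noise uses
#' a substream derived from the configuration seed. Runs the titration,
#' fits the spline and recommends a T_Low.
#'
#' @param config A [simulation_config()]; its `settings$t_low` and
#'   `n_cycles` are overridden per step by the protocol.
#' @param protocol A [titration_protocol()].
#' @param warmup_cycles Cycles ventilated at `t_low_start` before the sweep
#'   (not fitted); sized so that slow reopening dynamics settle.
#' @param discard_first Passed to [run_titration()]: drop each step's first
#'   cycle as a settling transient before fitting.
#' @return A completed `titration_curve`.
#' @export
titrate_scenario <- function(config, protocol = titration_protocol(),
                             warmup_cycles = 40, discard_first = TRUE) {
  grid <- build_titration_grid(protocol)
  state <- list(volume = 0, recruited = 1)
  if (warmup_cycles >= 1) {
    s <- config$settings
    warm_cfg <- simulation_config(
      settings = ventilator_settings(s$p_high, s$t_high, s$p_low, grid[1],
                                     s$rise_time_constant),
      lung = config$lung, recruitment = config$recruitment,
      n_cycles = warmup_cycles, dt = config$dt, seed = config$seed)
    state <- simulate_aprv(warm_cfg, initial = state)$meta$final_state
  }
  simulate_step <- function(t_low) {
    i <- which(abs(grid - t_low) < 1e-9)[1]
    s <- config$settings
    step_cfg <- simulation_config(
      settings = ventilator_settings(s$p_high, s$t_high, s$p_low, t_low,
                                     s$rise_time_constant),
      lung = config$lung, recruitment = config$recruitment,
      n_cycles = protocol$cycles_per_step, dt = config$dt,
      noise_sd_pressure = config$noise_sd_pressure,
      noise_sd_flow = config$noise_sd_flow,
      seed = (config$seed + 7919L * i) %% .Machine$integer.max)
    rec <- simulate_aprv(step_cfg, initial = state)
    state <<- rec$meta$final_state
    rec
  }
  recommend_tlow(run_titration(simulate_step, protocol, discard_first))
}

#' Expiratory flow metrics for one breath
#'
#' Descriptive measures of the expiratory flow decay used by manual APRV
#' titration practice: the peak expiratory flow magnitude, the flow
#' magnitude at end-expiration, their ratio, and the time for the flow to
#' effectively reach zero (first fall below 1% of the peak).
#'
#' @param record A [waveform_record()].
#' @param segment One row of a [breath_segments()] data frame.
#' @return A list with `peak_expiratory_flow` (L/s, magnitude),
#'   `end_expiratory_flow` (L/s, magnitude), `ee_pe_ratio`, and
#'   `time_to_zero_flow` (s from the start of expiration; `NA` if the flow
#'   never falls below 1% of peak).
#' @export
expiratory_flow_metrics <- function(record, segment) {
  validate_waveform_record(record)
  i0 <- segment$insp_end_index[1] + 1L   # 1-based expiration start
  i1 <- segment$end_index[1]
  if (i1 - i0 + 1L < 3L) {
    aprv_error("expiratory phase must span at least 3 samples",
               "aprv_invalid_input")
  }
  f <- record$flow[i0:i1]
  peak <- max(-f)
  if (peak <= 0) {
    aprv_error("zero peak expiratory flow: end/peak ratio undefined",
               "aprv_undefined_ratio")
  }
  eef <- abs(f[length(f)])
  below <- which(abs(f) < 0.01 * peak)
  t_zero <- if (length(below)) (below[1] - 1L) / record$sample_rate else NA_real_
  list(peak_expiratory_flow = peak,
       end_expiratory_flow = eef,
       ee_pe_ratio = eef / peak,
       time_to_zero_flow = t_zero)
}

#' Write / read a titration table
#'
#' Delimited text with one row per grid step and columns
#' `tlow_s,e2_cmh2o_per_l2,r1,r2,e1,p0,rmse,missing`.
#'
#' @param curve A `titration_curve`.
#' @param path File path.
#' @return `path` (writer) or a data frame (reader).
#' @export
write_titration_table <- function(curve, path) {
  g <- function(field) vapply(seq_along(curve$t_low_values), function(i) {
    if (curve$missing[i]) NA_real_ else curve$estimates[[i]][[field]]
  }, numeric(1))
  df <- data.frame(tlow_s = curve$t_low_values,
                   e2_cmh2o_per_l2 = curve$e2_values,
                   r1 = g("r1"), r2 = g("r2"), e1 = g("e1"), p0 = g("p0"),
                   rmse = g("rmse"),
                   missing = as.integer(curve$missing))
  lines <- c(paste(names(df), collapse = ","),
             apply(df, 1, function(row) paste(
               ifelse(is.na(row), "NA", sprintf("%.9g", as.numeric(row))),
               collapse = ",")))
  atomic_write_lines(lines, path)
  invisible(path)
}

#' @rdname write_titration_table
#' @export
read_titration_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("tlow_s", "e2_cmh2o_per_l2", "missing")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    aprv_error(paste0("titration table missing column(s): ",
                      paste(miss, collapse = ", ")), "aprv_parse_error")
  }
  df
}

#' Write a recommendation report as JSON
#'
#' @param curve A completed `titration_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recommendation_report <- function(curve, path) {
  payload <- list(
    recommended_t_low_s = curve$recommended_t_low,
    max_curvature = curve$max_curvature,
    no_optimum_flag = isTRUE(curve$no_optimum_flag),
    protocol = unclass(curve$protocol),
    software_version = as.character(utils::packageVersion("aprvtitrate"))
  )
  atomic_write_lines(
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     na = "null"),
    path)
  invisible(path)
}
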