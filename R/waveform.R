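#' Ventilator waveform record
#'
#' Container for a uniformly sampled airway pressure / flow recording.
#' Pressure is airway opening pressure in cmH2O, flow is in L/s with
#' inspiration positive, and volume (L) is absent until derived by
#' [integrate_volume()].
#'
#' @param time Sample times in seconds, uniformly spaced, strictly increasing.
#' @param pressure Airway pressure in cmH2O, same length as `time`.
#' @param flow Airway flow in L/s (inspiratory positive), same length as `time`.
#' @param volume Optional volume channel in L (normally derived, not supplied).
#' @param sample_rate Sampling rate in Hz. Defaults to `1 / median(diff(time))`.
#' @param phase Optional per-sample phase label, one of `"inspiration"`,
#'   `"expiration"`, `"unknown"`.
#' @param meta Named list of free-form provenance (settings, seed, truth).
#'
#' @return An object of class `waveform_record`: a list with the fields above.
#' @examples
#' t <- seq(0, 1, by = 0.005)
#' rec <- waveform_record(t, pressure = rep(5, length(t)),
#'                        flow = rep(0, length(t)))
#' rec
#' @export
waveform_record <- function(time, pressure, flow, volume = NULL,
                            sample_rate = NULL, phase = NULL, meta = list()) {
  time <- as.numeric(time)
  pressure <- as.numeric(pressure)
  flow <- as.numeric(flow)
  if (is.null(sample_rate)) {
    if (length(time) < 2L) {
      aprv_error("cannot infer sample_rate from fewer than 2 samples",
                 "aprv_invalid_input")
    }
    sample_rate <- 1 / stats::median(diff(time))
  }
  rec <- structure(list(
    time = time, pressure = pressure, flow = flow,
    volume = if (!is.null(volume)) as.numeric(volume),
    sample_rate = as.numeric(sample_rate),
    phase = if (!is.null(phase)) as.character(phase),
    meta = meta
  ), class = "waveform_record")
  validate_waveform_record(rec)
}

#' @rdname waveform_record
#' @param x,rec A `waveform_record`.
#' @export
validate_waveform_record <- function(rec) {
  n <- length(rec$time)
  if (n < 2L) aprv_error("waveform needs at least 2 samples", "aprv_invalid_input")
  if (length(rec$pressure) != n || length(rec$flow) != n) {
    aprv_error("time, pressure and flow must have equal length",
               "aprv_invalid_input")
  }
  if (!is_scalar_num(rec$sample_rate) || rec$sample_rate <= 0) {
    aprv_error("sample_rate must be a positive number", "aprv_invalid_input")
  }
  dt <- diff(rec$time)
  step <- 1 / rec$sample_rate
  if (any(dt <= 0) || max(abs(dt - step)) > 1e-6 * step) {
    aprv_error(
      "time must be strictly increasing with uniform step 1/sample_rate (relative jitter < 1e-6)",
      "aprv_nonuniform_time")
  }
  if (!is.null(rec$volume) && length(rec$volume) != n) {
    aprv_error("volume channel must match waveform length", "aprv_invalid_input")
  }
  if (!is.null(rec$phase)) {
    if (length(rec$phase) != n ||
        !all(rec$phase %in% c("inspiration", "expiration", "unknown"))) {
      aprv_error("phase must label every sample as inspiration/expiration/unknown",
                 "aprv_invalid_input")
    }
  }
  rec
}

#' @export
print.waveform_record <- function(x, ...) {
  dur <- x$time[length(x$time)] - x$time[1]
  cat(sprintf("<waveform_record> %d samples @ %.6g Hz (%.3f s)\n",
              length(x$time), x$sample_rate, dur))
  cat(sprintf("  pressure [cmH2O]: %.3g .. %.3g\n",
              min(x$pressure), max(x$pressure)))
  cat(sprintf("  flow     [L/s]  : %.3g .. %.3g\n", min(x$flow), max(x$flow)))
  if (!is.null(x$volume)) {
    cat(sprintf("  volume   [L]    : %.3g .. %.3g\n",
                min(x$volume), max(x$volume)))
  }
  if (!is.null(x$phase)) cat("  phase channel present\n")
  invisible(x)
}

#' @export
length.waveform_record <- function(x) length(x$time)

#' APRV ventilator settings
#'
#' The four APRV parameters plus the pressure-source rise time constant:
#' the high (inspiratory) pressure `p_high` held for `t_high`, released to
#' `p_low` for `t_low`.
#'
#' @param p_high Inspiratory pressure, cmH2O.
#' @param t_high Inspiratory duration, s.
#' @param p_low Release (expiratory) pressure, cmH2O.
#' @param t_low Release duration, s.
#' @param rise_time_constant Exponential rise/fall time constant of the
#'   pressure source, s (0 = ideal square wave).
#' @return An object of class `ventilator_settings`.
#' @examples
#' ventilator_settings(p_high = 23, t_high = 4, p_low = 0, t_low = 0.5)
#' @export
ventilator_settings <- function(p_high, t_high, p_low = 0, t_low = 0.5,
                                rise_time_constant = 0.05) {
  s <- structure(list(p_high = p_high, t_high = t_high, p_low = p_low,
                      t_low = t_low, rise_time_constant = rise_time_constant),
                 class = "ventilator_settings")
  for (f in names(s)) {
    if (!is_scalar_num(s[[f]])) {
      aprv_error(sprintf("setting '%s' must be a finite number", f),
                 "aprv_invalid_parameter")
    }
  }
  if (!(s$p_high > s$p_low) || s$p_low < 0) {
    aprv_error("require p_high > p_low >= 0", "aprv_invalid_parameter")
  }
  if (s$t_high <= 0 || s$t_low <= 0) {
    aprv_error("t_high and t_low must be positive", "aprv_invalid_parameter")
  }
  if (s$rise_time_constant < 0) {
    aprv_error("rise_time_constant must be >= 0", "aprv_invalid_parameter")
  }
  s
}

#' @export
print.ventilator_settings <- function(x, ...) {
  cat(sprintf(
    "<ventilator_settings> P_High %.4g cmH2O x %.4g s | P_Low %.4g cmH2O x %.4g s (rise tau %.3g s)\n",
    x$p_high, x$t_high, x$p_low, x$t_low, x$rise_time_constant))
  invisible(x)
}

#' Breath segments
#'
#' One row per complete ventilatory cycle. Indices are 0-based and half-open:
#' inspiration spans `[start_index, insp_end_index)`, expiration spans
#' `[insp_end_index, end_index)`.
#'
#' @param start_index,insp_end_index,end_index Integer sample indices.
#' @param sample_rate Hz, used to derive the measured durations.
#' @return A data frame of class `breath_segments` with columns
#'   `start_index`, `insp_end_index`, `end_index`, `t_high_measured`,
#'   `t_low_measured`.
#' @export
breath_segments <- function(start_index, insp_end_index, end_index,
                            sample_rate) {
  if (!(length(start_index) == length(insp_end_index) &&
        length(end_index) == length(start_index))) {
    aprv_error("segment index vectors must have equal length",
               "aprv_invalid_input")
  }
  if (length(start_index) &&
      !all(start_index < insp_end_index & insp_end_index < end_index)) {
    aprv_error("require start_index < insp_end_index < end_index",
               "aprv_invalid_input")
  }
  out <- data.frame(
    start_index = as.integer(start_index),
    insp_end_index = as.integer(insp_end_index),
    end_index = as.integer(end_index),
    t_high_measured = (insp_end_index - start_index) / sample_rate,
    t_low_measured = (end_index - insp_end_index) / sample_rate
  )
  class(out) <- c("breath_segments", "data.frame")
  out
}

#' Zero-phase low-pass filter
#'
#' Filters the pressure and flow channels with a zero-phase (forward-backward)
#' Butterworth low-pass, second-order sections applied twice so the overall
#' response is fourth-order with unit DC gain and no phase distortion.
#' Mirrors the analog anti-noise filtering applied to ventilator waveforms
#' before recording.
#'
#' @param record A [waveform_record()].
#' @param cutoff_hz Cutoff frequency in Hz; must lie in (0, sample_rate / 2).
#' @return A new `waveform_record` with filtered pressure and flow; time,
#'   sample rate and any volume channel are unchanged.
#' @examples
#' t <- seq(0, 2, by = 0.005)
#' rec <- waveform_record(t, pressure = 10 + sin(2 * pi * 40 * t),
#'                        flow = rep(0, length(t)))
#' f <- lowpass_filter(rec, cutoff_hz = 10)
#' @export
lowpass_filter <- function(record, cutoff_hz) {
  validate_waveform_record(record)
  nyq <- record$sample_rate / 2
  if (!is_scalar_num(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq) {
    aprv_error(sprintf(
      "cutoff_hz must lie strictly between 0 and the Nyquist frequency (%.6g Hz)",
      nyq), "aprv_invalid_parameter")
  }
  bf <- signal::butter(2, cutoff_hz / nyq, type = "low")
  # Pad with edge-reflected samples so filtfilt start-up transients do not
  # leak into the record; pad length follows the usual 3 * filter-order rule
  # scaled to the cutoff period.
  record$pressure <- .filtfilt_padded(bf, record$pressure)
  record$flow <- .filtfilt_padded(bf, record$flow)
  record
}

.filtfilt_padded <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1L, max(12L, 3L * ceiling(1 / (bf$b[1] + 1e-12))))
  np <- min(np, 500L)
  left <- 2 * x[1] - x[seq(np + 1L, 2L, by = -1L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - np, by = -1L)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(np + 1L):(np + n)]
}

#' Integrate flow to volume
#'
#' Computes the volume channel by trapezoidal integration of flow, resetting
#' to zero at each supplied index. With a single reset at the start of a
#' record that begins at the relaxed end-expiratory state, the volume is
#' referenced to that state throughout; per-breath resets are available for
#' drift control on long noisy recordings.
#'
#' @param record A [waveform_record()].
#' @param reset_indices 1-based sample indices (sorted) at which volume is
#'   reset to zero; the first must be at or before the first sample used for
#'   mechanics fitting.
#' @return The record with its `volume` channel populated (L).
#' @examples
#' t <- seq(0, 2, by = 0.005)
#' rec <- waveform_record(t, pressure = rep(0, length(t)),
#'                        flow = rep(0.5, length(t)))
#' rec <- integrate_volume(rec, reset_indices = 1)
#' max(rec$volume)  # 1 L after 2 s at 0.5 L/s
#' @export
integrate_volume <- function(record, reset_indices) {
  validate_waveform_record(record)
  if (length(reset_indices) == 0L) {
    aprv_error(
      "reset_indices is empty: segment breaths first (see segment_breaths) and pass the breath-start indices",
      "aprv_invalid_input")
  }
  reset_indices <- as.integer(sort(reset_indices))
  n <- length(record$time)
  if (reset_indices[1] < 1L || reset_indices[length(reset_indices)] > n) {
    aprv_error("reset_indices out of range", "aprv_invalid_input")
  }
  dt <- 1 / record$sample_rate
  f <- record$flow
  # cumulative trapezoid
  v <- c(0, cumsum((f[-n] + f[-1]) / 2 * dt))
  # reset: subtract the running value at each reset index from that point on
  bounds <- c(reset_indices, n + 1L)
  for (k in seq_along(reset_indices)) {
    i0 <- bounds[k]; i1 <- bounds[k + 1L] - 1L
    v[i0:i1] <- v[i0:i1] - v[i0]
  }
  record$volume <- v
  record
}

#' Segment breaths from an APRV pressure waveform
#'
#' Detects complete ventilatory cycles (inspiration followed by a full
#' expiration) from threshold crossings of the pressure signal at the
#' midpoint between `p_high` and `p_low`, with hysteresis of 10% of the
#' pressure span for noise robustness. When the record carries a phase
#' channel (e.g. simulator output) it overrides threshold detection.
#'
#' @param record A [waveform_record()].
#' @param settings The [ventilator_settings()] in force during the recording.
#' @return A [breath_segments()] data frame (possibly with zero rows; a
#'   warning is emitted when no crossings are found).
#' @export
segment_breaths <- function(record, settings) {
  validate_waveform_record(record)
  n <- length(record$time)

  if (!is.null(record$phase)) {
    insp <- record$phase == "inspiration"
    starts <- which(insp & !c(FALSE, insp[-n]))      # rising edges
    ends <- which(!insp & c(FALSE, insp[-n]))        # insp -> exp transitions
    return(.segments_from_edges(starts, ends, n, record$sample_rate))
  }

  mid <- (settings$p_high + settings$p_low) / 2
  hys <- 0.10 * (settings$p_high - settings$p_low)
  p <- record$pressure
  state <- NA_character_
  starts <- integer(0); ends <- integer(0)
  hi <- p > mid + hys
  lo <- p < mid - hys
  for (i in seq_len(n)) {
    if (is.na(state)) {
      if (hi[i]) {
        # record opens in (or at the onset of) inspiration
        state <- "high"; starts <- c(starts, i)
      } else if (lo[i]) state <- "low"
    } else if (state == "low" && hi[i]) {
      state <- "high"; starts <- c(starts, i)
    } else if (state == "high" && lo[i]) {
      state <- "low"; ends <- c(ends, i)
    }
  }
  if (length(starts) == 0L && length(ends) == 0L) {
    aprv_warn("no pressure threshold crossings found; returning no segments",
              "aprv_no_crossings")
    return(breath_segments(integer(0), integer(0), integer(0),
                           record$sample_rate))
  }
  .segments_from_edges(starts, ends, n, record$sample_rate)
}

# Pair rising edges (breath starts) with the following falling edge
# (inspiration end) and the next rising edge (cycle end). Only complete
# cycles are returned; a trailing expiration that runs to the end of the
# record closes the final cycle.
.segments_from_edges <- function(starts, ends, n, sample_rate) {
  seg_start <- integer(0); seg_mid <- integer(0); seg_end <- integer(0)
  for (s in starts) {
    e_mid <- ends[ends > s]
    if (length(e_mid) == 0L) next
    e_mid <- e_mid[1]
    nxt <- starts[starts > e_mid]
    e_end <- if (length(nxt)) nxt[1] else n + 1L
    if (e_end > n + 1L) next
    seg_start <- c(seg_start, s); seg_mid <- c(seg_mid, e_mid)
    seg_end <- c(seg_end, e_end)
  }
  # last cycle: only keep a record-terminated expiration if it is non-trivial
  keep <- seg_end - seg_mid >= 2L
  breath_segments(seg_start[keep] - 1L, seg_mid[keep] - 1L,
                  seg_end[keep] - 1L, sample_rate)
}
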