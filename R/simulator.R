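#' Ground-truth lung mechanics for simulation
#'
#' Parameters of the nonlinear single-compartment model used as simulator
#' ground truth: linear and flow-dependent (Rohrer-type) resistance, linear
#' and volume-dependent elastance, and the baseline end-expiratory pressure.
#'
#' @param r1 Linear resistance, cmH2O.s/L (> 0).
#' @param r2 Flow-dependent resistance, cmH2O.s^2/L^2 (>= 0).
#' @param e1 Linear elastance, cmH2O/L (> 0).
#' @param e2 Volume-dependent elastance, cmH2O/L^2 (>= 0).
#' @param p0 Baseline end-expiratory pressure, cmH2O.
#' @return An object of class `lung_model`.
#' @export
lung_model <- function(r1 = 8, r2 = 4, e1 = 30, e2 = 15, p0 = 0) {
  m <- structure(list(r1 = r1, r2 = r2, e1 = e1, e2 = e2, p0 = p0),
                 class = "lung_model")
  for (f in names(m)) {
    if (!is_scalar_num(m[[f]])) {
      aprv_error(sprintf("lung parameter '%s' must be a finite number", f),
                 "aprv_invalid_parameter")
    }
  }
  if (m$r1 <= 0 || m$e1 <= 0 || m$r2 < 0 || m$e2 < 0) {
    aprv_error("require r1 > 0, e1 > 0, r2 >= 0, e2 >= 0",
               "aprv_invalid_parameter")
  }
  m
}

#' Pressure-dependent recruitment dynamics
#'
#' Emulates alveolar recruitment/derecruitment: the recruited fraction `r`
#' relaxes toward a sigmoidal equilibrium in alveolar pressure (midpoint
#' `p_crit`, slope scale `k`), with separate opening and closing time
#' constants. Derecruitment during a long release (T_Low) raises the
#' effective elastances, which is the physiological premise the T_Low
#' titration exploits.
#'
#' @param enabled Logical; when `FALSE` the lung is exactly the static
#'   nonlinear model.
#' @param p_crit Sigmoid midpoint, cmH2O.
#' @param k Sigmoid slope scale, cmH2O (> 0).
#' @param tau_open Opening (recruitment) time constant, s (> 0). Reopening
#'   of collapsed units is slow (breath-to-breath scale), so the default is
#'   much longer than one inspiratory hold.
#' @param tau_close Closing (derecruitment) time constant, s (> 0).
#' @param r_min Minimum recruited fraction, in (0, 1].
#' @param coupling How the recruitment state feeds back on mechanics:
#'   `"breath"` (default) freezes the effective elastances at each cycle
#'   start — units that close during one expiration stiffen the *next*
#'   breath, which is the premise the T_Low titration exploits — while
#'   `"continuous"` applies the instantaneous recruited fraction at every
#'   sample. The recruitment state itself always evolves continuously.
#' @return An object of class `recruitment_model`.
#' @export
recruitment_model <- function(enabled = FALSE, p_crit = 4.5, k = 1.5,
                              tau_open = 60, tau_close = 3, r_min = 0.5,
                              coupling = c("breath", "continuous")) {
  coupling <- match.arg(coupling)
  m <- structure(list(enabled = isTRUE(enabled), p_crit = p_crit, k = k,
                      tau_open = tau_open, tau_close = tau_close,
                      r_min = r_min, coupling = coupling),
                 class = "recruitment_model")
  for (f in setdiff(names(m), c("enabled", "coupling"))) {
    if (!is_scalar_num(m[[f]])) {
      aprv_error(sprintf("recruitment parameter '%s' must be a finite number", f),
                 "aprv_invalid_parameter")
    }
  }
  if (m$tau_open <= 0 || m$tau_close <= 0) {
    aprv_error("tau_open and tau_close must be positive",
               "aprv_invalid_parameter")
  }
  if (m$k <= 0) aprv_error("k must be positive", "aprv_invalid_parameter")
  if (m$r_min <= 0 || m$r_min > 1) {
    aprv_error("r_min must lie in (0, 1]", "aprv_invalid_parameter")
  }
  m
}

#' Simulation configuration
#'
#' @param settings A [ventilator_settings()].
#' @param lung A [lung_model()].
#' @param recruitment A [recruitment_model()]; disabled by default.
#' @param n_cycles Number of ventilatory cycles to simulate (>= 1).
#' @param dt Integration / sampling step, s (<= 0.005).
#' @param noise_sd_pressure Additive Gaussian noise SD on pressure, cmH2O.
#' @param noise_sd_flow Additive Gaussian noise SD on flow, L/s.
#' @param seed Integer seed for the noise generator.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(settings, lung = lung_model(),
                              recruitment = recruitment_model(),
                              n_cycles = 3, dt = 0.001,
                              noise_sd_pressure = 0, noise_sd_flow = 0,
                              seed = 1L) {
  if (!inherits(settings, "ventilator_settings")) {
    aprv_error("settings must be a ventilator_settings object",
               "aprv_invalid_parameter")
  }
  if (!inherits(lung, "lung_model")) {
    aprv_error("lung must be a lung_model object", "aprv_invalid_parameter")
  }
  if (!inherits(recruitment, "recruitment_model")) {
    aprv_error("recruitment must be a recruitment_model object",
               "aprv_invalid_parameter")
  }
  if (!is_scalar_num(dt) || dt <= 0 || dt > 0.005) {
    aprv_error("dt must be positive and at most 0.005 s",
               "aprv_invalid_parameter")
  }
  if (!is_count(n_cycles)) {
    aprv_error("n_cycles must be a positive integer", "aprv_invalid_parameter")
  }
  if (!is_scalar_num(noise_sd_pressure) || noise_sd_pressure < 0 ||
      !is_scalar_num(noise_sd_flow) || noise_sd_flow < 0) {
    aprv_error("noise SDs must be non-negative", "aprv_invalid_parameter")
  }
  structure(list(settings = settings, lung = lung, recruitment = recruitment,
                 n_cycles = as.integer(n_cycles), dt = dt,
                 noise_sd_pressure = noise_sd_pressure,
                 noise_sd_flow = noise_sd_flow,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' APRV pressure-source waveform
#'
#' Periodic square-ish airway pressure target: `p_high` during inspiration
#' (duration `t_high`), `p_low` during the release (duration `t_low`), each
#' approached exponentially with `rise_time_constant` (instantaneous when 0).
#'
#' @param settings A [ventilator_settings()].
#' @param t Time(s) since the start of the first inspiration, s (vectorized).
#' @return Airway pressure at `t`, cmH2O.
#' @examples
#' s <- ventilator_settings(23, 4, 0, 0.5, rise_time_constant = 0)
#' aprv_pressure_waveform(s, c(0, 2, 4.2))
#' @export
aprv_pressure_waveform <- function(settings, t) {
  period <- settings$t_high + settings$t_low
  tau <- settings$rise_time_constant
  tt <- t %% period
  insp <- tt < settings$t_high
  if (tau <= 0) {
    return(ifelse(insp, settings$p_high, settings$p_low))
  }
  # exponential approach from the level reached at the preceding switch;
  # at steady periodicity the switch levels are the fixed point of the
  # two-phase exponential map
  eh <- exp(-settings$t_high / tau)
  el <- exp(-settings$t_low / tau)
  # p_start_insp: level at inspiration onset; p_start_exp: at release onset
  # p_start_exp = p_high + (p_start_insp - p_high) * eh
  # p_start_insp = p_low + (p_start_exp - p_low) * el
  denom <- 1 - eh * el
  p_start_insp <- (settings$p_low * (1 - el) +
                     el * settings$p_high * (1 - eh)) / denom
  p_start_exp <- settings$p_high + (p_start_insp - settings$p_high) * eh
  out <- numeric(length(tt))
  out[insp] <- settings$p_high +
    (p_start_insp - settings$p_high) * exp(-tt[insp] / tau)
  out[!insp] <- settings$p_low +
    (p_start_exp - settings$p_low) * exp(-(tt[!insp] - settings$t_high) / tau)
  out
}

#' Flow from the resistive pressure drop
#'
#' Inverts the resistive part of the equation of motion: solves
#' `R2 * V' * |V'| + R1 * V' = D` for the flow `V'`, where `D` is the
#' driving pressure (airway pressure minus elastic recoil and baseline).
#' The unique real root is closed-form:
#' `sign(D) * (-R1 + sqrt(R1^2 + 4 * R2 * |D|)) / (2 * R2)`, with the limit
#' `D / R1` as `R2 -> 0`.
#'
#' @param drive Driving pressure D, cmH2O (vectorized).
#' @param r1 Linear resistance, cmH2O.s/L (> 0).
#' @param r2 Flow-dependent resistance, cmH2O.s^2/L^2 (>= 0).
#' @return Flow in L/s.
#' @examples
#' solve_flow(15, r1 = 10, r2 = 5)  # exactly 1 L/s
#' @export
solve_flow <- function(drive, r1, r2) {
  if (r1 <= 0 || r2 < 0) {
    aprv_error("require r1 > 0 and r2 >= 0", "aprv_invalid_parameter")
  }
  if (r2 < 1e-12) return(drive / r1)
  sign(drive) * (-r1 + sqrt(r1 * r1 + 4 * r2 * abs(drive))) / (2 * r2)
}

#' One recruitment-state update
#'
#' First-order relaxation of the recruited fraction toward its sigmoidal
#' equilibrium at the current alveolar pressure, using the exact exponential
#' step (unconditionally stable for any `dt`). The opening time constant
#' applies when recruiting, the closing one when derecruiting.
#'
#' @param r Current recruited fraction, in `[r_min, 1]`.
#' @param p_alv Alveolar (elastic recoil + baseline) pressure, cmH2O.
#' @param model A [recruitment_model()].
#' @param dt Time step, s (> 0).
#' @return The updated recruited fraction, clamped to `[r_min, 1]`.
#' @export
recruitment_update <- function(r, p_alv, model, dt) {
  if (dt <= 0) aprv_error("dt must be positive", "aprv_invalid_parameter")
  r_eq <- model$r_min +
    (1 - model$r_min) / (1 + exp(-(p_alv - model$p_crit) / model$k))
  tau <- if (r_eq > r) model$tau_open else model$tau_close
  r_new <- r_eq + (r - r_eq) * exp(-dt / tau)
  min(1, max(model$r_min, r_new))
}

#' Simulate APRV waveforms from a nonlinear lung
#'
#' Time-steps the nonlinear single-compartment lung driven by an ideal APRV
#' pressure source. Volume advances by an implicit trapezoidal rule (a few
#' fixed-point iterations per step), so the recorded pressure, flow and
#' internally tracked volume samples are mutually consistent with the
#' equation of motion at every sample. With recruitment enabled the
#' effective elastances are `E1 / r` and `E2 / r^2` (recruited units share
#' the delivered volume); the recruitment state is updated every time step
#' from the alveolar pressure, and feeds back on the mechanics either
#' continuously or frozen per breath depending on the model's `coupling`
#' (see [recruitment_model()]). Seeded Gaussian sensor noise is added to
#' the pressure and flow channels after simulation.
#'
#' @param config A [simulation_config()].
#' @param initial Optional initial state, a list with `volume` (L above the
#'   relaxed volume, default 0) and `recruited` (fraction, default 1).
#'   Passing the `meta$final_state` of a previous record chains simulations
#'   into one continuous ventilation session, as in a sequential T_Low
#'   titration.
#' @return A [waveform_record()] with a ground-truth phase channel and
#'   `meta` carrying the configuration, true parameters and (when
#'   recruitment is enabled) the recruited-fraction trace. The volume
#'   channel is left unpopulated, as it would be for a real recording;
#'   integrating the noise-free flow from the start of the record
#'   reproduces the simulator's volume state exactly.
#' @examples
#' cfg <- simulation_config(
#'   settings = ventilator_settings(23, 4, 0, 0.5),
#'   lung = lung_model(), n_cycles = 2, dt = 0.005)
#' simulate_aprv(cfg)
#' @export
simulate_aprv <- function(config, initial = list(volume = 0, recruited = 1)) {
  if (!inherits(config, "simulation_config")) {
    aprv_error("config must be a simulation_config", "aprv_invalid_parameter")
  }
  v0 <- initial$volume %||% 0
  r0 <- initial$recruited %||% 1
  s <- config$settings; lung <- config$lung; rec_m <- config$recruitment
  dt <- config$dt
  period <- s$t_high + s$t_low
  n <- as.integer(round(config$n_cycles * period / dt))
  t <- (seq_len(n) - 1L) * dt
  paw <- aprv_pressure_waveform(s, t)
  phase <- ifelse((t %% period) < s$t_high, "inspiration", "expiration")

  r1 <- lung$r1; r2 <- lung$r2; e1 <- lung$e1; e2 <- lung$e2; p0 <- lung$p0
  recr <- isTRUE(rec_m$enabled)
  V <- numeric(n); Q <- numeric(n); R <- numeric(n)
  rk <- if (recr) min(1, max(rec_m$r_min, r0)) else 1
  r_mech <- rk  # recruited fraction the mechanics feel (frozen per breath)
  breath_coupling <- recr && identical(rec_m$coupling, "breath")
  cycle_idx <- floor(t / period + 1e-9)
  V[1] <- v0
  e1e <- if (recr) e1 / r_mech else e1
  e2e <- if (recr) e2 / (r_mech * r_mech) else e2
  Q[1] <- solve_flow(paw[1] - (e1e * v0 + e2e * v0 * v0 + p0), r1, r2)
  R[1] <- rk
  use_quad <- r2 >= 1e-12
  half_dt <- dt / 2
  for (k in seq_len(n - 1L)) {
    if (recr) {
      if (breath_coupling) {
        if (cycle_idx[k + 1L] != cycle_idx[k]) r_mech <- rk
      } else r_mech <- rk
      e1e <- e1 / r_mech; e2e <- e2 / (r_mech * r_mech)
    }
    vk <- V[k]; qk <- Q[k]; pk1 <- paw[k + 1L]
    v <- vk + dt * qk  # explicit predictor
    # fixed-point solve of the implicit trapezoidal step; contraction factor
    # ~ dt * E_eff / (2 * R1) so a handful of iterations reach round-off
    for (it in 1:30) {
      d <- pk1 - (e1e * v + e2e * v * v + p0)
      q <- if (use_quad) {
        sign(d) * (-r1 + sqrt(r1 * r1 + 4 * r2 * abs(d))) / (2 * r2)
      } else d / r1
      vn <- vk + half_dt * (qk + q)
      if (abs(vn - v) <= 1e-14 * (1 + abs(vn))) { v <- vn; break }
      v <- vn
    }
    if (abs(v) > 5) {
      aprv_error(
        "simulation unstable (|V| > 5 L); use a smaller dt or check parameters",
        "aprv_instability")
    }
    V[k + 1L] <- v; Q[k + 1L] <- q
    if (recr) {
      p_alv <- e1e * v + e2e * v * v + p0
      rk <- recruitment_update(rk, p_alv, rec_m, dt)
    }
    R[k + 1L] <- rk
  }

  if (config$noise_sd_pressure > 0 || config$noise_sd_flow > 0) {
    with_local_seed(config$seed, {
      if (config$noise_sd_pressure > 0) {
        paw <- paw + stats::rnorm(n, sd = config$noise_sd_pressure)
      }
      if (config$noise_sd_flow > 0) {
        Q <- Q + stats::rnorm(n, sd = config$noise_sd_flow)
      }
    })
  }

  meta <- list(
    generator = "aprvtitrate::simulate_aprv",
    version = as.character(utils::packageVersion("aprvtitrate")),
    seed = config$seed,
    settings = unclass(s),
    truth = unclass(lung),
    recruitment = unclass(rec_m),
    dt = dt, n_cycles = config$n_cycles,
    noise_sd_pressure = config$noise_sd_pressure,
    noise_sd_flow = config$noise_sd_flow,
    true_volume = V,
    recruited_fraction = if (recr) R,
    final_state = list(volume = V[n], recruited = rk)
  )
  waveform_record(time = t, pressure = paw, flow = Q,
                  sample_rate = 1 / dt, phase = phase, meta = meta)
}
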