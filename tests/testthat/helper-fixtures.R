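# Shared builders for the test suite. Everything is generated in code at
# test time; no stored fixtures.

cd_settings <- function(t_low = 0.5, rise = 0.05) {
  ventilator_settings(p_high = 23, t_high = 4, p_low = 0, t_low = t_low,
                      rise_time_constant = rise)
}

test_lung <- function() lung_model(r1 = 8, r2 = 4, e1 = 25, e2 = 10, p0 = 5)

demo_lung <- function() lung_model(r1 = 8, r2 = 4, e1 = 30, e2 = 15, p0 = 0)

demo_recruitment <- function() recruitment_model(enabled = TRUE)

# simulate -> segment -> integrate -> fit, fitting the last `last` cycles
fit_pipeline <- function(cfg, last = 2) {
  rec <- simulate_aprv(cfg)
  seg <- segment_breaths(rec, cfg$settings)
  seg <- seg[max(1L, nrow(seg) - last + 1L):nrow(seg), , drop = FALSE]
  rec <- integrate_volume(rec, reset_indices = 1L)
  fit_mechanics(rec, seg)
}

coef_vec <- function(est) c(est$r1, est$r2, est$e1, est$e2, est$p0)

# independent oracle: explicit normal-equations least squares
normal_equations_fit <- function(pressure, flow, volume) {
  X <- cbind(flow, flow * abs(flow), volume, volume^2, 1)
  drop(solve(crossprod(X), crossprod(X, pressure)))
}

# a simple synthetic waveform record
flat_record <- function(n = 100, pressure = 5, flow = 0, fs = 200) {
  t <- (seq_len(n) - 1) / fs
  waveform_record(t, rep(pressure, n), rep(flow, n))
}
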