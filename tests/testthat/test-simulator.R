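test_that("APRV pressure source hits its targets and is periodic", {
  cd <- cd_settings(rise = 0)
  expect_equal(aprv_pressure_waveform(cd, 2.0), 23)
  injury <- ventilator_settings(40, 2.5, 0, 0.5, rise_time_constant = 0)
  expect_equal(aprv_pressure_waveform(injury, 1.0), 40)
  t <- seq(0, 4.4, by = 0.01)
  expect_identical(aprv_pressure_waveform(cd, t),
                   aprv_pressure_waveform(cd, t + (4 + 0.5)))
  # with a finite rise the waveform approaches the targets monotonically
  cds <- cd_settings(rise = 0.05)
  expect_lt(aprv_pressure_waveform(cds, 0.01), 23)
  expect_lt(abs(aprv_pressure_waveform(cds, 3.9) - 23), 1e-6)
  expect_equal(aprv_pressure_waveform(cds, t),
               aprv_pressure_waveform(cds, t + 4.5), tolerance = 1e-12)
})

test_that("flow solver inverts the quadratic resistance exactly", {
  expect_equal(solve_flow(0, 10, 5), 0)
  expect_equal(solve_flow(15, 10, 5), 1.0)
  expect_equal(solve_flow(-15, 10, 5), -1.0)
  expect_equal(solve_flow(3, 6, 0), 0.5)  # linear limit
  set.seed(21)
  for (i in 1:25) {
    r1 <- runif(1, 1, 20); r2 <- runif(1, 0.1, 10); d <- runif(1, -40, 40)
    q <- solve_flow(d, r1, r2)
    # bracketing root-finder on the residual as oracle
    oracle <- stats::uniroot(function(v) r2 * v * abs(v) + r1 * v - d,
                             c(-50, 50), tol = 1e-12)$root
    expect_lt(abs(q - oracle), 1e-9)
  }
})

test_that("recruitment update is an exact exponential relaxation", {
  m <- recruitment_model(enabled = TRUE, p_crit = 8, k = 2,
                         tau_open = 0.5, tau_close = 0.4, r_min = 0.5)
  r_eq <- function(p) m$r_min + (1 - m$r_min) / (1 + exp(-(p - m$p_crit) / m$k))
  # fixed point
  expect_equal(recruitment_update(r_eq(10), 10, m, 0.01), r_eq(10))
  # exact single-step decrement toward equilibrium
  r0 <- 0.9; p <- 3; dt <- 0.07
  expected <- r_eq(p) + (r0 - r_eq(p)) * exp(-dt / m$tau_close)
  expect_equal(recruitment_update(r0, p, m, dt), expected, tolerance = 1e-14)
  # saturation: sustained high pressure opens fully
  r <- 0.5
  for (i in 1:2000) r <- recruitment_update(r, 40, m, 0.01)
  expect_lt(abs(r - 1), 1e-6)
  # clamped at r_min
  r <- 0.5
  for (i in 1:2000) r <- recruitment_update(r, -20, m, 0.01)
  expect_gte(r, m$r_min)
})

test_that("simulation is bit-identical for a fixed seed", {
  cfg <- simulation_config(cd_settings(), lung = demo_lung(),
                           recruitment = demo_recruitment(),
                           n_cycles = 2, dt = 0.005,
                           noise_sd_pressure = 0.5, noise_sd_flow = 0.01,
                           seed = 77)
  a <- simulate_aprv(cfg)
  b <- simulate_aprv(cfg)
  expect_identical(a$pressure, b$pressure)
  expect_identical(a$flow, b$flow)
})

test_that("the simulated lung reaches a periodic steady state", {
  cfg <- simulation_config(cd_settings(), lung = demo_lung(),
                           n_cycles = 6, dt = 0.001)
  rec <- simulate_aprv(cfg)
  v <- rec$meta$true_volume
  cyc <- round(4.5 / 0.001)
  expect_lt(abs(v[5 * cyc + 1] - v[4 * cyc + 1]), 1e-6)
  # volume stays non-negative when p_low >= p0
  expect_gte(min(v), -1e-9)
})

test_that("halving the time step barely perturbs the output", {
  cfg1 <- simulation_config(cd_settings(), lung = demo_lung(),
                            n_cycles = 2, dt = 0.002)
  cfg2 <- simulation_config(cd_settings(), lung = demo_lung(),
                            n_cycles = 2, dt = 0.001)
  coarse <- simulate_aprv(cfg1)
  fine <- simulate_aprv(cfg2)
  i2 <- seq(1, length(fine), by = 2)
  expect_lt(max(abs(coarse$flow - fine$flow[i2])) / max(abs(fine$flow)), 1e-4)
  expect_lt(max(abs(coarse$meta$true_volume - fine$meta$true_volume[i2])) /
              max(fine$meta$true_volume), 1e-4)
})

test_that("estimation round-trips the configured parameters", {
  cfg <- simulation_config(cd_settings(), lung = test_lung(),
                           n_cycles = 6, dt = 0.001)
  est <- fit_pipeline(cfg, last = 2)
  truth <- c(8, 4, 25, 10, 5)
  expect_lt(max(abs(coef_vec(est) - truth) / truth), 1e-6)
})

test_that("re-integrating the recorded flow reproduces the simulator volume", {
  cfg <- simulation_config(cd_settings(), lung = demo_lung(),
                           recruitment = demo_recruitment(),
                           n_cycles = 2, dt = 0.002)
  rec <- simulate_aprv(cfg)
  rec <- integrate_volume(rec, reset_indices = 1)
  expect_lt(max(abs(rec$volume - rec$meta$true_volume)), 1e-12)
})

test_that("numerical blow-up raises an instability error", {
  cfg <- simulation_config(
    ventilator_settings(40, 4, 0, 0.5), n_cycles = 1, dt = 0.005,
    lung = lung_model(r1 = 0.5, r2 = 0, e1 = 0.01, e2 = 0, p0 = 0))
  expect_error(simulate_aprv(cfg), class = "aprv_instability")
})

test_that("breath coupling freezes mechanics within a cycle", {
  rm_b <- recruitment_model(enabled = TRUE, tau_open = 10, tau_close = 1,
                            coupling = "breath")
  cfg <- simulation_config(cd_settings(), lung = demo_lung(),
                           recruitment = rm_b, n_cycles = 2, dt = 0.005)
  rec <- simulate_aprv(cfg)
  # continuous recruitment state moves within the cycle...
  r <- rec$meta$recruited_fraction
  expect_gt(diff(range(r)), 0)
  # ...but the recorded samples of any single cycle satisfy one static
  # equation of motion exactly (fit one cycle -> rmse ~ 0)
  rec <- integrate_volume(rec, reset_indices = 1)
  seg <- segment_breaths(rec, cfg$settings)
  est <- fit_mechanics(rec, seg[2, , drop = FALSE])
  expect_lt(est$rmse, 1e-8)
})
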