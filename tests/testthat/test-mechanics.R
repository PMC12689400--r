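test_that("design matrix columns follow the equation of motion", {
  X <- build_design_matrix(flow = c(1, -2, 0, 1, 2),
                           volume = c(1, 0.5, 0, 0.2, 0.1))
  expect_equal(unname(X[1, ]), c(1, 1, 1, 1, 1))
  expect_equal(unname(X[2, ]), c(-2, -4, 0.5, 0.25, 1))
  expect_equal(unname(X[3, ]), c(0, 0, 0, 0, 1))
  expect_error(build_design_matrix(1:5, 1:4), class = "aprv_invalid_input")
  expect_error(build_design_matrix(1:3, 1:3), class = "aprv_invalid_input")
})

test_that("noiseless simulated cycles are recovered essentially exactly", {
  cfg <- simulation_config(cd_settings(rise = 0), lung = test_lung(),
                           n_cycles = 1, dt = 0.001)
  est <- fit_pipeline(cfg, last = 1)
  truth <- c(8, 4, 25, 10, 5)
  expect_lt(max(abs(coef_vec(est) - truth) / truth), 1e-8)
  expect_lt(abs(est$r_squared - 1), 1e-12)
  expect_lt(est$rmse, 1e-8)
})

test_that("fit matches an explicit normal-equations solve", {
  set.seed(11)
  for (i in 1:10) {
    cfg <- simulation_config(
      cd_settings(t_low = runif(1, 0.3, 1)),
      lung = lung_model(runif(1, 2, 20), runif(1, 0.5, 10),
                        runif(1, 10, 60), runif(1, 1, 40), runif(1, 0, 15)),
      n_cycles = 2, dt = 0.005, noise_sd_pressure = 0.5, seed = i)
    rec <- simulate_aprv(cfg)
    seg <- segment_breaths(rec, cfg$settings)
    rec <- integrate_volume(rec, reset_indices = 1)
    est <- suppressWarnings(fit_mechanics(rec, seg))
    oracle <- normal_equations_fit(rec$pressure, rec$flow, rec$volume)
    expect_lt(max(abs(coef_vec(est) - oracle) / pmax(abs(oracle), 1e-8)), 1e-10)
  }
})

test_that("adding a pressure offset shifts only P0", {
  cfg <- simulation_config(cd_settings(), lung = test_lung(),
                           n_cycles = 2, dt = 0.005)
  rec <- simulate_aprv(cfg)
  seg <- segment_breaths(rec, cfg$settings)
  rec <- integrate_volume(rec, reset_indices = 1)
  base <- fit_mechanics(rec, seg)
  rec$pressure <- rec$pressure + 3
  shifted <- fit_mechanics(rec, seg)
  expect_equal(shifted$p0, base$p0 + 3, tolerance = 1e-10)
  expect_lt(max(abs(coef_vec(shifted)[1:4] - coef_vec(base)[1:4])), 1e-10)
})

test_that("rank-deficient designs raise a descriptive error", {
  rec <- flat_record(n = 200, pressure = 5)
  rec$volume <- rep(0, 200)
  seg <- breath_segments(0, 100, 200, rec$sample_rate)
  err <- tryCatch(fit_mechanics(rec, seg), error = function(e) e)
  expect_s3_class(err, "aprv_rank_deficiency")
  expect_match(conditionMessage(err), "flow")
})

test_that("small sample counts warn and volume is required", {
  cfg <- simulation_config(cd_settings(), lung = test_lung(),
                           n_cycles = 1, dt = 0.005)
  rec <- simulate_aprv(cfg)
  seg <- segment_breaths(rec, cfg$settings)
  expect_error(fit_mechanics(rec, seg), class = "aprv_invalid_input")
  rec <- integrate_volume(rec, reset_indices = 1)
  tiny <- breath_segments(0, 10, 20, rec$sample_rate)
  expect_warning(try(fit_mechanics(rec, tiny), silent = TRUE),
                 class = "aprv_few_samples")
})

test_that("residual diagnostics satisfy the normal equations", {
  cfg <- simulation_config(cd_settings(), lung = test_lung(),
                           n_cycles = 2, dt = 0.005, noise_sd_pressure = 0.5,
                           seed = 3)
  rec <- simulate_aprv(cfg)
  seg <- segment_breaths(rec, cfg$settings)
  rec <- integrate_volume(rec, reset_indices = 1)
  est <- fit_mechanics(rec, seg)
  d <- fit_diagnostics(est, rec, seg)
  scale <- est$n_samples * max(abs(rec$pressure))
  expect_true(all(abs(d$orthogonality) < 1e-8 * scale))
  # perfect fit: residuals vanish
  cfg0 <- simulation_config(cd_settings(), lung = test_lung(),
                            n_cycles = 2, dt = 0.005)
  rec0 <- integrate_volume(simulate_aprv(cfg0), 1)
  seg0 <- segment_breaths(rec0, cfg0$settings)
  est0 <- fit_mechanics(rec0, seg0)
  expect_lt(fit_diagnostics(est0, rec0, seg0)$max_abs_residual, 1e-8)
})

test_that("rmse estimates the injected noise level", {
  # fixed design from one simulated record, 100 seeded noise draws
  cfg <- simulation_config(cd_settings(), lung = test_lung(),
                           n_cycles = 3, dt = 0.005)
  rec <- integrate_volume(simulate_aprv(cfg), 1)
  seg <- segment_breaths(rec, cfg$settings)
  idx <- 1:2400
  clean <- rec$pressure
  inside <- vapply(0:99, function(s) {
    set.seed(s)
    rec$pressure <- clean + stats::rnorm(length(clean))
    sub <- rec
    sub$time <- sub$time[idx]; sub$pressure <- sub$pressure[idx]
    sub$flow <- sub$flow[idx]; sub$volume <- sub$volume[idx]
    sub$phase <- sub$phase[idx]
    est <- fit_mechanics(sub, breath_segments(0, 1200, 2400, rec$sample_rate))
    est$rmse >= 0.9 && est$rmse <= 1.1
  }, logical(1))
  expect_gte(sum(inside), 95)
})

test_that("unit changes rescale the resistances exactly", {
  cfg <- simulation_config(cd_settings(), lung = test_lung(),
                           n_cycles = 2, dt = 0.005)
  rec <- integrate_volume(simulate_aprv(cfg), 1)
  seg <- segment_breaths(rec, cfg$settings)
  base <- fit_mechanics(rec, seg)
  rec_ml <- rec
  rec_ml$flow <- rec$flow * 1000  # mL/s
  ml <- fit_mechanics(rec_ml, seg)
  expect_equal(ml$r1, base$r1 * 1e-3, tolerance = 1e-10)
  expect_equal(ml$r2, base$r2 * 1e-6, tolerance = 1e-10)
  expect_equal(ml$e1, base$e1, tolerance = 1e-10)
})

test_that("noisy complete-exhalation cycles recover E2 within 10%", {
  rel <- vapply(1:30, function(s) {
    cfg <- simulation_config(cd_settings(t_low = 1.0), lung = demo_lung(),
                             n_cycles = 3, dt = 0.005,
                             noise_sd_pressure = 1, seed = s)
    abs(fit_pipeline(cfg)$e2 / 15 - 1)
  }, numeric(1))
  expect_lt(stats::median(rel), 0.10)
})
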