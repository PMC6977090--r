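test_that("effective_rate applies Q10 and drug scaling", {
  expect_identical(effective_rate(0.20, 37, 2.5, 1.0), 0.20)
  expect_equal(effective_rate(0.20, 27, 3.077, 1.0), 0.2 / 3.077,
               tolerance = 1e-12)
  expect_equal(effective_rate(0.20, 27, 3.077, 1.0), 0.065, tolerance = 1e-3)
  expect_identical(effective_rate(0.284, 37, 2.5, 0.0), 0)
  expect_error(effective_rate(0.2, 37, 0), class = "netrate_config_error")
  expect_error(effective_rate(0.2, 37, -1), class = "netrate_config_error")
})

test_that("Q10 ratio across a 10 degC step equals q10 exactly", {
  for (q10 in c(1.5, 2.5, 3.077)) for (T0 in c(37, 30, 25)) {
    r <- effective_rate(0.2, T0, q10) / effective_rate(0.2, T0 - 10, q10)
    expect_equal(r, q10, tolerance = 1e-12)
  }
})

test_that("terminal_intensity follows the phase-wise kinetic model", {
  # no uptake, no bleach: flat at baseline
  expect_equal(terminal_intensity(5, "control", 100), 100)
  expect_equal(terminal_intensity(9, "test", 100, uptake_rate = 0), 100)
  # linear uptake: +10 %/min for 5 min
  expect_equal(terminal_intensity(5, "test", 100, uptake_rate = 0.10,
                                  test_start = 0), 150)
  # geometric bleach decay: 10 prior exposures at 5 % each
  expect_equal(terminal_intensity(3, "control", 100, bleach_per_exposure = 0.05,
                                  exposures_so_far = 10), 100 * 0.95^10)
  # washout declines from its start value and floors at zero
  expect_equal(terminal_intensity(7, "washout", 100, uptake_rate = 0.5,
                                  washout_rate = -0.1, test_start = 0,
                                  washout_start = 6), 400 * 0.9)
  expect_equal(terminal_intensity(100, "washout", 100, washout_rate = -0.1,
                                  test_start = 0, washout_start = 0), 0)
  expect_error(terminal_intensity(1, "recovery", 100),
               class = "netrate_phase_error")
})

test_that("render_stack renders terminals at their positions", {
  blank <- small_config(n_terminals = 0)
  st <- render_stack(blank, 0)
  expect_true(all(st == 0))

  one <- small_config(n_terminals = 1)
  st <- render_stack(one, 0)
  expect_true(all(st >= 0))
  truth <- simulate_series(one)$truth
  peak <- which(st == max(st), arr.ind = TRUE)[1, ]
  expect_lt(abs(peak[1] - truth$slice), 1.01)
  expect_lt(abs(peak[2] - truth$row), 1.01)
  expect_lt(abs(peak[3] - truth$col), 1.01)

  expect_error(render_stack(one, 99), class = "netrate_config_error")
})

test_that("rendering is deterministic and non-negative under noise", {
  cfg <- small_config(noise_sd = 15, n_background_blobs = 2, seed = 3L)
  a <- render_stack(cfg, 3)
  b <- render_stack(cfg, 3)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  # different timepoints draw different noise
  expect_false(identical(render_stack(cfg, 3), render_stack(cfg, 4)))
})

test_that("control stacks are identical up to noise and series is reproducible", {
  cfg <- small_config(uptake_rate_mean = 0.2)
  sim <- simulate_series(cfg)
  ctrl <- which(sim$series$phases == "control")
  expect_identical(sim$series$stacks[[ctrl[1]]], sim$series$stacks[[ctrl[2]]])
  expect_identical(sim$series$stacks[[ctrl[1]]], sim$series$stacks[[ctrl[3]]])

  sim2 <- simulate_series(cfg)
  expect_identical(sim$series$stacks, sim2$series$stacks)
  expect_identical(sim$truth, sim2$truth)
})

test_that("per-exposure bleaching is strictly monotone when kinetics are flat", {
  cfg <- small_config(uptake_rate_mean = 0, bleach_per_exposure = 0.08)
  sim <- simulate_series(cfg)
  truth <- sim$truth
  roi <- terminal_roi(truth$row[1], truth$col[1], radius = 2.5,
                      reference_slice = round(truth$slice[1]),
                      terminal_id = 1L)
  tr <- measure_trace(sim$series, roi)
  expect_true(all(diff(tr$values) < 0))
  # matches the closed-form geometric decay up to rendering scale
  expect_equal(tr$values / tr$values[1],
               0.92^(seq_along(tr$values) - 1), tolerance = 1e-9)
})

test_that("without bleaching, dropping imaging events leaves intensities unchanged", {
  full <- small_config(schedule = sim_schedule(c(0, 1, 2), 3:10),
                       uptake_rate_mean = 0.15)
  reduced <- small_config(schedule = sim_schedule(c(0, 1, 2), c(3, 4, 10)),
                          uptake_rate_mean = 0.15)
  s_full <- simulate_series(full)$series
  s_red <- simulate_series(reduced)$series
  for (t0 in c(3, 4, 10)) {
    i <- which(s_full$times == t0); j <- which(s_red$times == t0)
    expect_equal(s_full$stacks[[i]], s_red$stacks[[j]], tolerance = 1e-12)
  }
})

test_that("with bleaching, a reduced schedule preserves more signal at endpoint", {
  mk <- function(test_times) small_config(
    schedule = sim_schedule(c(0, 1, 2), test_times),
    uptake_rate_mean = 0.10, bleach_per_exposure = 0.16)
  s_const <- simulate_series(mk(3:17))
  s_red <- simulate_series(mk(c(3, 4, 5, 17)))
  truth <- s_const$truth
  roi <- terminal_roi(truth$row[1], truth$col[1], radius = 2.5,
                      reference_slice = round(truth$slice[1]))
  v_const <- measure_trace(s_const$series, roi)$values
  v_red <- measure_trace(s_red$series, roi)$values
  expect_gt(tail(v_red, 1), tail(v_const, 1))
})

test_that("moment-matched rate draws hit the configured mean and SD exactly", {
  cfg <- small_config(n_terminals = 12, uptake_rate_mean = 0.2,
                      uptake_rate_sd = 0.05, washout_rate = -0.121,
                      washout_rate_sd = 0.03, standardize_rates = TRUE,
                      image_shape = c(6, 128, 128), seed = 42L)
  truth <- simulate_series(cfg)$truth
  expect_equal(mean(truth$true_uptake_rate), 0.2, tolerance = 1e-12)
  expect_equal(sd(truth$true_uptake_rate), 0.05, tolerance = 1e-12)
  expect_equal(mean(truth$true_washout_rate), -0.121, tolerance = 1e-12)
  # draws are still heterogeneous, not constant
  expect_gt(diff(range(truth$true_uptake_rate)), 0.01)
  # temperature/drug scaling applies after matching, scaling the mean exactly
  cfg2 <- small_config(n_terminals = 12, uptake_rate_mean = 0.2,
                       uptake_rate_sd = 0.05, standardize_rates = TRUE,
                       temperature_c = 27, q10 = 2.5,
                       image_shape = c(6, 128, 128), seed = 42L)
  truth2 <- simulate_series(cfg2)$truth
  expect_equal(mean(truth2$true_uptake_rate), 0.2 / 2.5, tolerance = 1e-12)
})

test_that("config validation rejects malformed schedules and parameters", {
  expect_error(sim_schedule(c(0, 2, 1), 3:4), class = "netrate_config_error")
  expect_error(small_config(q10 = -1), class = "netrate_config_error")
  expect_error(small_config(bleach_per_exposure = 1.2),
               class = "netrate_config_error")
  expect_error(small_config(image_shape = c(4, 20, 20), n_terminals = 3),
               class = "netrate_config_error")
  # phases out of protocol order
  bad <- data.frame(time_min = c(0, 1, 2), phase = c("test", "control", "test"))
  expect_error(small_config(schedule = bad), class = "netrate_config_error")
})
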