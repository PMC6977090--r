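test_that("normalisation divides by the mean control baseline", {
  tr <- make_trace(0:3, c(10, 10, 10, 15), c(rep("control", 3), "test"))
  nt <- normalize_trace(tr)
  expect_equal(nt$baseline, 10)
  expect_equal(nt$dF, 0.5)
  # identity: a test value equal to baseline gives dF = 0
  tr2 <- make_trace(0:3, c(10, 10, 10, 10), c(rep("control", 3), "test"))
  expect_equal(normalize_trace(tr2)$dF, 0)
  # complete loss of the terminal: raw 0 maps to the -1 floor
  tr3 <- make_trace(0:3, c(10, 10, 10, 0), c(rep("control", 3), "washout"))
  expect_equal(normalize_trace(tr3)$dF, -1)
})

test_that("degenerate baselines are rejected with a classed condition", {
  tr <- make_trace(0:3, c(0, 0, 0, 5), c(rep("control", 3), "test"))
  expect_error(normalize_trace(tr), class = "netrate_degenerate_baseline")
  tr2 <- make_trace(0:1, c(5, 6), c("test", "test"))
  expect_error(normalize_trace(tr2), class = "netrate_format_error")
})

test_that("dF floor: non-negative raw traces never fall below -1", {
  set.seed(31)
  for (i in 1:50) {
    v <- abs(rnorm(8, 10, 8))
    tr <- make_trace(0:7, v, c(rep("control", 3), rep("test", 5)))
    nt <- tryCatch(normalize_trace(tr),
                   netrate_degenerate_baseline = function(e) NULL)
    if (!is.null(nt)) expect_true(all(nt$dF >= -1))
  }
})

test_that("uptake slope reproduces exactly linear normalised points", {
  nt <- make_ntrace(0:3, c(0, 0.072, 0.144, 0.216))
  fit <- fit_uptake_rate(nt)
  expect_equal(fit$slope, 7.2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 4L)

  flat <- fit_uptake_rate(make_ntrace(0:4, rep(0.3, 5)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 1)

  expect_error(fit_uptake_rate(make_ntrace(0, 0.1)),
               class = "netrate_fit_error")
  expect_error(fit_uptake_rate(make_ntrace(0:5, (0:5) / 10),
                               window = c(10, 20)),
               class = "netrate_fit_error")
})

test_that("automatic window takes the longest linear prefix (R^2 >= 0.95)", {
  # linear for five points, then a hard plateau
  times <- 0:7
  dF <- c(0, 0.1, 0.2, 0.3, 0.4, 0.42, 0.42, 0.42)
  fit <- fit_uptake_rate(make_ntrace(times, dF))
  # independently find the expected prefix with the closed-form slope
  r2_of <- function(k) {
    t <- times[1:k]; y <- dF[1:k]
    b <- oracle_slope(t, y); a <- mean(y) - b * mean(t)
    1 - sum((y - a - b * t)^2) / sum((y - mean(y))^2)
  }
  ks <- seq(length(times), 3)
  expected_k <- ks[which(vapply(ks, r2_of, 0) >= 0.95)[1]]
  expect_equal(fit$n_points, expected_k)
  expect_lt(fit$window[2], 7)
  expect_equal(fit$slope, 100 * oracle_slope(times[1:expected_k],
                                             dF[1:expected_k]),
               tolerance = 1e-9)
  # an explicit window overrides the rule
  fit2 <- fit_uptake_rate(make_ntrace(times, dF), window = c(0, 7))
  expect_equal(fit2$n_points, 8L)
})

test_that("washout slope is the OLS gradient over the requested interval", {
  nt <- make_ntrace(c(0, 5), c(1.0, 0.395), phases = rep("washout", 2))
  expect_equal(fit_washout_rate(nt)$slope, -12.1, tolerance = 1e-9)
  flat <- make_ntrace(c(0, 5, 10), rep(0.4, 3), phases = rep("washout", 3))
  expect_equal(fit_washout_rate(flat)$slope, 0)
  expect_error(fit_washout_rate(nt, interval = c(0, 1)),
               class = "netrate_fit_error")
})

test_that("net_rate objects behave like small fitted models", {
  nt <- make_ntrace(0:5, 0.05 * (0:5) + c(0, 0.01, -0.01, 0, 0.01, -0.01))
  fit <- fit_uptake_rate(nt, window = c(0, 5))
  expect_named(coef(fit), c("intercept", "slope"))
  expect_equal(unname(coef(fit)["slope"]), fit$slope)
  expect_length(predict(fit, newdata = c(0, 10)), 2L)
  expect_equal(predict(fit, newdata = 10) - predict(fit, newdata = 0),
               10 * fit$slope / 100)
  expect_equal(fitted(fit) + residuals(fit), nt$dF, tolerance = 1e-12)
  expect_output(print(fit), "%/min")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})

test_that("noiseless end-to-end recovery matches configured kinetics to 1e-6", {
  cfg <- small_config(uptake_rate_mean = 0.284, noise_sd = 0,
                      n_background_blobs = 0)
  sim <- simulate_series(cfg)
  roi <- terminal_roi(sim$truth$row[1], sim$truth$col[1], radius = 2.5,
                      reference_slice = round(sim$truth$slice[1]))
  nt <- normalize_trace(measure_trace(sim$series, roi))
  fit <- fit_uptake_rate(nt)
  expect_equal(fit$slope, 28.4, tolerance = 1e-6)

  # washout: no uptake during the test phase, pure tyramine-style efflux;
  # imaged minute-by-minute so the decline is sampled before the -1 floor
  cfgw <- small_config(uptake_rate_mean = 0, washout_rate = -0.264,
                       noise_sd = 0, n_background_blobs = 0,
                       schedule = sim_schedule(c(0, 1, 2), 3:8, 9:11))
  simw <- simulate_series(cfgw)
  roiw <- terminal_roi(simw$truth$row[1], simw$truth$col[1], radius = 2.5,
                       reference_slice = round(simw$truth$slice[1]))
  ntw <- normalize_trace(measure_trace(simw$series, roiw))
  fw <- fit_washout_rate(ntw, interval = c(9, 11))
  expect_equal(fw$slope, -26.4, tolerance = 1e-6)
})

test_that("kinetic estimates are invariant to the raw intensity scale", {
  set.seed(41)
  for (k in c(0.05, 3, 117)) {
    v <- c(100, 101, 99, 110, 121, 128, 141)
    ph <- c(rep("control", 3), rep("test", 4))
    f1 <- fit_uptake_rate(normalize_trace(make_trace(0:6, v, ph)))
    f2 <- fit_uptake_rate(normalize_trace(make_trace(0:6, k * v, ph)))
    expect_equal(f1$slope, f2$slope, tolerance = 1e-9)
    expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-9)
  }
})

test_that("slope estimation is unbiased under Gaussian noise", {
  set.seed(52)
  m <- 0.15; slopes <- numeric(200)
  for (i in 1:200) {
    raw <- 100 * (1 + m * (0:6)) + rnorm(7, 0, 5)
    tr <- make_trace(c(-2, -1, 0, 0:6 + 1), c(100 + rnorm(3, 0, 5), raw),
                     c(rep("control", 3), rep("test", 7)))
    slopes[i] <- fit_uptake_rate(normalize_trace(tr),
                                 window = c(1, 7))$slope
  }
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 100 * m), 3 * se)
})

test_that("percent excess, fold change and error combination agree with closed forms", {
  expect_equal(percent_excess(6.5, 4.0), 62.5)
  expect_equal(percent_excess(20.0, 11.8), 69.4915, tolerance = 1e-4)
  expect_equal(percent_excess(5, 5), 0)
  expect_equal(percent_excess(-26.4, -12.1, denominator = "a"), 54.1667,
               tolerance = 1e-4)
  expect_error(percent_excess(1, 0), class = "netrate_value_error")

  expect_equal(fold_change(20.0, 6.5), 3.0769, tolerance = 1e-4)
  expect_equal(fold_change(7, 7), 1)
  expect_error(fold_change(1, 0), class = "netrate_value_error")

  # percent_excess = 100 * (fold_change - 1), for any pair
  set.seed(61)
  for (i in 1:20) {
    a <- rnorm(1, 10, 5); b <- rnorm(1, 10, 5)
    if (abs(b) < 0.1) next
    expect_equal(percent_excess(a, b), 100 * (fold_change(a, b) - 1),
                 tolerance = 1e-9)
  }

  expect_equal(combine_relative_errors(c(1, 1), c(0.03, 0.04)), 0.05)
  expect_equal(combine_relative_errors(7, 0), 0)
  expect_equal(combine_relative_errors(c(6.5, 4.0), c(0.6, 0.3)), 0.118936,
               tolerance = 1e-5)
  expect_error(combine_relative_errors(c(0, 1), c(0.1, 0.1)),
               class = "netrate_value_error")
})

test_that("schedule_delta reads endpoint differences off the trace", {
  nt <- make_ntrace(c(6, 8, 20), c(0.4, 0.41, 0.15))
  expect_equal(schedule_delta(nt, 6, 20), -0.25)
  expect_equal(schedule_delta(nt, 6, 6), 0)
  expect_error(schedule_delta(nt, 6, 21), class = "netrate_value_error")
})
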