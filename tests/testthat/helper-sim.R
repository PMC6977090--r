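# Shared fixture builders. All fixtures are generated in code at test time;
# the default is a small noiseless field so kinetic recovery is exact.

small_config <- function(...) {
  args <- list(
    image_shape = c(6, 64, 64), n_terminals = 2, terminal_radius = 2.5,
    intervaricose_spacing = 10, n_background_blobs = 0,
    baseline_intensity = 100, uptake_rate_mean = 0.1, uptake_rate_sd = 0,
    washout_rate = -0.1, washout_rate_sd = 0, bleach_per_exposure = 0,
    noise_sd = 0, psf_sigma = 0.8, schedule = sim_schedule(c(0, 1, 2), 3:8),
    seed = 11L)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# norm_trace built directly from dF values (unit tests of the fitting layer)
make_ntrace <- function(times, dF, phases = rep("test", length(times)),
                        baseline = 100, id = 1L) {
  structure(list(terminal_id = id, times = times, dF = dF, phases = phases,
                 baseline = baseline, n_control = 3L),
            class = "norm_trace")
}

# fluor_trace built directly from raw values
make_trace <- function(times, values, phases, id = 1L) {
  structure(list(terminal_id = id, times = times, values = values,
                 phases = phases), class = "fluor_trace")
}

# closed-form OLS slope, independent of the package's fitting path
oracle_slope <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}
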