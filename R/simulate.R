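#' Imaging schedule for a simulated experiment
#'
#' Builds the per-timepoint acquisition schedule: times (minutes, strictly
#' increasing) and experimental phase labels. Phases must appear in protocol
#' order: control stacks first (dilute pre-label), then the test period
#' (concentrated substrate), then an optional washout.
#'
#' @param control_times,test_times,washout_times numeric vectors of
#'   acquisition times in minutes. `washout_times` may be empty.
#' @return a data.frame with columns `time_min` and `phase`.
#' @examples
#' sim_schedule(0:2, 3:9)                 # 3 control stacks, 1-min test imaging
#' sim_schedule(0:2, 3:8, c(9, 14, 19))   # with 5-min washout intervals
#' @export
sim_schedule <- function(control_times = c(0, 1, 2),
                         test_times = 3:9,
                         washout_times = numeric(0)) {
  df <- data.frame(
    time_min = c(control_times, test_times, washout_times),
    phase = rep(PHASES, times = c(length(control_times), length(test_times),
                                  length(washout_times))),
    stringsAsFactors = FALSE
  )
  if (nrow(df) == 0L)
    stop_netrate("schedule must contain at least one imaging event",
                 "netrate_config_error")
  if (any(diff(df$time_min) <= 0))
    stop_netrate("schedule times must be strictly increasing",
                 "netrate_config_error")
  df
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic confocal time-lapse generator and
#' validates it. Defaults emulate the reference acquisition protocol:
#' ~15 slices at 1 um spacing, 512 x 512 px fields of sparse varicose
#' terminals, three control stacks followed by one-minute test imaging, an
#' intra-terminal baseline of 100 a.u. after dilute pre-label, and an uptake
#' rate drawn per terminal around 0.284 of baseline per minute (28.4 %/min,
#' the fastest printed control condition) with the between-terminal spread
#' implied by its SEM at n_t = 24.
#'
#' @param image_shape integer (slices, height, width) in px.
#' @param voxel_size numeric (z, y, x) voxel size in um.
#' @param n_terminals number of varicosities to place.
#' @param terminal_radius apparent terminal radius, px (Gaussian spot sigma is
#'   `terminal_radius / 2` before PSF widening).
#' @param intervaricose_spacing spacing between beads along an axon path, px.
#' @param n_background_blobs count of dim, diffuse non-neuronal blobs.
#' @param background_intensity brightness of non-neuronal blobs relative to
#'   `baseline_intensity`; a free parameter (default 0.3), as non-neuronal
#'   fluorescence is only qualitatively characterised in real preparations.
#' @param baseline_intensity mean intra-terminal intensity during the control
#'   phase, arbitrary units.
#' @param uptake_rate_mean,uptake_rate_sd per-terminal uptake slope
#'   distribution, fraction of baseline per minute (0.284 = 28.4 %/min).
#' @param washout_rate,washout_rate_sd per-terminal washout slope
#'   distribution, fraction of the washout-start value per minute (negative
#'   for decline).
#' @param bleach_per_exposure fraction of signal lost per imaging event
#'   (photobleaching is exposure-driven, not time-driven).
#' @param q10 temperature coefficient (fold rate change per 10 degC); must be
#'   positive.
#' @param temperature_c bath temperature, degC; reference is 37 degC.
#' @param rate_multiplier unitless drug scaling of the uptake rate (0 for a
#'   full transporter block, <1 for partial inhibition).
#' @param standardize_rates if `TRUE`, the per-terminal uptake and washout
#'   draws are affinely rescaled so the realized sample mean and SD equal the
#'   configured values exactly (moment matching). Useful when emulating a
#'   cohort whose summary statistics are known; the default (`FALSE`) draws
#'   i.i.d. normal rates.
#' @param noise_sd additive Gaussian detector noise, a.u.
#' @param poisson_noise also apply Poisson (photon) resampling of the signal.
#' @param psf_sigma lateral PSF sigma, px; widens every rendered blob.
#' @param schedule acquisition schedule from [sim_schedule()].
#' @param seed mandatory integer seed; identical config + seed gives
#'   bit-identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(image_shape = c(15, 512, 512),
                       voxel_size = c(1, 0.41, 0.41),
                       n_terminals = 6,
                       terminal_radius = 3,
                       intervaricose_spacing = 14,
                       n_background_blobs = 4,
                       background_intensity = 0.3,
                       baseline_intensity = 100,
                       uptake_rate_mean = 0.284,
                       uptake_rate_sd = 0.201,
                       washout_rate = -0.121,
                       washout_rate_sd = 0.083,
                       standardize_rates = FALSE,
                       bleach_per_exposure = 0,
                       q10 = 2.5,
                       temperature_c = 37,
                       rate_multiplier = 1,
                       noise_sd = 10,
                       poisson_noise = FALSE,
                       psf_sigma = 1,
                       schedule = sim_schedule(),
                       seed = 1L) {
  cfg <- structure(
    list(image_shape = as.integer(image_shape), voxel_size = voxel_size,
         n_terminals = as.integer(n_terminals),
         terminal_radius = terminal_radius,
         intervaricose_spacing = intervaricose_spacing,
         n_background_blobs = as.integer(n_background_blobs),
         background_intensity = background_intensity,
         baseline_intensity = baseline_intensity,
         uptake_rate_mean = uptake_rate_mean,
         uptake_rate_sd = uptake_rate_sd,
         washout_rate = washout_rate, washout_rate_sd = washout_rate_sd,
         standardize_rates = isTRUE(standardize_rates),
         bleach_per_exposure = bleach_per_exposure,
         q10 = q10, temperature_c = temperature_c,
         rate_multiplier = rate_multiplier,
         noise_sd = noise_sd, poisson_noise = isTRUE(poisson_noise),
         psf_sigma = psf_sigma, schedule = schedule, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (length(cfg$image_shape) != 3L || any(cfg$image_shape < 1L))
    stop_netrate("image_shape must be (slices, height, width), all >= 1",
                 "netrate_config_error")
  if (cfg$q10 <= 0)
    stop_netrate("q10 must be positive", "netrate_config_error")
  if (cfg$baseline_intensity <= 0)
    stop_netrate("baseline_intensity must be positive", "netrate_config_error")
  if (cfg$bleach_per_exposure < 0 || cfg$bleach_per_exposure >= 1)
    stop_netrate("bleach_per_exposure must be in [0, 1)",
                 "netrate_config_error")
  if (cfg$n_terminals < 0L || cfg$n_background_blobs < 0L)
    stop_netrate("object counts must be non-negative", "netrate_config_error")
  sch <- cfg$schedule
  if (!all(c("time_min", "phase") %in% names(sch)) || nrow(sch) == 0L)
    stop_netrate("schedule must be a non-empty data.frame with time_min and phase",
                 "netrate_config_error")
  if (any(diff(sch$time_min) <= 0))
    stop_netrate("schedule times must be strictly increasing",
                 "netrate_config_error")
  if (!all(sch$phase %in% PHASES))
    stop_netrate("schedule phases must be control/test/washout",
                 "netrate_config_error")
  ord <- match(sch$phase, PHASES)
  if (any(diff(ord) < 0))
    stop_netrate("phases must appear in order control -> test -> washout",
                 "netrate_config_error")
  if (cfg$n_terminals > 0L) {
    margin <- detection_margin(cfg)
    if (cfg$image_shape[2] <= 2 * margin || cfg$image_shape[3] <= 2 * margin)
      stop_netrate(
        sprintf("image too small to place terminals with a %d px margin",
                margin), "netrate_config_error")
  }
  cfg
}

# lateral margin keeping a terminal's ROI + background annulus in bounds
detection_margin <- function(cfg) as.integer(ceiling(cfg$terminal_radius) + 9L)

#' @export
print.sim_config <- function(x, ...) {
  sch <- x$schedule
  cat("<sim_config> ", paste(x$image_shape, collapse = " x "),
      " px, ", x$n_terminals, " terminals\n", sep = "")
  cat("  schedule: ", sum(sch$phase == "control"), " control / ",
      sum(sch$phase == "test"), " test / ",
      sum(sch$phase == "washout"), " washout events over [",
      min(sch$time_min), ", ", max(sch$time_min), "] min\n", sep = "")
  cat(sprintf("  uptake %.3f +/- %.3f /min, washout %.3f /min, bleach %.3f/exposure\n",
              x$uptake_rate_mean, x$uptake_rate_sd, x$washout_rate,
              x$bleach_per_exposure))
  cat(sprintf("  T = %g degC (Q10 %g), rate multiplier %g, noise sd %g, seed %d\n",
              x$temperature_c, x$q10, x$rate_multiplier, x$noise_sd, x$seed))
  invisible(x)
}

#' Temperature- and drug-scaled transport rate
#'
#' Applies the Q10 temperature model and a drug multiplier to a base uptake
#' rate: `rate = base * multiplier * q10^((T - 37) / 10)`. The reference
#' temperature is fixed at 37 degC (the physiological upper bound), so the
#' rate at 37 degC is the base rate; cooling by 10 degC divides the rate by
#' exactly `q10`, the classic signature of carrier-mediated (rather than
#' passive) transport.
#'
#' @param base_rate transport rate at 37 degC, fraction of baseline per min.
#' @param temperature_c bath temperature, degC.
#' @param q10 temperature coefficient; must be positive.
#' @param rate_multiplier unitless drug scaling (0 = complete block).
#' @return scaled rate, fraction of baseline per minute. Vectorised.
#' @examples
#' effective_rate(0.20, 37, 2.5)            # identity at reference T
#' effective_rate(0.20, 27, 3.077)          # ~0.065: threefold slowing
#' effective_rate(0.284, 37, 2.5, rate_multiplier = 0)  # full block
#' @export
effective_rate <- function(base_rate, temperature_c, q10, rate_multiplier = 1) {
  if (any(!is.finite(q10)) || any(q10 <= 0))
    stop_netrate("q10 must be positive", "netrate_config_error")
  base_rate * rate_multiplier * q10^((temperature_c - 37) / 10)
}

#' Intra-terminal intensity under the phase-wise kinetic model
#'
#' The generator's per-terminal forward model. During the control phase the
#' intensity sits at `baseline`; during the test phase it rises linearly,
#' `baseline * (1 + m * (t - test_start))`; during washout it declines
#' linearly from its value at washout start,
#' `F_w * (1 + w * (t - washout_start))`, floored at zero (complete loss of
#' the terminal corresponds to a normalised value of -1). Each imaging event
#' bleaches the fluorophore by a fixed fraction, applied as
#' `(1 - bleach_per_exposure)^exposures_so_far` — bleaching is driven by
#' exposure count, not elapsed time, so unimaged intervals lose no signal.
#'
#' @param t time, minutes.
#' @param phase one of "control", "test", "washout".
#' @param baseline control-phase intensity, a.u. (> 0).
#' @param uptake_rate linear uptake slope m, fraction of baseline per minute.
#' @param washout_rate washout slope w, fraction of the washout-start value
#'   per minute (negative for decline).
#' @param test_start,washout_start phase onset times, minutes.
#' @param bleach_per_exposure fraction lost per imaging event.
#' @param exposures_so_far number of prior imaging events.
#' @return intensity in a.u., never negative. Vectorised over the kinetic
#'   parameters (one value per terminal).
#' @export
terminal_intensity <- function(t, phase, baseline, uptake_rate = 0,
                               washout_rate = 0, test_start = 0,
                               washout_start = NA_real_,
                               bleach_per_exposure = 0,
                               exposures_so_far = 0) {
  if (!phase %in% PHASES)
    stop_netrate(sprintf("unknown phase label '%s'", phase),
                 "netrate_phase_error")
  f <- switch(phase,
    control = baseline + 0 * uptake_rate,
    test = baseline * (1 + uptake_rate * (t - test_start)),
    washout = {
      if (is.na(washout_start))
        stop_netrate("washout phase requires washout_start",
                     "netrate_phase_error")
      f_w <- baseline * pmax(0, 1 + uptake_rate * (washout_start - test_start))
      f_w * (1 + washout_rate * (t - washout_start))
    })
  pmax(0, f) * (1 - bleach_per_exposure)^exposures_so_far
}

# Ground truth: terminal geometry ("beads on a string"), per-terminal kinetic
# draws, and static background blobs. Deterministic under cfg$seed; called
# identically by render_stack() and simulate_series() so standalone renders
# match series stacks voxel for voxel.
sim_truth <- function(cfg) {
  draw_rates <- function(n, mu, sigma) {
    x <- rnorm(n, mu, sigma)
    if (cfg$standardize_rates && n >= 2L && sigma > 0)
      x <- mu + sigma * (x - mean(x)) / sd(x)
    x
  }
  with_seed(cfg$seed, {
    terms <- place_terminals(cfg)
    base <- draw_rates(cfg$n_terminals, cfg$uptake_rate_mean,
                       cfg$uptake_rate_sd)
    rate <- effective_rate(base, cfg$temperature_c, cfg$q10,
                           cfg$rate_multiplier)
    wash <- draw_rates(cfg$n_terminals, cfg$washout_rate,
                       cfg$washout_rate_sd)
    blobs <- if (cfg$n_background_blobs > 0L) {
      data.frame(
        slice = runif(cfg$n_background_blobs, 1, cfg$image_shape[1]),
        row = runif(cfg$n_background_blobs, 1, cfg$image_shape[2]),
        col = runif(cfg$n_background_blobs, 1, cfg$image_shape[3]))
    } else {
      data.frame(slice = numeric(0), row = numeric(0), col = numeric(0))
    }
    truth <- data.frame(
      terminal_id = seq_len(cfg$n_terminals),
      slice = terms$slice, row = terms$row, col = terms$col,
      true_uptake_rate = rate, true_washout_rate = wash)
    list(terminals = truth, blobs = blobs)
  })
}

# Varicosities along smooth random axon paths: a start point, a heading with
# small cumulative curvature, beads every intervaricose_spacing px, z drifting
# gently between slices. Paths falling outside the placeable area are redrawn.
place_terminals <- function(cfg, beads_per_path = 4L) {
  n <- cfg$n_terminals
  if (n == 0L)
    return(data.frame(slice = numeric(0), row = numeric(0), col = numeric(0)))
  margin <- detection_margin(cfg)
  nz <- cfg$image_shape[1]; nr <- cfg$image_shape[2]; nc <- cfg$image_shape[3]
  sl <- rw <- cl <- numeric(0)
  tries <- 0L
  while (length(rw) < n) {
    tries <- tries + 1L
    if (tries > 500L)
      stop_netrate("could not place terminals inside the image; enlarge the field or reduce n_terminals",
                   "netrate_config_error")
    k <- min(beads_per_path, n - length(rw))
    r0 <- runif(1, margin + 1, nr - margin)
    c0 <- runif(1, margin + 1, nc - margin)
    theta <- runif(1, 0, 2 * pi) + cumsum(c(0, rnorm(k - 1, 0, 0.25)))
    step <- cfg$intervaricose_spacing
    rr <- r0 + c(0, cumsum(sin(theta[-k]) * step))
    cc <- c0 + c(0, cumsum(cos(theta[-k]) * step))
    z0 <- runif(1, 1.5, max(1.5, nz - 0.5))
    zz <- pmin(nz, pmax(1, z0 + cumsum(c(0, rnorm(k - 1, 0, 0.4)))))
    ok <- rr > margin & rr <= nr - margin & cc > margin & cc <= nc - margin
    # separation from already-placed beads so ROIs do not overlap
    if (length(rw) && any(ok)) {
      d2 <- outer(rr, rw, "-")^2 + outer(cc, cl, "-")^2
      ok <- ok & apply(d2, 1, min) > (2 * cfg$terminal_radius + 2)^2
    }
    if (!all(ok)) next
    sl <- c(sl, zz); rw <- c(rw, rr); cl <- c(cl, cc)
  }
  data.frame(slice = sl[1:n], row = rw[1:n], col = cl[1:n])
}

# additive Gaussian blob, peak-normalised: voxel at the exact centre = amp
add_blob <- function(canvas, centre, amp, sigma_lat, sigma_z) {
  dims <- dim(canvas)
  hw <- ceiling(3 * sigma_lat)
  hz <- ceiling(3 * sigma_z)
  zi <- max(1, floor(centre[1] - hz)):min(dims[1], ceiling(centre[1] + hz))
  ri <- max(1, floor(centre[2] - hw)):min(dims[2], ceiling(centre[2] + hw))
  ci <- max(1, floor(centre[3] - hw)):min(dims[3], ceiling(centre[3] + hw))
  gz <- exp(-(zi - centre[1])^2 / (2 * sigma_z^2))
  gr <- exp(-(ri - centre[2])^2 / (2 * sigma_lat^2))
  gc <- exp(-(ci - centre[3])^2 / (2 * sigma_lat^2))
  patch <- amp * outer(gz, outer(gr, gc))
  canvas[zi, ri, ci] <- canvas[zi, ri, ci] + patch
  canvas
}

#' Render one synthetic z-stack
#'
#' Renders the field at schedule time `t`: each terminal is a Gaussian spot at
#' its 3-D position with its current kinetic intensity, plus dim diffuse
#' non-neuronal background blobs. The Gaussian PSF is folded analytically into
#' every blob (a Gaussian object convolved with a Gaussian PSF is a Gaussian
#' with summed variances), then detector noise is added and the stack clipped
#' at zero. Deterministic for a fixed config seed and `t`.
#'
#' @param config a [sim_config()].
#' @param t acquisition time, minutes; must be a schedule event.
#' @param exposures_so_far number of prior imaging events; defaults to the
#'   event's position in the schedule.
#' @param truth precomputed ground truth (internal reuse).
#' @return a 3-D array (slice, row, col) of intensities, all >= 0.
#' @export
render_stack <- function(config, t, exposures_so_far = NULL, truth = NULL) {
  cfg <- validate_sim_config(config)
  idx <- which(abs(cfg$schedule$time_min - t) < 1e-9)
  if (length(idx) != 1L)
    stop_netrate(sprintf("t = %g min is not a schedule event", t),
                 "netrate_config_error")
  exposures_so_far <- exposures_so_far %||% (idx - 1L)
  truth <- truth %||% sim_truth(cfg)
  phase <- cfg$schedule$phase[idx]
  test_start <- if (any(cfg$schedule$phase == "test"))
    min(cfg$schedule$time_min[cfg$schedule$phase == "test"]) else 0
  washout_start <- if (any(cfg$schedule$phase == "washout"))
    min(cfg$schedule$time_min[cfg$schedule$phase == "washout"]) else NA_real_

  canvas <- array(0, dim = cfg$image_shape)
  bleach <- (1 - cfg$bleach_per_exposure)^exposures_so_far
  tt <- truth$terminals
  if (nrow(tt)) {
    amp <- terminal_intensity(
      t, phase, cfg$baseline_intensity,
      uptake_rate = tt$true_uptake_rate, washout_rate = tt$true_washout_rate,
      test_start = test_start, washout_start = washout_start,
      bleach_per_exposure = cfg$bleach_per_exposure,
      exposures_so_far = exposures_so_far)
    s_lat <- sqrt((cfg$terminal_radius / 2)^2 + cfg$psf_sigma^2)
    s_z <- sqrt(1 + cfg$psf_sigma^2)
    for (i in seq_len(nrow(tt)))
      canvas <- add_blob(canvas, c(tt$slice[i], tt$row[i], tt$col[i]),
                         amp[i], s_lat, s_z)
  }
  bb <- truth$blobs
  if (nrow(bb)) {
    # non-neuronal fluorescence: broad, dim, static apart from bleaching
    amp_bg <- cfg$background_intensity * cfg$baseline_intensity * bleach
    s_bg <- sqrt(10^2 + cfg$psf_sigma^2)
    for (i in seq_len(nrow(bb)))
      canvas <- add_blob(canvas, c(bb$slice[i], bb$row[i], bb$col[i]),
                         amp_bg, s_bg, 3)
  }
  if (cfg$poisson_noise || cfg$noise_sd > 0) {
    canvas <- with_seed(cfg$seed + 100003L + idx, {
      v <- as.numeric(canvas)
      if (cfg$poisson_noise) v <- rpois(length(v), pmax(0, v))
      if (cfg$noise_sd > 0) v <- v + rnorm(length(v), 0, cfg$noise_sd)
      array(v, dim = cfg$image_shape)
    })
  }
  canvas[canvas < 0] <- 0
  canvas
}

#' Simulate a full acquisition run with ground truth
#'
#' Renders one z-stack per schedule event, applying photobleaching per imaging
#' event only (events absent from the schedule incur no bleach, so a
#' reduced-illumination schedule preserves signal), and returns the stack
#' series together with a ground-truth sidecar: per-terminal positions, the
#' temperature-/drug-scaled true uptake rate, the true washout rate, and the
#' per-event bleach factors.
#'
#' @param config a [sim_config()].
#' @return a list with elements `series` (a [stack_series()]) and `truth`
#'   (data.frame of per-terminal ground truth; the per-event bleach factors
#'   and the config are attached as attributes).
#' @examples
#' cfg <- sim_config(image_shape = c(6, 64, 64), n_terminals = 2,
#'                   noise_sd = 0, n_background_blobs = 0, seed = 7)
#' sim <- simulate_series(cfg)
#' sim$truth
#' @export
simulate_series <- function(config) {
  cfg <- validate_sim_config(config)
  truth <- sim_truth(cfg)
  stacks <- lapply(seq_len(nrow(cfg$schedule)), function(i)
    render_stack(cfg, cfg$schedule$time_min[i], exposures_so_far = i - 1L,
                 truth = truth))
  series <- stack_series(stacks, cfg$schedule$time_min, cfg$schedule$phase,
                         voxel_size = cfg$voxel_size)
  out <- truth$terminals
  attr(out, "bleach_factors") <-
    (1 - cfg$bleach_per_exposure)^(seq_len(nrow(cfg$schedule)) - 1L)
  attr(out, "config") <- cfg
  list(series = series, truth = out)
}
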