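#' Normalise a fluorescence trace to its control baseline
#'
#' Computes the per-terminal baseline as the mean of the control-phase values
#' (the dilute pre-label period) and expresses every later timepoint as a
#' relative change: `dF_t = (F_t - baseline) / baseline`. This removes the
#' arbitrary intensity scale set by native labelling and detector settings,
#' making traces comparable across terminals and experiments. A raw value of
#' zero maps to dF = -1, the complete-loss floor; for non-negative raw
#' values dF can never fall below -1.
#'
#' @param trace a [measure_trace()] result.
#' @return an object of class `norm_trace` holding the non-control
#'   timepoints: times, phases, dF values and the baseline (a.u.).
#' @section Degenerate baselines: a terminal whose control mean is not
#'   positive cannot be normalised; a condition of class
#'   `netrate_degenerate_baseline` is signalled (the pipeline catches it,
#'   excludes the terminal and logs the reason).
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  ctrl <- trace$values[trace$phases == "control"]
  if (length(ctrl) == 0L)
    stop_netrate("trace has no control timepoints", "netrate_format_error")
  baseline <- mean(ctrl)
  if (!is.finite(baseline) || baseline <= 0)
    stop_netrate(
      sprintf("terminal %s: control baseline %.3g is not positive",
              trace$terminal_id, baseline),
      "netrate_degenerate_baseline")
  keep <- trace$phases != "control"
  structure(list(terminal_id = trace$terminal_id,
                 times = trace$times[keep],
                 dF = (trace$values[keep] - baseline) / baseline,
                 phases = trace$phases[keep],
                 baseline = baseline, n_control = length(ctrl)),
            class = "norm_trace")
}

#' @export
print.norm_trace <- function(x, ...) {
  cat(sprintf("<norm_trace #%s> baseline %.4g a.u. (%d control stacks), %d points\n",
              x$terminal_id, x$baseline, x$n_control, length(x$times)))
  print(data.frame(time_min = x$times, phase = x$phases,
                   dF = signif(x$dF, 5)))
  invisible(x)
}

# OLS line through (t, y); returns slope/intercept/r2. r2 of an exactly flat
# (zero-variance) response is defined as 1: the line fits perfectly.
ols_line <- function(t, y) {
  fit <- lm(y ~ t)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(fit$residuals^2)
  r2 <- if (ss_tot < 1e-12) 1 else 1 - ss_res / ss_tot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2, fit = fit)
}

new_net_rate <- function(ls, times, dF, phase, terminal_id, window) {
  structure(list(slope = 100 * ls$slope, intercept = ls$intercept,
                 r_squared = ls$r2, window = window,
                 n_points = length(times), phase = phase,
                 terminal_id = terminal_id, times = times, dF = dF,
                 model = ls$fit),
            class = "net_rate")
}

#' Transporter reuptake rate from the linear uptake phase
#'
#' Fits an ordinary least-squares line y = mx + c through the normalised
#' (time, dF) points of the test phase and reports the gradient as the
#' reuptake rate in %/min (dF per minute x 100). The "linear portion" is
#' chosen automatically as the longest prefix of test-phase points whose fit
#' reaches R^2 >= 0.95 (minimum three points); if no prefix qualifies, all
#' test points are used. An explicit time window overrides the automatic
#' rule.
#'
#' @param ntrace a [normalize_trace()] result.
#' @param window `"auto"` (default) or a numeric `(start, end)` time window
#'   in minutes.
#' @return an object of class `net_rate`; see [net_rate-methods].
#' @examples
#' tr <- structure(list(terminal_id = 1L, times = 0:3,
#'                      dF = c(0, 0.072, 0.144, 0.216),
#'                      phases = rep("test", 4), baseline = 100,
#'                      n_control = 3L), class = "norm_trace")
#' fit_uptake_rate(tr)$slope   # 7.2 %/min
#' @export
fit_uptake_rate <- function(ntrace, window = "auto") {
  stopifnot(inherits(ntrace, "norm_trace"))
  sel <- ntrace$phases == "test"
  t <- ntrace$times[sel]; y <- ntrace$dF[sel]
  if (is.numeric(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; y <- y[keep]
    if (length(t) < 2L)
      stop_netrate("fewer than 2 test-phase points in window",
                   "netrate_fit_error")
    ls <- ols_line(t, y)
    return(new_net_rate(ls, t, y, "uptake", ntrace$terminal_id, range(t)))
  }
  if (length(t) < 2L)
    stop_netrate("fewer than 2 test-phase points", "netrate_fit_error")
  if (length(t) >= 3L) {
    for (k in seq(length(t), 3L)) {
      ls <- ols_line(t[1:k], y[1:k])
      if (ls$r2 >= 0.95)
        return(new_net_rate(ls, t[1:k], y[1:k], "uptake",
                            ntrace$terminal_id, range(t[1:k])))
    }
  }
  ls <- ols_line(t, y)
  new_net_rate(ls, t, y, "uptake", ntrace$terminal_id, range(t))
}

#' Washout decline rate
#'
#' OLS slope (in %/min) of the normalised fluorescence decline over washout
#' timepoints inside `interval` — conventionally the first five minutes of
#' washout. Negative slopes indicate substrate efflux; reverse-transport
#' substrates drive the trace towards the complete-loss floor of -1.
#'
#' @param ntrace a [normalize_trace()] result.
#' @param interval numeric `(start, end)` in minutes (absolute series time);
#'   default spans all washout points.
#' @return a `net_rate` object with `phase = "washout"`.
#' @export
fit_washout_rate <- function(ntrace, interval = NULL) {
  stopifnot(inherits(ntrace, "norm_trace"))
  sel <- ntrace$phases == "washout"
  t <- ntrace$times[sel]; y <- ntrace$dF[sel]
  if (!is.null(interval)) {
    keep <- t >= interval[1] & t <= interval[2]
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 2L)
    stop_netrate("fewer than 2 washout points in interval",
                 "netrate_fit_error")
  ls <- ols_line(t, y)
  new_net_rate(ls, t, y, "washout", ntrace$terminal_id, range(t))
}

#' Methods for `net_rate` objects
#'
#' A fitted rate behaves like a small regression model: `coef()` returns the
#' intercept (dF units) and slope (%/min), `predict()` evaluates the fitted
#' line at new times (dF units), `residuals()`/`fitted()` are in dF units,
#' `plot()` draws the points, the fitted line and the fitted window, and
#' `summary()` adds the underlying least-squares table.
#'
#' @param object,x a `net_rate` object.
#' @param newdata optional numeric vector of times (minutes).
#' @param ... passed on.
#' @name net_rate-methods
NULL

#' @rdname net_rate-methods
#' @export
print.net_rate <- function(x, ...) {
  cat(sprintf("<net_rate> %s slope %.2f %%/min (R^2 %.3f, n = %d, window %g-%g min)\n",
              x$phase, x$slope, x$r_squared, x$n_points,
              x$window[1], x$window[2]))
  invisible(x)
}

#' @rdname net_rate-methods
#' @export
summary.net_rate <- function(object, ...) {
  print(object)
  cat(sprintf("  terminal %s; intercept %.4f (dF units)\n",
              object$terminal_id, object$intercept))
  printCoefmat(summary(object$model)$coefficients)
  invisible(object)
}

#' @rdname net_rate-methods
#' @export
coef.net_rate <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @rdname net_rate-methods
#' @export
predict.net_rate <- function(object, newdata = NULL, ...) {
  t <- newdata %||% object$times
  object$intercept + (object$slope / 100) * t
}

#' @rdname net_rate-methods
#' @export
residuals.net_rate <- function(object, ...) {
  object$dF - predict(object, object$times)
}

#' @rdname net_rate-methods
#' @export
fitted.net_rate <- function(object, ...) predict(object, object$times)

#' @rdname net_rate-methods
#' @export
plot.net_rate <- function(x, ...) {
  plot(x$times, x$dF, xlab = "time (min)", ylab = expression(Delta * F),
       main = sprintf("%s rate: %.2f %%/min", x$phase, x$slope), ...)
  rect(x$window[1], min(x$dF) - 1, x$window[2], max(x$dF) + 1,
       col = gray(0.9, 0.4), border = NA)
  points(x$times, x$dF)
  abline(x$intercept, x$slope / 100, col = "firebrick")
  invisible(x)
}

#' Percent excess of one rate over another
#'
#' `100 * (a - b) / denom`, the "X % higher/greater" statistic used for
#' between-group rate comparisons. The denominator is the reference group
#' `b` by default; the alternative convention (`denominator = "a"`) divides
#' by the first group, which is how washout accelerations are reported when
#' the faster-declining group serves as the reference magnitude.
#'
#' @param a,b rates, %/min (scalars).
#' @param denominator `"b"` (default) or `"a"`.
#' @return percent difference (scalar).
#' @examples
#' percent_excess(6.5, 4.0)    # 62.5 % faster in the heart than the artery
#' percent_excess(-26.4, -12.1, denominator = "a")  # 54.2 % washout excess
#' @export
percent_excess <- function(a, b, denominator = c("b", "a")) {
  denominator <- match.arg(denominator)
  denom <- if (denominator == "b") b else a
  if (denom == 0)
    stop_netrate("percent_excess denominator is zero", "netrate_value_error")
  100 * (a - b) / denom
}

#' Fold change between two rates
#'
#' @param a,b rates, %/min; `b` must be non-zero.
#' @return `a / b`. Satisfies
#'   `percent_excess(a, b) == 100 * (fold_change(a, b) - 1)`.
#' @export
fold_change <- function(a, b) {
  if (b == 0)
    stop_netrate("fold_change divisor is zero", "netrate_value_error")
  a / b
}

#' Root-sum-of-squares combination of relative errors
#'
#' Combines the uncertainties of several estimates into one relative error:
#' `sqrt(sum((sem_i / mean_i)^2))`. Used when reporting percent differences
#' between groups whose means each carry an SEM.
#'
#' @param means,sems numeric vectors of equal length; means non-zero, sems
#'   non-negative.
#' @return combined relative error (unitless).
#' @examples
#' combine_relative_errors(c(1, 1), c(0.03, 0.04))  # 0.05
#' @export
combine_relative_errors <- function(means, sems) {
  stopifnot(length(means) == length(sems))
  if (any(means == 0))
    stop_netrate("cannot form a relative error around a zero mean",
                 "netrate_value_error")
  if (any(sems < 0))
    stop_netrate("sems must be non-negative", "netrate_value_error")
  sqrt(sum((sems / means)^2))
}

#' Change in normalised fluorescence between two timepoints
#'
#' `dF(t_b) - dF(t_a)`: the endpoint statistic used to compare imaging
#' schedules (with heavy per-exposure photobleaching, constant imaging drives
#' this negative while a reduced-illumination schedule keeps it positive).
#'
#' @param ntrace a [normalize_trace()] result.
#' @param t_a,t_b timepoints, minutes; both must be present in the trace.
#' @return scalar dF difference (unitless).
#' @export
schedule_delta <- function(ntrace, t_a, t_b) {
  stopifnot(inherits(ntrace, "norm_trace"))
  pick <- function(t0) {
    i <- which(abs(ntrace$times - t0) < 1e-8)
    if (length(i) != 1L)
      stop_netrate(sprintf("timepoint t = %g min not present in trace", t0),
                   "netrate_value_error")
    ntrace$dF[i]
  }
  pick(t_b) - pick(t_a)
}
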