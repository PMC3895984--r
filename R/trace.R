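#' Output-trace container
#'
#' A coincidence-detector output (or closed-form prediction) sampled on a
#' probe-trial time grid, together with provenance metadata.
#'
#' @param time Strictly increasing time grid in seconds.
#' @param value Output values, same length as `time`, all finite.
#' @param meta Named list of metadata (model variant, noise specs, seeds,
#'   provenance = "simulated" or "analytic", ...).
#' @return An object of class `"sbf_trace"`.
#' @export
sbf_trace <- function(time, value, meta = list()) {
  if (length(time) == 0L) stop("empty time grid", call. = FALSE)
  if (length(time) != length(value)) {
    stop("`time` and `value` lengths differ", call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  if (!all(is.finite(value))) stop("trace values must be finite", call. = FALSE)
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 meta = meta), class = "sbf_trace")
}

#' @export
print.sbf_trace <- function(x, ...) {
  cat(sprintf("SBF output trace: %d samples on [%.3g, %.3g] s%s\n",
              length(x$time), x$time[1], x$time[length(x$time)],
              if (!is.null(x$meta$provenance)) paste0(" (", x$meta$provenance, ")") else ""))
  pk <- which.max(x$value)
  cat(sprintf("  max %.4g at t = %.4g s\n", x$value[pk], x$time[pk]))
  invisible(x)
}

#' @export
as.data.frame.sbf_trace <- function(x, ...) {
  data.frame(time_s = x$time, out = x$value)
}

#' @export
plot.sbf_trace <- function(x, ..., xlab = "time (s)", ylab = "output",
                           type = "l") {
  plot(x$time, x$value, type = type, xlab = xlab, ylab = ylab, ...)
}

#' Max-normalize a trace
#'
#' Rescales the values so the maximum equals 1.  Closed-form and simulated
#' traces differ by amplitude constants (normalization of the weights, trial
#' counts), so shape comparisons are made on max-normalized curves.
#'
#' @param trace An [sbf_trace()].
#' @return The trace with values divided by their maximum.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "sbf_trace"))
  m <- max(trace$value)
  if (m == 0) stop("cannot normalize an all-zero trace", call. = FALSE)
  trace$value <- trace$value / m
  trace$meta$normalized <- TRUE
  trace
}

#' Default probe-trial time grid
#'
#' `dt = 1/(20 f_max)` (at least 20 samples per cycle of the fastest
#' oscillator) spanning `[0, 3 T]`, the conventional probe-trial length of
#' about three criterion times.
#'
#' @param spec An [osc_bank_spec()].
#' @param T_crit Criterion time in seconds.
#' @param span Multiple of `T_crit` to cover (default 3).
#' @return Numeric time grid in seconds.
#' @export
probe_grid <- function(spec, T_crit, span = 3) {
  dt <- 1 / (20 * spec$f_max)
  seq(0, span * T_crit, by = dt)
}
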