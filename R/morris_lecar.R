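#' Morris-Lecar neuron parameters
#'
#' Two-variable conductance-based oscillator: membrane potential `V` and a
#' slow potassium gating variable `w`, with instantaneous calcium activation.
#' The default set is the classic Hopf-regime (type II) parameterization with
#' the calcium conductance slightly reduced and the kinetics rescaled
#' (`C = 32` uF/cm^2, `gCa = 3.2` mS/cm^2, `phi = 0.025` /ms) so that the
#' monotone part of the f-I curve spans roughly 7.6-12.3 Hz and the cortical
#' alpha band (8-12 Hz) is reachable by bias-current calibration alone.
#'
#' @param C Membrane capacitance (uF/cm^2).
#' @param gL,gCa,gK Leak, calcium and potassium conductances (mS/cm^2, >= 0).
#' @param VL,VCa,VK Reversal potentials (mV).
#' @param v1,v2 Half-activation voltage and slope of calcium activation (mV).
#' @param v3,v4 Half-activation voltage and slope of potassium activation (mV).
#' @param phi Potassium recovery rate scale (1/ms).
#' @param I_bias Default bias current (uA/cm^2).
#' @param dt Integration step in seconds (default 1e-4 s = 0.1 ms; fixed-step
#'   RK4, chosen so halving `dt` changes the firing period by far less than
#'   0.5 percent).
#' @param v_thresh Spike-detection threshold (mV); spikes are upward
#'   crossings.
#' @return An object of class `"ml_params"`.
#' @export
ml_params <- function(C = 32, gL = 2, gCa = 3.2, gK = 8,
                      VL = -60, VCa = 120, VK = -84,
                      v1 = -1.2, v2 = 18, v3 = 2, v4 = 30,
                      phi = 0.025, I_bias = 160,
                      dt = 1e-4, v_thresh = 0) {
  if (any(c(gL, gCa, gK) < 0)) stop("conductances must be >= 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  structure(
    list(C = C, gL = gL, gCa = gCa, gK = gK, VL = VL, VCa = VCa, VK = VK,
         v1 = v1, v2 = v2, v3 = v3, v4 = v4, phi = phi, I_bias = I_bias,
         dt = dt, v_thresh = v_thresh),
    class = "ml_params"
  )
}

# Shared initial condition near the limit cycle; any fixed choice is fine
# because transients are discarded before rates/states are measured.
.ml_v0 <- -26
.ml_w0 <- 0.13

#' Integrate Morris-Lecar neurons
#'
#' Fixed-step RK4 integration of one neuron (or a bank of neurons differing
#' only in bias current).  Deterministic given the parameters.
#'
#' @param params An [ml_params()].
#' @param duration Simulated time in seconds.
#' @param I_bias Bias current(s), uA/cm^2; one neuron per element.  Defaults
#'   to `params$I_bias`.
#' @param record_dt Sampling interval of the returned voltage trace in
#'   seconds (default 2 ms).
#' @return List with `time` (s), `voltage` (matrix, one column per neuron;
#'   a plain vector if one neuron), and `spikes` (list of spike-time vectors
#'   in seconds, upward crossings of `params$v_thresh`).
#' @export
ml_integrate <- function(params, duration, I_bias = params$I_bias,
                         record_dt = 2e-3) {
  stopifnot(inherits(params, "ml_params"), duration > 0)
  dt_ms <- params$dt * 1e3
  stride <- max(1L, as.integer(round(record_dt / params$dt)))
  res <- .ml_bank_rk4(unclass(params), as.numeric(I_bias), duration * 1e3,
                      dt_ms, stride, params$v_thresh, .ml_v0, .ml_w0)
  v <- res$voltage
  time <- (seq_len(nrow(v)) - 1) * stride * params$dt
  spikes <- lapply(res$spikes, function(s) s * 1e-3)
  if (length(I_bias) == 1L) v <- drop(v)
  list(time = time, voltage = v, spikes = spikes)
}

#' Mean firing rate from spike times
#'
#' Rate over the spikes after a transient is discarded; inverse of the mean
#' inter-spike interval.
#'
#' @param spikes Numeric vector of spike times in seconds.
#' @param discard Transient to discard in seconds.
#' @return Rate in Hz (0 if fewer than 3 post-transient spikes).
#' @export
ml_rate <- function(spikes, discard = 0.5) {
  s <- spikes[spikes > discard]
  if (length(s) < 3) return(0)
  (length(s) - 1) / (s[length(s)] - s[1])
}

#' Morris-Lecar f-I curve
#'
#' Firing rate as a function of bias current, measured by direct integration.
#'
#' @param params An [ml_params()].
#' @param I Bias-current grid (uA/cm^2).
#' @param duration Integration time per current in seconds.
#' @return Data frame with columns `I` and `rate_hz`.
#' @export
ml_fi_curve <- function(params, I = seq(115, 260, by = 5), duration = 6) {
  res <- ml_integrate(params, duration, I_bias = I)
  data.frame(I = I, rate_hz = vapply(res$spikes, ml_rate, numeric(1)))
}

#' Calibrate bias currents to target firing rates
#'
#' Inverts the f-I curve: finds, for each target frequency, the bias current
#' at which the measured firing rate matches the target within `tol`
#' (relative).  A coarse monotone f-I curve provides the initial bracket and
#' vectorized bisection refines all targets simultaneously.
#'
#' @param target_f Target rate(s) in Hz.
#' @param params An [ml_params()].
#' @param tol Relative rate tolerance (default 0.01).
#' @param I_range Currents bracketing the searchable band.
#' @param duration Integration time per bisection step in seconds.
#' @param max_iter Maximum bisection iterations.
#' @return Numeric vector of calibrated bias currents (attributes
#'   `rates` = achieved rates).  Errors if any target is outside the
#'   achievable band, naming that band.
#' @export
calibrate_bias <- function(target_f, params = ml_params(), tol = 0.01,
                           I_range = c(115, 260), duration = 6,
                           max_iter = 12) {
  stopifnot(all(is.finite(target_f)))
  curve <- ml_fi_curve(params, I = seq(I_range[1], I_range[2], length.out = 25),
                       duration = duration)
  osc <- curve$rate_hz > 0
  if (!any(osc)) stop("no oscillatory regime in `I_range`", call. = FALSE)
  # monotone increasing section of the f-I curve
  i0 <- which(osc)[1]
  imax <- i0 - 1 + which.max(curve$rate_hz[i0:nrow(curve)])
  f_lo <- curve$rate_hz[i0]; f_hi <- curve$rate_hz[imax]
  if (any(target_f < f_lo * (1 - tol) | target_f > f_hi * (1 + tol))) {
    stop(sprintf(
      "target rate outside the achievable band [%.2f, %.2f] Hz", f_lo, f_hi),
      call. = FALSE)
  }
  seg <- curve[i0:imax, ]
  guess <- approx(seg$rate_hz, seg$I, xout = pmin(pmax(target_f, f_lo), f_hi),
                  rule = 2)$y
  span <- diff(range(seg$I)) / (nrow(seg) - 1)
  lo <- pmax(guess - span, seg$I[1]); hi <- pmin(guess + span, seg$I[nrow(seg)])
  rate_at <- function(I) {
    vapply(ml_integrate(params, duration, I_bias = I)$spikes, ml_rate,
           numeric(1))
  }
  mid <- (lo + hi) / 2
  rates <- rate_at(mid)
  for (k in seq_len(max_iter)) {
    if (all(abs(rates - target_f) / target_f < tol / 2)) break
    up <- rates > target_f
    hi[up] <- mid[up]; lo[!up] <- mid[!up]
    mid <- (lo + hi) / 2
    rates <- rate_at(mid)
  }
  bad <- abs(rates - target_f) / target_f >= tol
  if (any(bad)) {
    stop(sprintf("calibration failed for %d target(s); achievable band [%.2f, %.2f] Hz",
                 sum(bad), f_lo, f_hi), call. = FALSE)
  }
  structure(mid, rates = rates)
}

#' Build a calibrated Morris-Lecar oscillator bank
#'
#' Draws the bank's target frequencies from an [osc_bank_spec()], calibrates
#' each neuron's bias current and integrates the whole bank for `duration`
#' seconds, storing the voltage traces used by [ml_states()].
#'
#' @param spec An [osc_bank_spec()].
#' @param params An [ml_params()].
#' @param duration Length of the stored traces in seconds (cover the longest
#'   probe trial you intend to run).
#' @param seed Seed for uniform frequency placement.
#' @param record_dt Trace sampling interval in seconds.
#' @param calib_duration Integration time per calibration step (s).
#' @return An object of class `"ml_bank"`: list with `freqs`, `I_bias`,
#'   `rates`, `time`, `states` (normalized to `[-a, a]`), `states_centered`
#'   (additionally mean-centred per neuron), `spec`, `params`.
#' @export
ml_bank <- function(spec, params = ml_params(), duration = 12, seed = 1,
                    record_dt = 2e-3, calib_duration = 6) {
  stopifnot(inherits(spec, "osc_bank_spec"))
  freqs <- make_frequencies(spec, seed = seed)
  I <- calibrate_bias(freqs, params, duration = calib_duration)
  res <- ml_integrate(params, duration, I_bias = I, record_dt = record_dt)
  v <- res$voltage
  if (is.null(dim(v))) v <- matrix(v, ncol = 1L)
  keep <- res$time > 1           # post-transient window for the flatness check
  osc_amp <- apply(v[keep, , drop = FALSE], 2, max) -
             apply(v[keep, , drop = FALSE], 2, min)
  if (any(osc_amp < 1)) {
    stop("flat Morris-Lecar trace: calibration produced a non-oscillating neuron",
         call. = FALSE)
  }
  rng_lo <- apply(v, 2, min)     # rescale over the whole simulated window
  rng_hi <- apply(v, 2, max)
  S <- sweep(sweep(v, 2, rng_lo), 2, (rng_hi - rng_lo) / 2, "/") - 1
  S <- S * spec$amplitude
  Sc <- sweep(S, 2, colMeans(S[keep, , drop = FALSE]))
  structure(
    list(freqs = freqs, I_bias = as.numeric(I), rates = attr(I, "rates"),
         time = res$time, states = S, states_centered = Sc,
         spec = spec, params = params, seed = seed),
    class = "ml_bank"
  )
}

#' @export
print.ml_bank <- function(x, ...) {
  cat(sprintf("Morris-Lecar bank: %d neurons, %.2f-%.2f Hz, traces 0-%.1f s\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$time[length(x$time)]))
  cat(sprintf("  max calibration error: %.3g%%\n",
              100 * max(abs(x$rates - x$freqs) / x$freqs)))
  invisible(x)
}

#' Normalized Morris-Lecar states on a time grid
#'
#' Linear interpolation of the bank's stored voltage traces, affinely
#' rescaled per neuron to `[-a, a]` over the simulated window (so the ML
#' states play the same role as the sine states in the coincidence readout).
#' With `centered = TRUE` each neuron's temporal mean is additionally
#' removed, which suppresses the waveform's DC component; the experiment
#' pipeline uses centred states so the readout is a pure coincidence signal.
#'
#' `rate_scale` evaluates the (periodic, calibrated) waveforms at
#' `rate_scale * t`, realizing a common frequency multiplier; per-neuron bias
#' jitter through the inverse f-I map is available via [calibrate_bias()].
#'
#' @param bank An [ml_bank()].
#' @param t Time grid in seconds (within the stored trace, after scaling).
#' @param centered Remove each neuron's temporal mean.
#' @param rate_scale Common clock-speed multiplier (default 1).
#' @return Matrix with `length(t)` rows and one column per neuron.
#' @export
ml_states <- function(bank, t, centered = FALSE, rate_scale = 1) {
  stopifnot(inherits(bank, "ml_bank"))
  S <- if (centered) bank$states_centered else bank$states
  ts <- t * rate_scale
  tmax <- bank$time[length(bank$time)]
  if (any(ts < 0) || any(ts > tmax + 1e-9)) {
    stop(sprintf("requested times exceed the stored traces (0-%.2f s)", tmax),
         call. = FALSE)
  }
  dtr <- bank$time[2] - bank$time[1]
  idx <- pmin(pmax(ts / dtr, 0), length(bank$time) - 2)
  i0 <- floor(idx)
  fr <- idx - i0
  S[i0 + 1, , drop = FALSE] * (1 - fr) + S[i0 + 2, , drop = FALSE] * fr
}
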