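#' Oscillator-bank specification
#'
#' Defines the population of cortical input oscillators: how many there are,
#' the frequency band they tile and the oscillation amplitude.  The default
#' band is the cortical alpha band (8-12 Hz).
#'
#' @param n_osc Number of input oscillators (positive integer).
#' @param f_min,f_max Band edges in Hz; `0 < f_min < f_max`.
#' @param amplitude Oscillation amplitude `a` (dimensionless, > 0).
#' @param spacing `"equal"` for the equally spaced comb
#'   `f_k = f_min + k (f_max - f_min)/n_osc`, `k = 0, ..., n_osc - 1`,
#'   or `"uniform"` for independent uniform draws on `(f_min, f_max)`.
#'   Equal spacing matches the closed-form analysis; uniform placement avoids
#'   the comb's alias recurrence at `n_osc / (f_max - f_min)` seconds, which
#'   matters for small banks probed over long trials.
#' @return An object of class `"osc_bank_spec"`.
#' @examples
#' spec <- osc_bank_spec(n_osc = 1000, f_min = 8, f_max = 12)
#' head(make_frequencies(spec))
#' @export
osc_bank_spec <- function(n_osc, f_min = 8, f_max = 12, amplitude = 1,
                          spacing = c("equal", "uniform")) {
  spacing <- match.arg(spacing)
  if (!is.numeric(n_osc) || length(n_osc) != 1L || n_osc < 1 ||
      n_osc != round(n_osc)) {
    stop("`n_osc` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(f_min) || f_min <= 0) stop("`f_min` must be > 0", call. = FALSE)
  if (!is.numeric(f_max) || f_max <= f_min) {
    stop("`f_max` must exceed `f_min`", call. = FALSE)
  }
  if (!is.numeric(amplitude) || amplitude <= 0) {
    stop("`amplitude` must be > 0", call. = FALSE)
  }
  structure(
    list(n_osc = as.integer(n_osc), f_min = f_min, f_max = f_max,
         amplitude = amplitude, spacing = spacing),
    class = "osc_bank_spec"
  )
}

#' @export
print.osc_bank_spec <- function(x, ...) {
  cat(sprintf("Oscillator bank: %d oscillators, %.3g-%.3g Hz (%s spacing), a = %g\n",
              x$n_osc, x$f_min, x$f_max, x$spacing, x$amplitude))
  invisible(x)
}

#' Oscillator frequency grid
#'
#' Frequencies of the bank members.  For equal spacing,
#' `f_k = f_min + k * df` with `df = (f_max - f_min)/n_osc` and
#' `k = 0, ..., n_osc - 1`, so the grid covers `[f_min, f_max - df]`.
#' Uniform spacing draws iid frequencies (sorted) and requires a seed for
#' reproducibility.
#'
#' @param spec An [osc_bank_spec()].
#' @param seed Integer seed, used only for `spacing = "uniform"`.
#' @return Numeric vector of frequencies in Hz, strictly increasing, all
#'   `< f_max`.
#' @export
make_frequencies <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "osc_bank_spec"))
  if (spec$spacing == "equal") {
    df <- (spec$f_max - spec$f_min) / spec$n_osc
    spec$f_min + df * (seq_len(spec$n_osc) - 1)
  } else {
    if (is.null(seed)) stop("uniform spacing needs a `seed`", call. = FALSE)
    sort(with_seed(seed, runif(spec$n_osc, spec$f_min, spec$f_max)))
  }
}

#' Sine-oscillator states
#'
#' Membrane potential of each phase oscillator, `v_i(t) = a cos(2 pi f_i t)`.
#' All oscillators are in phase at `t = 0` (stimulus onset resets the bank).
#'
#' @param freqs Frequency vector in Hz (one per oscillator).
#' @param amplitude Oscillation amplitude `a`.
#' @param t Time in seconds; scalar or vector.
#' @return If `t` is scalar, a numeric vector (one state per oscillator);
#'   otherwise a matrix with `length(t)` rows and one column per oscillator.
#' @export
sine_states <- function(freqs, amplitude = 1, t = 0) {
  stopifnot(all(t >= 0))
  if (length(t) == 1L) {
    amplitude * cos(2 * pi * freqs * t)
  } else {
    amplitude * cos(2 * pi * outer(t, freqs))
  }
}

# Evaluate set.seed()ed code without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
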