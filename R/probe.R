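#' Coincidence-detector output on probe trials
#'
#' The striatal output neuron computes the dot product between the stored
#' reference weights `w_i` and the current oscillator states `v_i(t)`:
#' `out(t) = sum_i w_i a cos(2 pi f_i (1 + xi) t)`, averaged over
#' `n_probe_trials` probe trials.  Frequency noise perturbs the oscillation
#' frequencies during the probe; the multipliers are drawn afresh each trial
#' and held fixed within a trial.
#'
#' Two sampling modes are supported.  `"per_trial"` draws one multiplier per
#' trial, shared by the whole bank (a global clock-speed fluctuation,
#' `f_ij = f_i (1 + xi_j)`); this is the regime in which the skewed,
#' long-tailed output arises for a finite band.  `"per_oscillator"` draws an
#' independent multiplier for every (oscillator, trial) pair; independent
#' jitter decorrelates a narrow-band bank and flattens the trial-averaged
#' output.
#'
#' `average = "signed"` returns the plain average of the trial outputs (this
#' is what the closed-form expectation describes); `"rectified"` averages
#' `|out|` across trials, the behavioural analogue of accumulating response
#' rates, used for envelope analyses of narrow-band banks.
#'
#' @param memory An [encode_reference()] result.
#' @param freqs Oscillator frequencies in Hz (defaults to `memory$freqs`).
#' @param amplitude Oscillation amplitude `a`.
#' @param grid Probe-trial time grid in seconds (see [probe_grid()]).
#' @param freq_noise A [noise_spec()] for the probe-trial frequencies.
#' @param n_probe_trials Number of probe trials averaged.
#' @param mode `"per_trial"` or `"per_oscillator"` (see Details).
#' @param average `"signed"` or `"rectified"`.
#' @param states_fun Optional function `f(times, mult)` returning the
#'   oscillator-state matrix at `times` with frequency multiplier(s) `mult`
#'   (scalar in `"per_trial"` mode, vector in `"per_oscillator"` mode);
#'   replaces the sine states, e.g. for a Morris-Lecar bank.
#' @param return_peaks Also record each trial's coincidence-peak time
#'   (argmax of `|out_j|` over the grid), returned as `meta$trial_peaks`.
#'   The distribution of these per-trial peak times is the model's analogue
#'   of a response-time histogram.
#' @return An [sbf_trace()].
#' @export
probe_output <- function(memory, freqs = memory$freqs, amplitude = 1,
                         grid = NULL,
                         freq_noise = noise_spec("none"),
                         n_probe_trials = 1,
                         mode = c("per_trial", "per_oscillator"),
                         average = c("signed", "rectified"),
                         states_fun = NULL, return_peaks = FALSE) {
  stopifnot(inherits(memory, "sbf_memory"))
  mode <- match.arg(mode)
  average <- match.arg(average)
  if (is.null(grid) || length(grid) == 0L) {
    stop("probe time grid is empty", call. = FALSE)
  }
  w <- memory$weights
  if (length(w) != length(freqs)) {
    stop("memory and frequency grid sizes differ", call. = FALSE)
  }
  if (freq_noise$distribution == "none") n_probe_trials <- 1L

  n_mult <- if (mode == "per_trial") n_probe_trials else
    n_probe_trials * length(freqs)
  mult <- sample_multipliers(freq_noise, n_mult)
  if (mode == "per_oscillator") {
    mult <- matrix(mult, nrow = length(freqs), ncol = n_probe_trials)
  }

  # evaluate in time blocks so the state matrix stays modest
  block <- max(1L, floor(2e7 / length(freqs)))
  one_trial <- function(j) {
    mj <- if (mode == "per_trial") mult[j] else mult[, j]
    out <- numeric(length(grid))
    for (s0 in seq(1L, length(grid), by = block)) {
      s1 <- min(s0 + block - 1L, length(grid))
      g <- grid[s0:s1]
      out[s0:s1] <- if (is.null(states_fun)) {
        amplitude * drop(cos(2 * pi * outer(g, freqs * mj)) %*% w)
      } else {
        drop(states_fun(g, mj) %*% w)
      }
    }
    out
  }

  acc <- numeric(length(grid))
  peaks <- if (return_peaks) numeric(n_probe_trials) else NULL
  for (j in seq_len(n_probe_trials)) {
    oj <- one_trial(j)
    if (return_peaks) peaks[j] <- grid[which.max(abs(oj))]
    acc <- acc + if (average == "rectified") abs(oj) else oj
  }
  acc <- acc / n_probe_trials

  sbf_trace(grid, acc, meta = list(
    trial_peaks = peaks,
    provenance = "simulated",
    model = if (is.null(states_fun)) "sbf-sin" else "sbf-ml",
    criterion = memory$criterion,
    criterion_noise = memory$noise[c("distribution", "sigma", "seed")],
    freq_noise = freq_noise[c("distribution", "sigma", "seed")],
    n_probe_trials = n_probe_trials, mode = mode, average = average
  ))
}
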