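#' Encode the reference memory of a criterion time
#'
#' Over `n_trials` fixed-interval (FI) trials the circuit stores the state of
#' every oscillator at the moment of reinforcement.  Trial `j` memorizes the
#' criterion as `T_j = T (1 + xi_j)` (multiplicative criterion-time noise);
#' the stored weight of oscillator `i` is the average state
#' `u_i = mean_j cos(2 pi f_i T_j)` (for sine oscillators; for a
#' Morris-Lecar bank pass `states_fun`), normalized by `max_i |u_i|` so that
#' `max_i |w_i| = 1`.
#'
#' @param freqs Oscillator frequencies in Hz.
#' @param T_crit Criterion time in seconds (> 0; `T = 0` is tolerated for
#'   degenerate tests, where every weight is 1).
#' @param n_trials Number of FI trials (>= 1).
#' @param noise A [noise_spec()] for the stored criterion (default none).
#' @param states_fun Function `f(times)` returning the oscillator-state matrix
#'   (`length(times)` rows, one column per oscillator) used in place of the
#'   sine states; used for Morris-Lecar banks.
#' @param positive If `TRUE` use the positively defined weights
#'   `(1 + w_i)/2` in `[0, 1]` instead of the signed weights.
#' @param keep_criteria Keep the sampled `T_j` for audit.
#' @return An object of class `"sbf_memory"`: list with `weights`, `criterion`,
#'   `n_trials`, `norm_constant`, `freqs`, and optionally `criteria`.
#' @export
encode_reference <- function(freqs, T_crit, n_trials = 1000,
                             noise = noise_spec("none"),
                             states_fun = NULL, positive = FALSE,
                             keep_criteria = FALSE) {
  stopifnot(T_crit >= 0, n_trials >= 1)
  mult <- sample_multipliers(noise, n_trials)
  Tj <- T_crit * mult
  state_at <- if (is.null(states_fun)) {
    function(times) cos(2 * pi * outer(times, freqs))
  } else states_fun
  # accumulate the trial average in blocks so the state matrix stays modest
  block <- max(1L, floor(2e7 / length(freqs)))
  u <- numeric(length(freqs))
  for (s0 in seq(1L, n_trials, by = block)) {
    s1 <- min(s0 + block - 1L, n_trials)
    u <- u + colSums(state_at(Tj[s0:s1]))
  }
  u <- u / n_trials
  norm_const <- max(abs(u))
  if (norm_const == 0) {
    stop("degenerate reference memory: all weights are zero", call. = FALSE)
  }
  w <- u / norm_const
  if (positive) w <- (1 + w) / 2
  structure(
    list(weights = w, criterion = T_crit, n_trials = as.integer(n_trials),
         norm_constant = norm_const, freqs = freqs, positive = positive,
         noise = noise,
         criteria = if (keep_criteria) Tj else NULL),
    class = "sbf_memory"
  )
}

#' @export
print.sbf_memory <- function(x, ...) {
  cat(sprintf(
    "Reference memory: T = %g s over %d FI trials (%s criterion noise, sigma = %g)\n",
    x$criterion, x$n_trials, x$noise$distribution, x$noise$sigma))
  cat(sprintf("  %d weights in [%.3f, %.3f], norm constant %.4g\n",
              length(x$weights), min(x$weights), max(x$weights),
              x$norm_constant))
  invisible(x)
}
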