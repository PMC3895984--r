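#' Experiment configuration
#'
#' Bundles the settings of a reproducible SBF experiment: model variant,
#' oscillator bank, criterion times, noise target and levels, trial counts and
#' the master seed.  Defaults reflect the headline simulation conditions: an
#' alpha-band (8-12 Hz) bank of 1000 oscillators, criterion times extending
#' the published pair {10, 30} s so regressions have enough support.
#'
#' @param model `"sbf-sin"` or `"sbf-ml"`.
#' @param spec An [osc_bank_spec()].
#' @param criteria Criterion times in seconds (non-empty, all > 0).
#' @param noise_target `"none"`, `"criterion"` or `"frequency"`.
#' @param distribution Noise family (see [noise_spec()]).
#' @param sigmas Noise fractional SD(s).
#' @param n_fi_trials FI trials encoded per reference memory.
#' @param n_probe_trials Probe trials averaged (frequency noise).
#' @param n_memory_avg Independent reference-memory re-encodings averaged for
#'   rectified criterion-noise traces (used by the ML pipeline).
#' @param replicates Independent replicate runs for slope statistics.
#' @param seed Master seed; every random draw in the experiment derives from
#'   it deterministically.
#' @param grid_span Probe length as a multiple of the criterion (default 3).
#' @param ml_parameters An [ml_params()] for the `"sbf-ml"` variant.
#' @return An object of class `"sbf_config"`.
#' @export
experiment_config <- function(model = c("sbf-sin", "sbf-ml"),
                              spec = osc_bank_spec(1000, 8, 12),
                              criteria = c(5, 10, 20, 30, 40, 50),
                              noise_target = c("none", "criterion", "frequency"),
                              distribution = "gaussian",
                              sigmas = 0.1,
                              n_fi_trials = 1000,
                              n_probe_trials = 200,
                              n_memory_avg = 20,
                              replicates = 1,
                              seed = 1,
                              grid_span = 3,
                              ml_parameters = ml_params()) {
  model <- match.arg(model)
  noise_target <- match.arg(noise_target)
  if (length(criteria) == 0 || any(criteria <= 0)) {
    stop("`criteria` must be a non-empty vector of positive times", call. = FALSE)
  }
  structure(
    list(model = model, spec = spec, criteria = criteria,
         noise_target = noise_target, distribution = distribution,
         sigmas = sigmas, n_fi_trials = n_fi_trials,
         n_probe_trials = n_probe_trials, n_memory_avg = n_memory_avg,
         replicates = replicates, seed = seed, grid_span = grid_span,
         ml_parameters = ml_parameters),
    class = "sbf_config"
  )
}

# Deterministic sub-seed derivation from a master seed (stays below 2^31).
derive_seed <- function(master, ...) {
  key <- c(master, ...)
  as.integer((sum(key * (seq_along(key) * 7919 + 1)) %% 2147483629) + 1)
}

# Build (or reuse) the states accessor for a config: returns a list with
# `freqs` and `states_fun(times)` (centred states for ML, NULL for sine).
model_states <- function(config, duration) {
  if (config$model == "sbf-sin") {
    list(freqs = make_frequencies(config$spec,
                                  seed = if (config$spec$spacing == "uniform")
                                    derive_seed(config$seed, 17) else NULL),
         states_fun = NULL, bank = NULL)
  } else {
    bank <- ml_bank(config$spec, config$ml_parameters,
                    duration = duration + 1,
                    seed = derive_seed(config$seed, 17))
    tmax <- bank$time[length(bank$time)]
    list(freqs = bank$freqs,
         states_fun = function(times, mult = 1) {
           ml_states(bank, pmin(pmax(times * mult, 0), tmax), centered = TRUE)
         },
         bank = bank)
  }
}

# One criterion-noise width measurement (Gaussian-fit sigma of the envelope
# of the rectified coincidence output).
criterion_width <- function(ms, config, T_crit, sigma, seed) {
  grid <- probe_grid(config$spec, T_crit, config$grid_span)
  noise <- noise_spec(config$distribution, sigma, seed = seed)
  if (config$model == "sbf-sin") {
    mem <- encode_reference(ms$freqs, T_crit, config$n_fi_trials, noise)
    trace <- probe_output(mem, grid = grid)
    env <- upper_envelope(trace, rectify = TRUE)
    fit <- fit_gaussian(env, offset = TRUE)
  } else {
    # average the rectified output over independent re-encodings: the
    # behavioural analogue of accumulating response rates over sessions.
    # The (noise-free) probe states are the same for every re-encoding, so
    # they are interpolated once.
    S_grid <- ms$states_fun(grid, 1)
    acc <- numeric(length(grid))
    for (r in seq_len(config$n_memory_avg)) {
      noise_r <- noise_spec(config$distribution, sigma,
                            seed = derive_seed(seed, r))
      mem <- encode_reference(ms$freqs, T_crit, config$n_fi_trials, noise_r,
                              states_fun = function(times)
                                ms$states_fun(times))
      acc <- acc + abs(drop(S_grid %*% mem$weights))
    }
    trace <- sbf_trace(grid, acc / config$n_memory_avg,
                       meta = list(provenance = "simulated", model = "sbf-ml"))
    fit <- fit_gaussian(trace, offset = TRUE, t_min = 1)
  }
  list(width = fit$sigma, mu = fit$mu, r2 = fit$r2)
}

# One frequency-noise run: width from a Gaussian-plus-background fit to the
# trial-rectified average; skewness from the distribution of per-trial
# coincidence-peak times (the response-time histogram), which is free of the
# symmetric Dirichlet-kernel wings that ride under the averaged trace.
# The skew ratio uses the 12/50/88 percent quantiles of the peak-time sample,
# the robust analogue of the half-height crossings (a Gaussian's half-height
# points sit at +/- 1.18 sd, i.e. its 12th and 88th percentiles), so a
# symmetric peak gives 1 and a long right tail gives > 1.
frequency_trace_metrics <- function(ms, config, T_crit, sigma, seed) {
  grid <- probe_grid(config$spec, T_crit, config$grid_span)
  noise <- noise_spec(config$distribution, sigma, seed = seed)
  mem <- encode_reference(ms$freqs, T_crit, 1, noise_spec("none"),
                          states_fun = if (is.null(ms$states_fun)) NULL else
                            function(times) ms$states_fun(times))
  trace <- probe_output(mem, freqs = ms$freqs, grid = grid,
                        freq_noise = noise,
                        n_probe_trials = config$n_probe_trials,
                        mode = "per_trial", average = "rectified",
                        states_fun = ms$states_fun, return_peaks = TRUE)
  fit <- fit_gaussian(trace, offset = TRUE, t_min = 1)
  q <- quantile(trace$meta$trial_peaks, c(0.12, 0.5, 0.88), names = FALSE)
  list(width = fit$sigma, mu = fit$mu, r2 = fit$r2,
       skew_ratio = (q[3] - q[2]) / (q[2] - q[1]), t_peak = q[2])
}

#' Noiseless-circuit experiment
#'
#' Simulates the noise-free model for each criterion time and measures the
#' output width (half-height full width of the envelope of the rectified
#' output).  The noiseless width is set by the frequency band alone, so it is
#' the same for every criterion: the noiseless circuit violates time-scale
#' invariance.
#'
#' @param config An [experiment_config()] with `noise_target = "none"`.
#' @return An object of class `"sbf_report"` with one row per criterion
#'   (columns `T`, `width`, `peak`, `seed`), plus `width_spread` (max relative
#'   spread) and, for `"sbf-sin"`, `predicted_width` from the closed form.
#' @export
run_noiseless <- function(config) {
  stopifnot(inherits(config, "sbf_config"), config$noise_target == "none")
  ms <- model_states(config, duration = config$grid_span * max(config$criteria))
  rows <- lapply(config$criteria, function(T_crit) {
    grid <- probe_grid(config$spec, T_crit, config$grid_span)
    mem <- encode_reference(ms$freqs, T_crit, 1, noise_spec("none"),
                            states_fun = if (is.null(ms$states_fun)) NULL else
                              function(times) ms$states_fun(times))
    trace <- probe_output(mem, freqs = ms$freqs, grid = grid,
                          states_fun = ms$states_fun)
    env <- upper_envelope(trace, rectify = TRUE)
    guard <- env$time >= 1
    pk <- half_width_points(sbf_trace(env$time[guard], env$value[guard]))
    data.frame(T = T_crit, width = pk$fwhm, peak = pk$t_peak,
               seed = config$seed)
  })
  tab <- do.call(rbind, rows)
  spread <- (max(tab$width) - min(tab$width)) / min(tab$width)
  structure(
    list(kind = "noiseless", table = tab, width_spread = spread,
         predicted_width = if (config$model == "sbf-sin" &&
                               config$spec$spacing == "equal")
           noiseless_width(config$spec) else NA_real_,
         config = config),
    class = "sbf_report"
  )
}

#' Scalar-property experiment
#'
#' For each noise level, measures the output width at every criterion time
#' and regresses width on criterion time; a linear relation (width
#' proportional to the timed duration) is the scalar property.  Criterion
#' noise gives symmetric Gaussian-like outputs; frequency noise gives skewed,
#' long-tailed outputs.  With `replicates > 1` the whole sweep is repeated
#' with fresh seeds and the slope mean and SD across replicates are reported.
#'
#' @param config An [experiment_config()] with `noise_target` `"criterion"`
#'   or `"frequency"`.
#' @return An object of class `"sbf_report"`: `table` with one row per
#'   (replicate, sigma, T); `fits` a data frame with one row per (replicate,
#'   sigma) regression; `slopes` the per-sigma summary (mean and SD across
#'   replicates).
#' @export
run_scalar_experiment <- function(config) {
  stopifnot(inherits(config, "sbf_config"),
            config$noise_target %in% c("criterion", "frequency"))
  dur <- config$grid_span * max(config$criteria)
  # frequency noise evaluates ML waveforms at sped-up clock times
  if (config$noise_target == "frequency" && config$model == "sbf-ml") {
    dur <- dur * (1 + 4 * max(config$sigmas))
  }
  ms <- model_states(config, duration = dur)
  rows <- list(); fits <- list()
  for (rep in seq_len(config$replicates)) {
    for (s in config$sigmas) {
      res <- lapply(config$criteria, function(T_crit) {
        seed <- derive_seed(config$seed, rep, round(1e6 * s), round(100 * T_crit))
        m <- if (config$noise_target == "criterion") {
          criterion_width(ms, config, T_crit, s, seed)
        } else {
          frequency_trace_metrics(ms, config, T_crit, s, seed)
        }
        cbind(data.frame(replicate = rep, sigma = s, T = T_crit, seed = seed),
              as.data.frame(m))
      })
      tab <- do.call(rbind, res)
      rows[[length(rows) + 1L]] <- tab
      reg <- scalar_regression(tab$T, tab$width)
      fits[[length(fits) + 1L]] <- data.frame(
        replicate = rep, sigma = s, slope = reg$slope,
        intercept = reg$intercept, r2 = reg$r2)
    }
  }
  tab <- do.call(rbind, rows)
  fits <- do.call(rbind, fits)
  slopes <- do.call(rbind, lapply(split(fits, fits$sigma), function(d) {
    data.frame(sigma = d$sigma[1], slope_mean = mean(d$slope),
               slope_sd = if (nrow(d) > 1) sd(d$slope) else NA_real_,
               r2_mean = mean(d$r2))
  }))
  rownames(slopes) <- NULL
  structure(
    list(kind = paste0("scalar-", config$noise_target), table = tab,
         fits = fits, slopes = slopes, config = config),
    class = "sbf_report"
  )
}

#' @export
print.sbf_report <- function(x, ...) {
  cat(sprintf("SBF experiment report (%s), %d rows\n", x$kind, nrow(x$table)))
  if (!is.null(x$slopes)) {
    print(x$slopes, row.names = FALSE)
  } else if (!is.null(x$width_spread)) {
    cat(sprintf("  widths: %s (max relative spread %.3g%%)\n",
                paste(signif(x$table$width, 4), collapse = ", "),
                100 * x$width_spread))
  }
  invisible(x)
}

#' Frequency-noise closed-form sweep
#'
#' Evaluates the infinite-band Gaussian-frequency-noise output on a dense
#' grid for each noise SD, measures the half-width points in normalized time
#' (`t / t_peak`), and fits (i) the quadratic of the skewness ratio
#' `tau2/tau1` over the full sweep and (ii) the line of the half-height width
#' for `sigma_f < 0.5`.
#'
#' @param sigma_grid Noise SDs in (0, 1].
#' @param T_crit Criterion time (the normalized-time results do not depend on
#'   it).
#' @param n_grid Number of time samples.
#' @param span Grid extent as a multiple of `T_crit` (the long tail at large
#'   `sigma_f` needs a generous span).
#' @return An object of class `"sbf_report"` with `table` (per-sigma metrics),
#'   `quad` (skewness quadratic) and `lin` (width line, `sigma_f < 0.5`).
#' @export
run_fig5_sweep <- function(sigma_grid = seq(0.025, 1, by = 0.025),
                           T_crit = 10, n_grid = 400001, span = 60) {
  stopifnot(all(sigma_grid > 0), all(sigma_grid <= 1))
  grid <- seq(1e-4 * T_crit, span * T_crit, length.out = n_grid)
  rows <- lapply(sigma_grid, function(s) {
    pk <- half_width_points(frequency_output_infinite(T_crit, s, grid),
                            normalized_time = TRUE)
    data.frame(sigma_f = s, t_peak = pk$t_peak, x1 = pk$x1, x2 = pk$x2,
               tau1 = pk$tau1, tau2 = pk$tau2, ratio = pk$skew_ratio,
               width_norm = pk$fwhm)
  })
  tab <- do.call(rbind, rows)
  lo <- tab$sigma_f < 0.5
  structure(
    list(kind = "fig5-sweep", table = tab,
         quad = if (nrow(tab) >= 3)
           skew_quadratic_fit(tab$sigma_f, tab$ratio) else NULL,
         lin = if (sum(lo) >= 3)
           width_linear_fit(tab$sigma_f[lo], tab$width_norm[lo]) else NULL,
         config = list(sigma_grid = sigma_grid, T_crit = T_crit,
                       n_grid = n_grid, span = span)),
    class = "sbf_report"
  )
}
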