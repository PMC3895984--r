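# Closed-form output functions of the SBF circuit.
#
# All forms are derived from the coincidence readout
#   out(t) = sum_i w_i a cos(2 pi f_i t),  w_i = <cos(2 pi f_i T_j)>_j
# by product-to-sum expansion and, for the infinite-band limits, replacing the
# frequency comb by an integral.  Each form is cross-validated in the test
# suite against brute-force summation / Monte-Carlo averaging of the
# simulator, which is the arbiter for any transcription ambiguity.

# Dirichlet-type kernel sum_k cos(2 pi f_k x) for the equally spaced comb:
#   cos(a0 x) sin(b0 x) / sin(b0 x / N)
# with removable singularities where sin(b0 x / N) = 0.
dirichlet_sum <- function(x, a0, b0, n) {
  u <- b0 * x
  s <- sin(u / n)
  out <- ifelse(abs(s) < 1e-12,
                n * cos(u) / cos(u / n),   # L'Hopital at the singularity
                sin(u) / s)
  cos(a0 * x) * out
}

#' Band constants of the noiseless closed form
#'
#' `a0 = pi (f_max + f_min - df)` (carrier) and `b0 = pi (f_max - f_min)`
#' (envelope) for the equally spaced comb.
#'
#' @param spec An [osc_bank_spec()].
#' @return List with `a0`, `b0`, `df`, `n` (radians/s except `n`).
#' @export
band_constants <- function(spec) {
  df <- (spec$f_max - spec$f_min) / spec$n_osc
  list(a0 = pi * (spec$f_max + spec$f_min - df),
       b0 = pi * (spec$f_max - spec$f_min),
       df = df, n = spec$n_osc)
}

#' Noiseless output function (closed form)
#'
#' For the equally spaced comb the coincidence output is a beat pattern
#' centred on the criterion time:
#' `out(t) = a/2 [ D(t - T) + D(t + T) ] / norm` where
#' `D(x) = cos(a0 x) sin(b0 x)/sin(b0 x / N)` and
#' `norm = max_i |cos(2 pi f_i T)|` is the weight normalization.  The
#' envelope of the `t - T` term is `sin(b0 x)/(2 sin(b0 x/N))`, which tends
#' to `N/2` at the peak and has zeros at `b0 (t - T) = k pi`.
#'
#' @param spec An [osc_bank_spec()] (equal spacing).
#' @param T_crit Criterion time in seconds.
#' @param grid Time grid in seconds.
#' @return An [sbf_trace()].
#' @export
noiseless_output <- function(spec, T_crit, grid) {
  k <- band_constants(spec)
  freqs <- make_frequencies(spec)
  norm_const <- max(abs(cos(2 * pi * freqs * T_crit)))
  val <- 0.5 * spec$amplitude *
    (dirichlet_sum(grid - T_crit, k$a0, k$b0, k$n) +
     dirichlet_sum(grid + T_crit, k$a0, k$b0, k$n)) / norm_const
  sbf_trace(grid, val, meta = list(provenance = "analytic",
                                   form = "noiseless", criterion = T_crit))
}

#' Envelope of the noiseless output
#'
#' `env(x) = sin(b0 x) / (2 sin(b0 x / N))` as a function of the offset
#' `x = t - T` from the criterion; `env(0) = N/2`.
#'
#' @param spec An [osc_bank_spec()].
#' @param x Offset from the criterion time, seconds.
#' @return Numeric vector.
#' @export
noiseless_envelope <- function(spec, x) {
  k <- band_constants(spec)
  u <- k$b0 * x
  s <- sin(u / k$n)
  ifelse(abs(s) < 1e-12, k$n * cos(u) / cos(u / k$n), sin(u) / s) / 2
}

#' Width of the noiseless output
#'
#' Solves `env(sigma/2) = env(0)/2` on the envelope (half of the maximum
#' amplitude), by root bracketing on the main lobe.  The result depends only
#' on the band (it scales as `1/b0`) and is independent of the criterion
#' time: the noiseless circuit violates time-scale invariance.
#'
#' @param spec An [osc_bank_spec()].
#' @param T_crit Criterion time (unused by the closed form; accepted to make
#'   the T-independence explicit in calling code).
#' @return Width in seconds (full width at half maximum of the envelope).
#' @export
noiseless_width <- function(spec, T_crit = NULL) {
  k <- band_constants(spec)
  half <- function(x) noiseless_envelope(spec, x) - k$n / 4
  lobe <- pi / k$b0              # first envelope zero
  root <- uniroot(half, c(1e-12, lobe * (1 - 1e-9)), tol = 1e-12)
  2 * root$root
}

# int_{f1}^{f2} exp(-alpha f^2) cos(beta f) df via the complex error function:
#   (sqrt(pi)/(2 sqrt(alpha))) exp(-beta^2/(4 alpha)) *
#     Re[ erf(sqrt(alpha) f - i beta/(2 sqrt(alpha))) ]_{f1}^{f2}
# erfz overflows once |Im z| = |beta|/(2 sqrt(alpha)) is large (the huge
# exp(Im^2) is cancelled analytically by the prefactor); in that
# fast-oscillation regime the integral is evaluated by its integration-by-
# parts asymptote, whose relative error is O(2 alpha f / beta^2) < 1e-3 at
# the switch point.
gauss_cos_integral <- function(alpha, beta, f1, f2) {
  stopifnot(alpha > 0)
  sa <- sqrt(alpha)
  out <- numeric(length(beta))
  safe <- abs(beta) / (2 * sa) <= 25
  if (any(safe)) {
    b <- beta[safe]
    zi <- -1i * b / (2 * sa)
    amp <- sqrt(pi) / (2 * sa) * exp(-b^2 / (4 * alpha))
    out[safe] <- amp * Re(pracma::erfz(sa * f2 + zi) - pracma::erfz(sa * f1 + zi))
  }
  if (any(!safe)) {
    b <- beta[!safe]
    out[!safe] <- (exp(-alpha * f2^2) * sin(b * f2) -
                   exp(-alpha * f1^2) * sin(b * f1)) / b
  }
  out
}

#' Output under Gaussian criterion-time noise, infinite band
#'
#' With `T_j = T (1 + xi_j)`, `xi ~ N(0, sigma_T^2)`, and an unbounded
#' frequency pool, the physically realizable term of the expected output
#' (the one centred at `+T`; the mirror image at `-T` lies outside the
#' trial) is a Gaussian centred exactly on the criterion:
#' `out(t) = exp(-(t - T)^2 / (2 (T sigma_T)^2))`.
#' Width `sigma_out = T sigma_T`: accurate timing and the scalar property.
#'
#' @param T_crit Criterion time (s).
#' @param sigma_T Fractional SD of the criterion noise (> 0).
#' @param grid Time grid (s).
#' @return An [sbf_trace()] (max-normalized shape).
#' @export
criterion_output_infinite <- function(T_crit, sigma_T, grid) {
  stopifnot(sigma_T > 0)
  s <- T_crit * sigma_T
  val <- exp(-(grid - T_crit)^2 / (2 * s^2))
  sbf_trace(grid, val, meta = list(provenance = "analytic",
                                   form = "criterion_infinite",
                                   criterion = T_crit, sigma_T = sigma_T))
}

#' Output under Gaussian criterion-time noise, finite band
#'
#' Restricting the oscillator pool to `(f_min, f_max)` multiplies each
#' Gaussian term by a band amplitude expressed through the difference of two
#' (complex-argument) error functions; as the band widens the normalized
#' shape converges to [criterion_output_infinite()].  The trace is symmetric
#' about `t = T` with Gaussian-fit width `T sigma_T`.
#'
#' @param spec An [osc_bank_spec()] giving the band.
#' @param T_crit Criterion time (s).
#' @param sigma_T Fractional SD of the criterion noise (> 0).
#' @param grid Time grid (s).
#' @return An [sbf_trace()].
#' @export
criterion_output_finite <- function(spec, T_crit, sigma_T, grid) {
  stopifnot(sigma_T > 0)
  alpha <- 2 * pi^2 * T_crit^2 * sigma_T^2
  val <- 0.5 * (gauss_cos_integral(alpha, 2 * pi * (grid - T_crit),
                                   spec$f_min, spec$f_max) +
                gauss_cos_integral(alpha, 2 * pi * (grid + T_crit),
                                   spec$f_min, spec$f_max))
  sbf_trace(grid, val, meta = list(provenance = "analytic",
                                   form = "criterion_finite",
                                   criterion = T_crit, sigma_T = sigma_T,
                                   band = c(spec$f_min, spec$f_max)))
}

#' Output under Gaussian frequency noise, infinite band
#'
#' With probe-trial frequencies `f (1 + xi)`, `xi ~ N(0, sigma_f^2)`, and an
#' unbounded pool, the physically realizable term of the expected output is
#' `out(t) = (1/t) exp(-(t - T)^2 / (2 sigma_f^2 t^2))`:
#' a Gaussian-like peak with a long right tail, peaking near
#' `T / (1 + sigma_f^2)`.  The `t`-dependent width of the local Gaussian
#' factor is what skews the shape.
#'
#' @param T_crit Criterion time (s).
#' @param sigma_f Fractional SD of the frequency noise (> 0).
#' @param grid Time grid (s); `t = 0` is assigned the limit value 0.
#' @return An [sbf_trace()].
#' @export
frequency_output_infinite <- function(T_crit, sigma_f, grid) {
  stopifnot(sigma_f > 0)
  val <- numeric(length(grid))
  pos <- grid > 0
  tp <- grid[pos]
  val[pos] <- exp(-(tp - T_crit)^2 / (2 * sigma_f^2 * tp^2)) / tp
  sbf_trace(grid, val, meta = list(provenance = "analytic",
                                   form = "frequency_infinite",
                                   criterion = T_crit, sigma_f = sigma_f))
}

#' Output under Gaussian frequency noise, finite band
#'
#' Finite-band counterpart of [frequency_output_infinite()]: the expected
#' output is the band integral of
#' `cos(2 pi f T) cos(2 pi f t) exp(-2 pi^2 sigma_f^2 t^2 f^2)`, expressed
#' through the difference of two complex-argument error functions.  Converges
#' to the infinite-band form as the band widens.
#'
#' @param spec An [osc_bank_spec()] giving the band.
#' @param T_crit Criterion time (s).
#' @param sigma_f Fractional SD of the frequency noise (> 0).
#' @param grid Time grid (s).
#' @return An [sbf_trace()].
#' @export
frequency_output_finite <- function(spec, T_crit, sigma_f, grid) {
  stopifnot(sigma_f > 0)
  val <- vapply(grid, function(t) {
    alpha <- 2 * pi^2 * sigma_f^2 * t^2
    if (alpha < 1e-14) {
      # no damping yet: plain band integral of the cosine product
      bcos <- function(beta) {
        if (abs(beta) < 1e-12) return(spec$f_max - spec$f_min)
        (sin(beta * spec$f_max) - sin(beta * spec$f_min)) / beta
      }
      0.5 * (bcos(2 * pi * (t - T_crit)) + bcos(2 * pi * (t + T_crit)))
    } else {
      0.5 * (gauss_cos_integral(alpha, 2 * pi * (t - T_crit),
                                spec$f_min, spec$f_max) +
             gauss_cos_integral(alpha, 2 * pi * (t + T_crit),
                                spec$f_min, spec$f_max))
    }
  }, numeric(1))
  sbf_trace(grid, val, meta = list(provenance = "analytic",
                                   form = "frequency_finite",
                                   criterion = T_crit, sigma_f = sigma_f,
                                   band = c(spec$f_min, spec$f_max)))
}

#' Predicted output peak location
#'
#' Criterion-time noise shifts the peak to `T (1 + gamma_T)`; frequency noise
#' to `T / (1 + gamma_f)`.  The constants depend on the noise distribution;
#' for Gaussian noise `gamma_T = 0` (accurate timing) and
#' `gamma_f = sigma_f^2`.
#'
#' @param noise_target `"criterion"` or `"frequency"`.
#' @param T_crit Criterion time (s).
#' @param gamma Distribution-dependent constant (>= 0).  For Gaussian noise
#'   pass 0 (criterion) or `sigma_f^2` (frequency).
#' @return List with `peak` (s), `gamma` and `noise_target`.
#' @export
predicted_peak <- function(noise_target = c("criterion", "frequency"),
                           T_crit, gamma = 0) {
  noise_target <- match.arg(noise_target)
  stopifnot(gamma >= 0)
  peak <- if (noise_target == "criterion") T_crit * (1 + gamma)
          else T_crit / (1 + gamma)
  list(peak = peak, gamma = gamma, noise_target = noise_target)
}
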