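test_that("noiseless envelope has the Dirichlet limit and zeros", {
  spec <- small_spec(100)
  k <- band_constants(spec)
  # removable singularity at the peak tends to N/2
  expect_equal(noiseless_envelope(spec, 0), 50)
  expect_equal(noiseless_envelope(spec, 1e-9), 50, tolerance = 1e-6)
  # zeros where the numerator sine vanishes (denominator does not)
  for (kk in 1:3) {
    expect_lt(abs(noiseless_envelope(spec, kk * pi / k$b0)), 1e-9)
  }
})

test_that("noiseless width is criterion-independent and scales as 1/band", {
  spec <- small_spec(1000)
  expect_equal(noiseless_width(spec, 10), noiseless_width(spec, 30),
               tolerance = 1e-6)
  # doubling the band halves the width
  spec2 <- osc_bank_spec(1000, 8, 16)
  expect_equal(noiseless_width(spec) / noiseless_width(spec2), 2,
               tolerance = 0.01)
  # and the width saturates in the number of oscillators
  expect_equal(noiseless_width(small_spec(100)),
               noiseless_width(small_spec(1000)), tolerance = 0.01)
  # the half-height condition holds on the envelope itself
  w <- noiseless_width(spec)
  expect_equal(noiseless_envelope(spec, w / 2), 1000 / 4, tolerance = 1e-6)
})

test_that("criterion-noise closed forms: accurate, Gaussian, scalar", {
  T0 <- 10; sig <- 0.1
  grid <- seq(5, 15, by = 0.01)
  tr <- criterion_output_infinite(T0, sig, grid)
  expect_equal(grid[which.max(tr$value)], T0)
  fit <- fit_gaussian(tr)
  expect_equal(fit$mu, T0, tolerance = 1e-6)
  expect_equal(fit$sigma, T0 * sig, tolerance = 1e-3 * T0 * sig)
  pk <- half_width_points(tr)
  expect_equal(pk$skew_ratio, 1, tolerance = 1e-6)

  # Gaussian-fit width grows linearly in T with the slope sigma_T; the band
  # must reach low enough that the weight damping width 1/(2 pi T sigma_T)
  # stays in-band for the largest criterion
  spec <- osc_bank_spec(400, 2e-4, 2)
  widths <- vapply(c(5, 10, 20, 30), function(Tc) {
    g <- seq(Tc * 0.5, Tc * 1.5, length.out = 2000)
    fit_gaussian(criterion_output_finite(spec, Tc, sig, g))$sigma
  }, numeric(1))
  reg <- scalar_regression(c(5, 10, 20, 30), widths)
  expect_gt(reg$r2, 0.999)
  expect_equal(reg$slope, sig, tolerance = 0.01)
})

test_that("finite-band forms equal the band integral and converge to the
           infinite-band shapes", {
  spec <- wide_spec()
  Tc <- 5; tt <- seq(3, 7, by = 0.05)
  # quadrature oracle, criterion noise
  sT <- 0.1
  num <- vapply(tt, function(t) {
    integrate(function(fr) cos(2 * pi * fr * Tc) * cos(2 * pi * fr * t) *
                exp(-2 * pi^2 * fr^2 * Tc^2 * sT^2),
              spec$f_min, spec$f_max, rel.tol = 1e-10)$value
  }, numeric(1))
  got <- criterion_output_finite(spec, Tc, sT, tt)$value
  expect_lt(max(abs(got - num)) / max(abs(num)), 1e-8)
  # quadrature oracle, frequency noise
  sf <- 0.15
  num2 <- vapply(tt, function(t) {
    integrate(function(fr) cos(2 * pi * fr * Tc) * cos(2 * pi * fr * t) *
                exp(-2 * pi^2 * sf^2 * t^2 * fr^2),
              spec$f_min, spec$f_max, rel.tol = 1e-10)$value
  }, numeric(1))
  got2 <- frequency_output_finite(spec, Tc, sf, tt)$value
  expect_lt(max(abs(got2 - num2)) / max(abs(num2)), 1e-8)

  # wide-band limit on the peak window
  wspec <- osc_bank_spec(2000, 1e-5, 20)
  g <- seq(5, 30, by = 0.02)
  expect_lt(supnorm_normalized(frequency_output_finite(wspec, 10, 0.2, g),
                               frequency_output_infinite(10, 0.2, g)), 1e-3)
  expect_lt(supnorm_normalized(criterion_output_finite(wspec, 10, 0.1, g),
                               criterion_output_infinite(10, 0.1, g)), 1e-3)
})

test_that("frequency-noise closed form is long-tailed with the predicted peak", {
  T0 <- 10
  g <- seq(0.02, 30, by = 0.02)
  for (sf in c(0.1, 0.2)) {
    tr <- frequency_output_infinite(T0, sf, g)
    pk <- half_width_points(tr)
    expect_gt(pk$tau2, pk$tau1)             # long right tail
    expect_equal(g[which.max(tr$value)],
                 predicted_peak("frequency", T0, sf^2)$peak,
                 tolerance = 0.021)          # within one 0.02 s grid step
  }
  tr <- frequency_output_infinite(T0, 0.2, g)
  expect_gt(half_width_points(tr)$skew_ratio, 1)
})

test_that("monte-carlo simulation converges to the closed forms", {
  # criterion noise: averaged weights at n = 1e5 FI trials
  spec <- wide_spec(400)
  f <- make_frequencies(spec)
  Tc <- 3; sT <- 0.1
  g <- seq(1.5, 4.5, by = 0.03)
  mem <- encode_reference(f, Tc, 1e5, noise_spec("gaussian", sT, seed = 21))
  mc <- probe_output(mem, grid = g)
  cf <- criterion_output_finite(spec, Tc, sT, g)
  expect_lt(supnorm_normalized(mc, cf), 0.02)

  # frequency noise, independent per-oscillator multipliers: within-trial
  # averaging makes the trial mean converge fast to the same expectation
  sf <- 0.15
  mem0 <- encode_reference(f, Tc, 1)
  cf2 <- frequency_output_finite(spec, Tc, sf, g)
  mc_po <- probe_output(mem0, grid = g,
                        freq_noise = noise_spec("gaussian", sf, seed = 23),
                        n_probe_trials = 2000, mode = "per_oscillator",
                        average = "signed")
  expect_lt(supnorm_normalized(mc_po, cf2), 0.02)

  # frequency noise, common per-trial multiplier: same expectation, but the
  # whole bank swings together so the averaging noise is ~sqrt(N) larger
  mc_pt <- probe_output(mem0, grid = g,
                        freq_noise = noise_spec("gaussian", sf, seed = 22),
                        n_probe_trials = 1e4, mode = "per_trial",
                        average = "signed")
  expect_lt(supnorm_normalized(mc_pt, cf2), 0.08)
  # ... and agrees with the infinite-band form on this wide band too
  cf3 <- frequency_output_infinite(Tc, sf, g)
  expect_lt(supnorm_normalized(mc_pt, cf3), 0.09)
})

test_that("peak prediction formulas", {
  expect_equal(predicted_peak("criterion", 10, 0)$peak, 10)
  expect_equal(predicted_peak("frequency", 10, 0)$peak, 10)
  expect_equal(predicted_peak("frequency", 30, 0.2^2)$peak, 30 / 1.04)
  expect_equal(predicted_peak("frequency", 10, 0.1^2)$peak, 9.90099,
               tolerance = 1e-6)
  expect_error(predicted_peak("frequency", 10, -1))
})
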