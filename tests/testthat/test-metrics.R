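test_that("upper envelope dominates the raw trace and recovers known envelopes", {
  spec <- small_spec(1000)
  T0 <- 3
  grid <- probe_grid(spec, T0)
  tr <- noiseless_output(spec, T0, grid)
  env <- upper_envelope(tr)
  expect_true(all(env$value >= tr$value - 1e-9))

  # |sin| has a constant envelope
  t <- seq(0, 2, by = 1e-3)
  c0 <- 0.7
  tr2 <- sbf_trace(t, c0 * abs(sin(2 * pi * 10 * t)))
  env2 <- upper_envelope(tr2)
  mid <- t > 0.2 & t < 1.8
  expect_lt(max(abs(env2$value[mid] - c0)) / c0, 0.01)

  # near the peak the rectified envelope knots follow the analytic envelope
  envr <- upper_envelope(tr, rectify = TRUE)
  kt <- envr$meta$knots$time; kv <- envr$meta$knots$value
  near <- abs(kt - T0) < 0.1
  predicted <- abs(noiseless_envelope(spec, kt[near] - T0))
  expect_lt(max(abs(kv[near] - predicted)) / max(predicted), 0.02)

  expect_error(upper_envelope(gaussian_trace()), "maxima")
})

test_that("gaussian fit recovers exact and near-gaussian shapes", {
  tr <- gaussian_trace(mu = 10, sigma = 1)
  fit <- fit_gaussian(tr)
  expect_equal(fit$mu, 10, tolerance = 1e-6)
  expect_equal(fit$sigma, 1, tolerance = 1e-6)
  expect_gt(fit$r2, 1 - 1e-10)

  # long tail degrades the fit relative to a symmetric trace of equal sigma
  g <- seq(0.05, 30, by = 0.01)
  r2_crit <- fit_gaussian(criterion_output_infinite(10, 0.3, g))$r2
  r2_freq <- fit_gaussian(frequency_output_infinite(10, 0.3, g))$r2
  expect_gt(r2_crit, r2_freq)

  # offset variant absorbs a constant background
  tr3 <- gaussian_trace(mu = 5, sigma = 0.5, offset = 0.2, hi = 10)
  fit3 <- fit_gaussian(tr3, offset = TRUE)
  expect_equal(fit3$sigma, 0.5, tolerance = 1e-4)
  expect_equal(fit3$offset, 0.2, tolerance = 1e-4)
})

test_that("half-width points quantify width and skewness", {
  tr <- gaussian_trace(mu = 10, sigma = 1)
  pk <- half_width_points(tr)
  expect_equal(pk$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-3)
  expect_equal(pk$skew_ratio, 1, tolerance = 1e-6)
  expect_equal(pk$x1 + pk$fwhm, pk$x2)
  expect_true(pk$x1 < pk$t_peak && pk$t_peak < pk$x2)

  # consistency between the two width conventions on a true Gaussian
  fit <- fit_gaussian(tr)
  expect_equal(pk$fwhm / fit$sigma, 2.3548, tolerance = 0.01)
  expect_equal(fit$mu, pk$t_peak, tolerance = tr$time[2] - tr$time[1])

  # skewness of the long-tailed frequency-noise form at sigma_f = 0.5
  # agrees with the quadratic trend fitted over the whole sweep
  g <- seq(1e-3, 600, length.out = 400001)
  pk2 <- half_width_points(frequency_output_infinite(10, 0.5, g),
                           normalized_time = TRUE)
  expect_equal(pk2$skew_ratio, 0.902 + 3.74 * 0.5 - 1.27 * 0.25,
               tolerance = 0.02 * 2.45)

  # truncation errors name the missing side
  half_gauss <- sbf_trace(seq(9, 20, by = 0.01),
                          exp(-(seq(9, 20, by = 0.01) - 10)^2 / 2))
  expect_error(half_width_points(half_gauss), "left")
  half_gauss2 <- sbf_trace(seq(0, 10.5, by = 0.01),
                           exp(-(seq(0, 10.5, by = 0.01) - 10)^2 / 2))
  expect_error(half_width_points(half_gauss2), "right")
})

test_that("scalar regression behaves like ordinary least squares", {
  # exact-line inputs trigger summary.lm's perfect-fit warning by design
  fit <- suppressWarnings(scalar_regression(c(10, 20, 30), c(1, 2, 3)))
  expect_equal(fit$slope, 0.1)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1)

  # affine equivariance: scaling widths scales slope and intercept exactly
  a <- c(5, 10, 20, 30); w <- c(0.6, 1.1, 2.0, 3.1)
  f1 <- scalar_regression(a, w)
  f2 <- scalar_regression(a, 3 * w)
  expect_equal(f2$slope, 3 * f1$slope)
  expect_equal(f2$intercept, 3 * f1$intercept)
  expect_equal(f2$r2, f1$r2)

  # repeated abscissa with noise: finite result, no crash
  f3 <- scalar_regression(c(10, 10, 20, 30), c(1, 1.2, 2, 3))
  expect_true(is.finite(f3$slope) && f3$r2 < 1)
  expect_error(scalar_regression(c(5, 5, 5), c(1, 2, 3)), "degenerate")
  expect_error(scalar_regression(c(1, 2), c(1, 2)), "3")
})

test_that("quadratic and linear sweep fits recover synthetic coefficients", {
  s <- seq(0.05, 1, by = 0.05)
  # suppressWarnings: summary.lm flags these noise-free fits as "essentially
  # perfect", which is the point of the test
  q <- suppressWarnings(skew_quadratic_fit(s, rep(1, length(s))))
  expect_equal(q$c0, 1, tolerance = 1e-12)
  expect_equal(q$c1, 0, tolerance = 1e-12)
  expect_equal(q$c2, 0, tolerance = 1e-12)

  q2 <- suppressWarnings(skew_quadratic_fit(s, 0.9 + 3.7 * s - 1.3 * s^2))
  expect_equal(q2$c0, 0.9, tolerance = 1e-10)
  expect_equal(q2$c1, 3.7, tolerance = 1e-10)
  expect_equal(q2$c2, -1.3, tolerance = 1e-10)

  lf <- suppressWarnings(width_linear_fit(s, 2.3548 * s))
  expect_equal(lf$slope, 2.3548, tolerance = 1e-10)
  expect_equal(lf$intercept, 0, tolerance = 1e-12)
  expect_equal(lf$r2, 1)
})
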