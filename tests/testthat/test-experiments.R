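test_that("noiseless experiment reports criterion-independent widths", {
  cfg <- experiment_config(spec = osc_bank_spec(400, 8, 12),
                           criteria = c(4, 8), noise_target = "none",
                           seed = 3)
  rep <- run_noiseless(cfg)
  expect_equal(nrow(rep$table), 2)
  expect_true(all(c("T", "width", "peak", "seed") %in% names(rep$table)))
  expect_lt(rep$width_spread, 0.02)
  expect_equal(rep$table$width, rep(rep$predicted_width, 2), tolerance = 0.02)
  expect_equal(rep$table$peak, rep$table$T, tolerance = 0.01)
})

test_that("experiments are deterministic given the config seed", {
  cfg <- experiment_config(spec = osc_bank_spec(150, 8, 12),
                           criteria = c(3, 5, 8), noise_target = "criterion",
                           sigmas = 0.1, n_fi_trials = 300, seed = 12)
  a <- run_scalar_experiment(cfg)
  b <- run_scalar_experiment(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$fits, b$fits)
})

test_that("the three noise regimes are distinguishable from reports alone", {
  spec <- osc_bank_spec(500, 8, 12)
  criteria <- c(4, 8, 12)
  seed <- 5

  none <- run_noiseless(experiment_config(spec = spec, criteria = criteria,
                                          noise_target = "none", seed = seed))
  crit <- run_scalar_experiment(experiment_config(
    spec = spec, criteria = criteria, noise_target = "criterion",
    sigmas = 0.15, n_fi_trials = 1000, seed = seed))
  freq <- run_scalar_experiment(experiment_config(
    spec = spec, criteria = criteria, noise_target = "frequency",
    sigmas = 0.15, n_probe_trials = 150, seed = seed))

  # noiseless: constant width (about 0.3 s for the alpha band, at every T)
  expect_lt(none$width_spread, 0.02)
  # criterion noise: width grows with T
  expect_gt(crit$fits$slope, 0.05)
  expect_gt(crit$fits$r2, 0.8)
  # frequency noise: width grows with T and the trace is right-skewed
  expect_gt(freq$fits$slope, 0.05)
  expect_gt(freq$fits$r2, 0.8)
  expect_true(all(freq$table$skew_ratio > 1))
  # measured peaks sit near the criterion for both noisy regimes
  expect_equal(crit$table$mu, crit$table$T, tolerance = 0.1 * max(criteria))
})

test_that("fixtures are deterministic and round-trip losslessly", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  f1 <- generate_fixtures(d1, seed = 9)
  f2 <- generate_fixtures(d2, seed = 9)
  expect_identical(basename(f1), basename(f2))
  for (k in seq_along(f1)) {
    expect_identical(unname(tools::md5sum(f1[k])), unname(tools::md5sum(f2[k])),
                     label = basename(f1[k]))
  }

  mem <- read_memory_csv(file.path(d1, "memory.csv"))
  expect_s3_class(mem, "sbf_memory")
  expect_equal(max(abs(mem$weights)), 1, tolerance = 1e-12)

  tr <- read_trace_csv(file.path(d1, "trace_noiseless.csv"))
  expect_s3_class(tr, "sbf_trace")
  tr0 <- read_trace_csv(file.path(d1, "trace_criterion_noise.csv"))
  env <- upper_envelope(tr0, rectify = TRUE)
  sel <- env$time >= 0.8 & env$time <= 5
  expect_lt(abs(env$time[sel][which.max(env$value[sel])] - 2), 0.5)

  # round trip through write/read preserves the numbers
  p <- file.path(tempdir(), "rt.csv")
  write_trace_csv(tr, p)
  tr2 <- read_trace_csv(p)
  expect_equal(tr2$time, tr$time)
  expect_equal(tr2$value, tr$value)
})

test_that("fig5 sweep approaches the ratio-1 symmetric limit as sigma -> 0", {
  # the skew ratio decays to 1 like ~1 + 2.4 sigma; tiny sigma needs a dense,
  # short grid to resolve the narrow peak
  lim <- run_fig5_sweep(sigma_grid = c(0.002, 0.005, 0.02), n_grid = 200001,
                        span = 5)
  expect_equal(lim$table$ratio[1], 1, tolerance = 0.01)
  expect_true(all(diff(lim$table$ratio) > 0))
  sw <- run_fig5_sweep(sigma_grid = c(0.1, 0.3, 0.6), n_grid = 150001,
                       span = 40)
  expect_true(all(diff(sw$table$ratio) > 0))
})
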