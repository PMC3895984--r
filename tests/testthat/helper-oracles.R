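# Shared fixtures and independent oracles used across test files.

# Small alpha-band spec for fast tests.
small_spec <- function(n = 100) osc_bank_spec(n, 8, 12)

# Wide low-frequency band where the mean-field closed forms are
# non-degenerate (the Gaussian damping keeps appreciable weight in-band).
wide_spec <- function(n = 400) osc_bank_spec(n, 0.02, 2)

# Brute-force double-sum oracle for the noiseless output: the coincidence
# readout computed directly from the definition, independent of the
# closed-form path.
brute_noiseless <- function(spec, T_crit, grid) {
  f <- make_frequencies(spec)
  w <- cos(2 * pi * f * T_crit)
  w <- w / max(abs(w))
  spec$amplitude * drop(cos(2 * pi * outer(grid, f)) %*% w)
}

# Gaussian trace generator for metric self-tests.
gaussian_trace <- function(mu = 10, sigma = 1, lo = 0, hi = 20, dt = 0.01,
                           amplitude = 1, offset = 0) {
  t <- seq(lo, hi, by = dt)
  sbf_trace(t, amplitude * exp(-(t - mu)^2 / (2 * sigma^2)) + offset)
}

# Sup-norm distance between max-normalized traces on a common grid.
supnorm_normalized <- function(a, b) {
  max(abs(a$value / max(a$value) - b$value / max(b$value)))
}
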