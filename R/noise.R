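#' Noise specification
#'
#' Describes the multiplicative noise applied either to the memorized
#' criterion time (`T_j = T (1 + xi_j)`) or to the oscillator frequencies
#' during probe trials (`f -> f (1 + xi)`).  `xi` has zero mean and standard
#' deviation `sigma` for every distribution family, so `sigma` is always the
#' fractional SD of the perturbed quantity.
#'
#' Families: `"gaussian"` (`xi ~ N(0, sigma^2)`); `"uniform"`
#' (`xi ~ U(-sqrt(3) sigma, sqrt(3) sigma)`); `"poisson"`
#' (`xi = (P(lambda) - lambda) * sigma / sqrt(lambda)`, a centred and scaled
#' Poisson count so the lattice spacing is `sigma/sqrt(lambda)`); `"none"`
#' (all multipliers exactly 1).
#'
#' @param distribution One of `"none"`, `"gaussian"`, `"uniform"`, `"poisson"`.
#' @param sigma Fractional standard deviation (>= 0; must be 0 for `"none"`).
#' @param seed Integer seed making draws reproducible.
#' @param lambda Poisson rate parameter (default 100).
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(distribution = c("none", "gaussian", "uniform", "poisson"),
                       sigma = 0, seed = NULL, lambda = 100) {
  distribution <- match.arg(distribution)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  }
  if (distribution == "none" && sigma != 0) {
    stop("`sigma` must be 0 when distribution = \"none\"", call. = FALSE)
  }
  if (distribution != "none" && sigma == 0) distribution <- "none"
  if (lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  structure(
    list(distribution = distribution, sigma = sigma, seed = seed,
         lambda = lambda),
    class = "noise_spec"
  )
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("Noise: %s, sigma = %g%s\n", x$distribution, x$sigma,
              if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  invisible(x)
}

#' Draw multiplicative noise factors
#'
#' Returns `n` factors `1 + xi` with `E[xi] = 0` and `SD[xi] = sigma`,
#' reproducible given the spec's seed.
#'
#' @param noise A [noise_spec()].
#' @param n Number of draws (>= 1).
#' @param seed Optional seed overriding `noise$seed`.
#' @return Numeric vector of length `n`.
#' @export
sample_multipliers <- function(noise, n, seed = NULL) {
  stopifnot(inherits(noise, "noise_spec"), n >= 1)
  n <- as.integer(n)
  if (noise$distribution == "none") return(rep(1, n))
  seed <- if (!is.null(seed)) seed else noise$seed
  draw <- function() {
    switch(noise$distribution,
      gaussian = rnorm(n, 0, noise$sigma),
      uniform  = runif(n, -sqrt(3) * noise$sigma, sqrt(3) * noise$sigma),
      poisson  = (rpois(n, noise$lambda) - noise$lambda) *
                   noise$sigma / sqrt(noise$lambda),
      stop("unknown noise distribution", call. = FALSE)
    )
  }
  xi <- if (is.null(seed)) draw() else with_seed(seed, draw())
  1 + xi
}
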