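#' Upper envelope of an oscillatory trace
#'
#' The monotone-grid trace through the local maxima of the raw output,
#' linearly interpolated back onto the original grid.  Each discrete maximum
#' is refined by a parabola through its three bracketing samples (the sampled
#' value undershoots the true carrier peak by up to half a grid step of
#' phase), and endpoints are carried over so the envelope covers the full
#' span.
#'
#' @param trace An [sbf_trace()].
#' @param rectify Take `|value|` before locating maxima (envelope of the
#'   rectified output); default `FALSE`.
#' @param refine Parabolic refinement of the maxima (default `TRUE`).
#' @return An [sbf_trace()] on the same grid.
#' @export
upper_envelope <- function(trace, rectify = FALSE, refine = TRUE) {
  stopifnot(inherits(trace, "sbf_trace"))
  y <- if (rectify) abs(trace$value) else trace$value
  n <- length(y)
  mx <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1
  if (length(mx) < 3) {
    stop("fewer than 3 local maxima: not an oscillatory trace; fit the raw trace instead",
         call. = FALSE)
  }
  tk <- trace$time[mx]; yk <- y[mx]
  if (refine) {
    # vertex of the parabola through (t_{m-1}, t_m, t_{m+1})
    y0 <- y[mx - 1]; y1 <- y[mx]; y2 <- y[mx + 1]
    denom <- y0 - 2 * y1 + y2
    ok <- is.finite(denom) & abs(denom) > .Machine$double.eps
    d <- ifelse(ok, 0.5 * (y0 - y2) / denom, 0)
    d <- pmax(pmin(d, 0.5), -0.5)
    h <- trace$time[mx + 1] - trace$time[mx]
    tk <- trace$time[mx] + d * h
    yk <- y1 - 0.25 * (y0 - y2) * d
    o <- order(tk)
    tk <- tk[o]; yk <- yk[o]
  }
  xs <- c(trace$time[1], tk, trace$time[n])
  ys <- c(max(yk[1], y[1]), yk, max(yk[length(yk)], y[n]))
  keep <- !duplicated(xs)
  env <- approx(xs[keep], ys[keep], xout = trace$time)$y
  env <- pmax(env, y)   # chords may undercut the raw trace where it is concave
  meta <- trace$meta; meta$envelope <- TRUE
  meta$knots <- list(time = tk, value = yk)
  sbf_trace(trace$time, env, meta)
}

#' Gaussian fit of an output function
#'
#' Nonlinear least squares of `A exp(-(t - mu)^2 / (2 sigma^2)) (+ B)` to the
#' trace, restricted to the window where the value is at least `window` times
#' the maximum (10 percent by default, so a long tail does not bias the fit).
#' Moment-based initialization; optional constant background `B` for traces
#' sitting on a noise floor.
#'
#' @param trace An [sbf_trace()].
#' @param window Fraction of the maximum defining the fitted sub-trace.
#' @param offset Include a constant background term.
#' @param t_min Ignore samples before this time (guards against the
#'   stimulus-onset coincidence at `t = 0`).
#' @return List with `mu`, `sigma`, `amplitude`, `offset`, `r2` (coefficient
#'   of determination on the fitted window) and `fitted_window` (time range).
#' @export
fit_gaussian <- function(trace, window = 0.1, offset = FALSE, t_min = 0) {
  stopifnot(inherits(trace, "sbf_trace"))
  keep <- trace$time >= t_min
  t <- trace$time[keep]; y <- trace$value[keep]
  base <- if (offset) min(y) else 0
  sel <- (y - base) >= window * (max(y) - base)
  tw <- t[sel]; yw <- y[sel]
  if (length(tw) < 5) stop("too few points above the fit window", call. = FALSE)
  mu0 <- tw[which.max(yw)]
  wts <- pmax(yw - base, 0)
  s0 <- sqrt(sum(wts * (tw - mu0)^2) / sum(wts))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(tw)) / 4
  a0 <- max(yw) - base

  df <- if (offset) data.frame(t = t, y = y) else data.frame(t = tw, y = yw)
  fit <- tryCatch(
    if (offset) {
      minpack.lm::nlsLM(y ~ A * exp(-(t - mu)^2 / (2 * s^2)) + B, data = df,
                        start = list(A = a0, mu = mu0, s = s0, B = base),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ A * exp(-(t - mu)^2 / (2 * s^2)), data = df,
                        start = list(A = a0, mu = mu0, s = s0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) {
      stop(sprintf(
        "Gaussian fit did not converge (init mu = %.3g, sigma = %.3g): %s",
        mu0, s0, conditionMessage(e)), call. = FALSE)
    })
  cf <- coef(fit)
  res <- df$y - predict(fit)
  r2 <- 1 - sum(res^2) / sum((df$y - mean(df$y))^2)
  list(mu = unname(cf["mu"]), sigma = abs(unname(cf["s"])),
       amplitude = unname(cf["A"]),
       offset = if (offset) unname(cf["B"]) else 0,
       r2 = r2, fitted_window = range(df$t))
}

#' Peak and half-width characterization
#'
#' Locates the global maximum and the two half-height crossings `x1 < t_peak
#' < x2` (linear interpolation between bracketing grid points), and derives
#' the half-widths `tau1 = t_peak - x1`, `tau2 = x2 - t_peak`, the full width
#' `fwhm = x2 - x1` and the skewness ratio `tau2/tau1` (1 for a symmetric
#' peak, > 1 for a long right tail).
#'
#' @param trace An [sbf_trace()].
#' @param normalized_time Report times in units of `t / t_peak`.
#' @param baseline Constant background subtracted before the half level is
#'   computed (default 0).
#' @return An object of class `"sbf_peak"`.
#' @export
half_width_points <- function(trace, normalized_time = FALSE, baseline = 0) {
  stopifnot(inherits(trace, "sbf_trace"))
  t <- trace$time; y <- trace$value - baseline
  i0 <- which.max(y)
  tp <- t[i0]; yp <- y[i0]
  half <- yp / 2
  below_l <- which(y[seq_len(i0 - 1)] < half)
  if (length(below_l) == 0) {
    stop("trace does not fall below half maximum on the left side", call. = FALSE)
  }
  a <- below_l[length(below_l)]
  x1 <- t[a] + (t[a + 1] - t[a]) * (half - y[a]) / (y[a + 1] - y[a])
  right <- y[i0:length(y)]
  below_r <- which(right < half)
  if (length(below_r) == 0) {
    stop("trace does not fall below half maximum on the right side", call. = FALSE)
  }
  b <- i0 + below_r[1] - 1
  x2 <- t[b - 1] + (t[b] - t[b - 1]) * (half - y[b - 1]) / (y[b] - y[b - 1])
  if (normalized_time) {
    x1 <- x1 / tp; x2 <- x2 / tp; tp_out <- 1
  } else tp_out <- tp
  tau1 <- tp_out - x1; tau2 <- x2 - tp_out
  structure(
    list(t_peak = tp, x1 = x1, x2 = x2, fwhm = x2 - x1,
         tau1 = tau1, tau2 = tau2, skew_ratio = tau2 / tau1,
         normalized_time = normalized_time, peak_value = yp + baseline),
    class = "sbf_peak"
  )
}

#' @export
print.sbf_peak <- function(x, ...) {
  cat(sprintf("Peak at t = %.4g%s; fwhm = %.4g (tau1 = %.4g, tau2 = %.4g); skew ratio = %.4g\n",
              if (x$normalized_time) 1 else x$t_peak,
              if (x$normalized_time) " (normalized time)" else " s",
              x$fwhm, x$tau1, x$tau2, x$skew_ratio))
  invisible(x)
}

#' Scalar-property regression
#'
#' Ordinary least squares of output width on the abscissa (criterion time or
#' noise SD).  A slope significantly above zero with high `r2` across
#' criteria is the hallmark of time-scale invariance.
#'
#' @param abscissa Criterion times (or noise SDs).
#' @param width Measured output widths (same length).
#' @return An object of class `"sbf_scalar_fit"`: `slope`, `intercept`, `r2`,
#'   and the input `pairs`.
#' @export
scalar_regression <- function(abscissa, width) {
  if (length(abscissa) != length(width) || length(abscissa) < 3) {
    stop("need at least 3 (abscissa, width) pairs", call. = FALSE)
  }
  if (length(unique(abscissa)) < 2) {
    stop("degenerate abscissa: all values equal", call. = FALSE)
  }
  fit <- lm(width ~ abscissa)
  s <- summary(fit)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = s$r.squared,
         pairs = data.frame(abscissa = abscissa, width = width)),
    class = "sbf_scalar_fit"
  )
}

#' @export
print.sbf_scalar_fit <- function(x, ...) {
  cat(sprintf("width = %.4g + %.4g * x   (R^2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$r2, nrow(x$pairs)))
  invisible(x)
}

#' Quadratic fit of the skewness ratio versus frequency-noise SD
#'
#' Least-squares quadratic `c0 + c1 sigma + c2 sigma^2` of the half-width
#' ratio `tau2/tau1` against `sigma_f`.
#'
#' @param sigma_f Noise SD grid.
#' @param ratios Skewness ratios (same length).
#' @return List with `c0`, `c1`, `c2`, `r2`, `adj_r2`.
#' @export
skew_quadratic_fit <- function(sigma_f, ratios) {
  stopifnot(length(sigma_f) == length(ratios), length(sigma_f) >= 3)
  fit <- lm(ratios ~ sigma_f + I(sigma_f^2))
  s <- summary(fit)
  cf <- coef(fit)
  list(c0 = unname(cf[1]), c1 = unname(cf[2]), c2 = unname(cf[3]),
       r2 = s$r.squared, adj_r2 = s$adj.r.squared)
}

#' Linear fit of the half-height width versus frequency-noise SD
#'
#' Least-squares line of the normalized-time half-height width `x2 - x1`
#' against `sigma_f` (intended for `sigma_f < 0.5`, where the relation is
#' close to linear).
#'
#' @param sigma_f Noise SD grid.
#' @param widths Half-height widths in normalized time (same length).
#' @return List with `intercept`, `slope`, `r2`, `adj_r2`.
#' @export
width_linear_fit <- function(sigma_f, widths) {
  stopifnot(length(sigma_f) == length(widths), length(sigma_f) >= 3)
  fit <- lm(widths ~ sigma_f)
  s <- summary(fit)
  cf <- coef(fit)
  list(intercept = unname(cf[1]), slope = unname(cf[2]),
       r2 = s$r.squared, adj_r2 = s$adj.r.squared)
}
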