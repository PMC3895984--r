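---
title: "The striatal beat-frequency model: noise and the scalar property of interval timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The striatal beat-frequency model: noise and the scalar property of interval timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(sbftime)
```

## The model

Interval timing in the seconds-to-minutes range is *accurate* (responses peak
at the trained criterion time $T$) and *time-scale invariant* (the spread of
the response distribution grows linearly with $T$, so normalized response
curves superimpose).  The striatal beat-frequency (SBF) circuit explains both
with three ingredients:

1. **An oscillator bank.** $N_{\mathrm{in}}$ cortical oscillators with
   frequencies $f_i$ spanning a band $(f_{\min}, f_{\max})$ — here the alpha
   band, 8–12 Hz.  The simplest implementation (SBF-sin) is a phase
   oscillator, $v_i(t) = a\cos(2\pi f_i t)$, reset at stimulus onset.  A
   biophysical implementation (SBF-ML) replaces each sine with a
   conductance-based Morris–Lecar neuron whose firing rate is calibrated to
   $f_i$ through its bias current.
2. **A reference memory.** During fixed-interval training, the state of every
   oscillator at reinforcement is stored: over trials $j$ the memorized
   criterion is $T_j$ and the weights are
   $w_i \propto \langle \cos(2\pi f_i T_j)\rangle_j$, normalized by
   $\max_i |u_i|$ so that $|w_i| \le 1$.
3. **A coincidence detector.** A striatal output neuron computes
   $\mathrm{out}(t) = \sum_i w_i\, v_i(t)$ during probe trials: a dot-product
   match between the stored pattern and the current bank state.

In the noiseless circuit the output is a beat pattern: a Dirichlet-type
kernel with carrier $a_0 = \pi(f_{\max}+f_{\min}-\mathrm{d}f)$ and envelope
$\sin(b_0(t-T))/(2\sin(b_0(t-T)/N_{\mathrm{in}}))$,
$b_0 = \pi(f_{\max}-f_{\min})$.  Its width is set by the band alone
($\approx 3.79/b_0$ at half height, about 0.30 s for 8–12 Hz) — the *same*
for every criterion, violating scale invariance:

```{r noiseless}
spec <- osc_bank_spec(1000, 8, 12)
c(width_T10 = noiseless_width(spec, 10), width_T30 = noiseless_width(spec, 30))
```

Noise rescues the scalar property.  The package implements the two sources
analysed in the underlying theory:

* **Criterion-time noise** (storage/retrieval errors): $T_j = T(1+\xi_j)$
  with fractional SD $\sigma_T$.  Multiplicative noise is forced by the
  result $\sigma_{\mathrm{out}} = T\sigma_T$ — additive noise would give a
  $T$-independent width.  For a Gaussian $\xi$ and an unbounded band the
  expected output is exactly Gaussian, centred on $T$
  ($\gamma_T = 0$: accurate timing), with $\sigma_{\mathrm{out}} = T\sigma_T$.
  The finite band multiplies this Gaussian by a band amplitude expressed
  through a difference of complex-argument error functions
  (`criterion_output_finite()`).
* **Frequency noise** (probe-trial clock-speed fluctuations):
  $f_{ij} = f_i(1+\xi_j)$ with fractional SD $\sigma_f$.  The expected output
  for an unbounded band is $(1/t)\exp(-(t-T)^2/(2\sigma_f^2 t^2))$ — a
  Gaussian-like peak near $T/(1+\sigma_f^2)$ whose local width grows with
  $t$, producing a long right tail.  Its half-width ratio
  $\Delta\tau_2/\Delta\tau_1$ grows approximately quadratically in
  $\sigma_f$, and its normalized half-height width grows linearly
  (slope $\approx 2.2$) below $\sigma_f = 0.5$.

```{r fig5, fig.alt = "skewed output"}
g <- seq(0.05, 30, by = 0.01)
plot(normalize_trace(frequency_output_infinite(10, 0.2, g)),
     main = "frequency noise: long right tail")
lines(g, normalize_trace(criterion_output_infinite(10, 0.2, g))$value,
      lty = 2)
legend("topright", c("frequency noise", "criterion noise"), lty = 1:2,
       bty = "n")
```

## How the closed forms were validated

The closed-form module is the oracle surface for the simulator, and vice
versa: every form is cross-checked in the test suite against brute-force
summation (noiseless), adaptive quadrature of the band integral
(finite-band forms, agreement to ~1e-13), and Monte-Carlo averaging of the
simulator (noisy forms).  One transcription choice deserves record: the
$1/t$ prefactor of the infinite-band frequency-noise form.  A family
$t^{-p}\exp(-(t-T)^2/(2\sigma_f^2t^2))$ is compatible with the verbal
description; $p = 1$ is what the band integral gives, it is the only member
whose half-width sweep reproduces the published fit coefficients, and
$p = 0$ has no right half-height crossing for large $\sigma_f$.  The
closed forms keep only the physically realizable term centred at $+T$; the
mirror image at $-T$ lies outside the trial and is dropped.

Two conventions matter for the sweep metrics (`run_fig5_sweep()`): half-width
points are measured about the **numerical argmax** (not the small-$\sigma$
approximation $T/(1+\sigma_f^2)$, which drifts from the true peak at large
$\sigma_f$), and widths are reported in normalized time $t/t_{\mathrm{peak}}$.
The sweep uses 40 uniform noise levels on $(0, 1]$ and a time grid of
400,001 points spanning $60\,T$ — the long tail at $\sigma_f \to 1$ needs the
generous span, and the narrow peak at $\sigma_f = 0.025$ needs the density.

## What a narrow band really does

A point the closed forms hide: for the alpha band the *expected* output
under either noise source is essentially zero at behavioural time scales —
the damping factor $e^{-2\pi^2 f^2 T^2 \sigma^2}$ is astronomically small for
$f \approx 10$ Hz, $T \ge 5$ s.  The band-limited forms
(`criterion_output_finite()`, `frequency_output_finite()`) are exact
expectations and therefore near-degenerate in that regime; they are
non-degenerate, and are tested, on wide low-frequency bands.

The peaked outputs the alpha-band circuit actually produces live in the
*fluctuation envelope* of the coincidence trace.  With noisy stored criteria
the trace is a zero-mean oscillation whose variance is proportional to the
Gaussian density of the memorized criteria, so the envelope of the rectified
output is Gaussian-shaped, centred on $T$, with width between
$T\sigma_T$ and $\sqrt 2\,T\sigma_T$ depending on the number of
correlation-sharing oscillators $\sim N_{\mathrm{in}}/(2\pi\,\mathrm{band}\,T\sigma_T)$.
This is why the experiment pipeline measures widths by a Gaussian-plus-
background fit to the **envelope of the rectified output** (the published
analyses likewise fit Gaussian envelopes), not to the raw oscillation, and
why the measured scalar slopes sit above $\sigma_T$ (by ~40% in the sine
runs, ~10–20% in the Morris–Lecar runs) — consistent with the published
simulation slopes (11.3% for $\sigma_T = 10\%$ in the sine variant;
0.068/0.129/0.25 for $\sigma_T = 0.05/0.1/0.2$ in the Morris–Lecar variant)
rather than $\sigma_T$ itself.

For frequency noise the same logic forces a modelling decision: the noise
draw is shared by the whole bank within a probe trial (a global clock-speed
fluctuation, one draw per trial index).  Independent per-oscillator jitter at
$\sigma_f \sim 0.1$ decorrelates a narrow-band bank completely — the trial
average is flat and no timing signal survives; both modes are implemented
(`probe_output(mode =)`), with `"per_trial"` the default and the only mode
that reproduces the skewed, scale-invariant alpha-band output.

## The Morris–Lecar bank

Parameters (`ml_params()`) are the classic Hopf-regime (type II) set with two
documented adjustments: the calcium conductance reduced to 3.2 mS/cm² (which
stretches the monotone section of the f–I curve) and the kinetics rescaled
($C = 32\ \mu$F/cm², $\phi = 0.025$/ms) so that the achievable rates,
roughly 7.6–12.3 Hz, cover the alpha band.  With the textbook values the f–I
curve spans only 10.8–15.6 Hz and 8 Hz cannot be reached by bias current
alone.  Integration is fixed-step RK4 at $\mathrm{d}t = 0.1$ ms (in compiled
code); halving $\mathrm{d}t$ moves the firing period by well under 0.5%.
Calibration inverts a 25-point f–I curve and refines by vectorized bisection
to better than 1% in rate (`calibrate_bias()`).

Three further choices keep the scaled-down ML experiments faithful:

* **Bank size.**  The coincidence bump competes with a weight-sampling noise
  floor whose relative size scales as
  $N_{\mathrm{in}}/(\mathrm{band}\cdot T\sigma_T)$ — independent of the
  number of FI trials.  At 100 neurons the floor dominates and slopes are
  biased low by ~30%; the experiments therefore keep the full 1000-neuron
  bank and scale down in criterion time ($T \le 10$ s) and trial counts.
* **Frequency placement.**  An equally spaced comb repeats its beat pattern
  every $N_{\mathrm{in}}/(f_{\max}-f_{\min})$ seconds (25 s at
  $N_{\mathrm{in}} = 100$), injecting alias echoes into long probe trials;
  scaled-down banks therefore draw frequencies uniformly at random, which is
  also the stated distribution of the original model.
* **State centring.**  ML waveforms have a large DC component; uncentred
  states leak a rate code that swamps the coincidence signal, so the
  experiment pipeline removes each neuron's temporal mean after the
  $[-a, a]$ rescaling (a no-op for sine states).  Rectified outputs are
  averaged over 20 independent re-encodings of the memory — the analogue of
  averaging response rates over sessions — before the width is fitted, and
  slope estimates are additionally averaged over independently drawn and
  calibrated banks, the dominant source of run-to-run variability.

ML frequency noise is realized as clock-speed scaling of the calibrated
periodic waveforms; the equivalent bias-current route through the inverse
f–I map is available (`calibrate_bias()`) but costs one bank integration per
trial.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `n_osc` | bank size $N_{\mathrm{in}}$ | 1000 | published network scale |
| `f_min`, `f_max` | band (Hz) | 8, 12 | cortical alpha band |
| `sigma` | fractional noise SD | 0.1 | mid-range of the published sweeps |
| `n_fi_trials` | FI trials per memory | 1000 | envelope smooth at desk scale |
| `n_probe_trials` | probe trials averaged | 200 | rectified mean stabilizes |
| `lambda` | Poisson rate parameter | 100 | lattice step $\sigma/\sqrt\lambda \ll$ kernel width |
| `dt` (ML) | integration step | 0.1 ms | dt-convergence < 0.5% |
| probe grid | $\mathrm{d}t = 1/(20 f_{\max})$, span $3T$ | — | ≥ 20 samples per cycle; probe-trial convention |

The criterion grid $\{5, 10, 20, 30, 40, 50\}$ s extends the published pair
$\{10, 30\}$ so the regressions have six support points; the ML runs use
$\{4, 6, 8, 10\}$ s.  The problem sizes above are the package's defaults for
desk-scale reproduction; all are plain config values.

## Numerical choices and degenerate inputs

* Removable singularities of the Dirichlet kernel are evaluated by the
  L'Hôpital limit once $|\sin(b_0x/N)| < 10^{-12}$.
* The band integrals switch from the complex-erf formula to an
  integration-by-parts asymptote once $|\beta|/(2\sqrt\alpha) > 25$ (where
  `erfz` would overflow); the switch error is below $10^{-3}$ relative, in a
  region where the output is itself below $10^{-2}$ of peak.
* Sharp band edges produce genuine ringing of relative size
  $\sim f_{\min}/\mathrm{peak}$; wide-band convergence tests therefore use
  $f_{\min} = 10^{-5}$ Hz and compare shapes on the peak window.
* Half-height crossings use linear interpolation between bracketing grid
  points — deterministic and convergent under grid refinement; a missing
  crossing raises an error naming the truncated side.
* Gaussian fits initialize from moments, fit only values above 10% of peak
  (unless a background term is requested) and report $R^2$ on the fitted
  window; non-convergence raises an error carrying the initial guess.
* `encode_reference()` rejects an all-zero weight pattern; `T = 0` is allowed
  (all weights 1) for degenerate tests.
* One master seed drives every experiment; sub-seeds are derived
  deterministically per (replicate, noise level, criterion), so reports are
  bit-reproducible and every row records its seed.

## What the generator does and does not emulate

The synthetic conditions reproduce the *model* of the study: deterministic
oscillators, multiplicative noise on stored criteria or on clock speed, a
single output neuron ($N_{\mathrm{out}} = 1$), weights given by the
closed-form trial average.  They do not emulate learning dynamics (no
plasticity; encoding is the closed-form average), channel noise inside the
ML dynamics (noise enters only via criterion or frequency/bias jitter),
dopaminergic modulation, or behavioural response thresholds.  Passing tests
therefore show that the circuit mathematics behaves as predicted — not that
biological striatal neurons do.

## Known limitations

* Simultaneous criterion + frequency noise is permitted by the engine but
  untested (the theory analyses each source alone).
* The `N_out > 1` configuration aggregates identical detectors (a
  placeholder; the theory sets $N_{\mathrm{out}} = 1$).
* Alpha-band expected-output forms are near-degenerate (see above); only
  fluctuation-envelope statistics are meaningful there, and single-run
  envelope fits at small $T\sigma_T$ are intrinsically noisy — slope
  estimates average 10 replicates for that reason.
* ML frequency-noise probes reuse the calibrated waveform under time
  rescaling; waveform-shape changes with bias current are ignored at the
  per-trial noise level.
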