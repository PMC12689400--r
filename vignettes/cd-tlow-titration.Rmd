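---
title: "Computationally directed T_Low titration: models and methods"
author: "aprvtitrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computationally directed T_Low titration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aprvtitrate)
```

## The problem

Airway pressure release ventilation (APRV) holds a high airway pressure
`P_High` for a long inspiratory time `T_High` and releases briefly to
`P_Low` for an expiratory time `T_Low`. `T_Low` is the critical setting:
long enough to eliminate CO2, short enough that alveoli do not collapse
(derecruit) during the release. This package implements a computational
method for choosing `T_Low` from respiratory mechanics alone: step `T_Low`
across a grid, estimate the volume-dependent elastance `E2` at each step,
and recommend the `T_Low` at which the `E2`-vs-`T_Low` curve bends hardest
upward — the point where derecruitment starts to accelerate.

## The mechanics model

Respiratory mechanics are described by a nonlinear single-compartment
equation of motion,

$$P = R_1 \dot V + R_2 \dot V |\dot V| + E_1 V + E_2 V^2 + P_0,$$

with airway pressure $P$ (cmH2O), flow $\dot V$ (L/s, inspiration
positive), and volume $V$ (L) above the relaxed end-expiratory state.
$R_1$ is linear resistance, $R_2$ a Rohrer-type flow-dependent resistance,
$E_1$ linear elastance, $E_2$ volume-dependent elastance (the stiffening of
the lung at higher distension — the titration readout), and $P_0$ the
end-expiratory pressure offset. The model is linear in its five
coefficients, so `fit_mechanics()` estimates them by ordinary least squares
of pressure on the regressors $(\dot V, \dot V|\dot V|, V, V^2, 1)$, with
columns rescaled internally for conditioning. The estimate carries fit
diagnostics (RMSE, $R^2$, condition number) and per-coefficient standard
errors from $\hat\sigma^2 (X^\top X)^{-1}$; the `E2` standard errors drive
the weighting of the titration curve below.

Two estimation policies deserve comment because the choice is genuinely
open:

* **Fit window.** Whole cycles (inspiration plus expiration) enter the
  regression rather than expiration only: both phases excite the
  resistive and elastic regressors over complementary ranges, and the
  richer excitation reduces the variance of all five coefficients. Of the
  three cycles delivered per titration step, the first is discarded as a
  settling transient and the last two are fitted jointly. (Fitting the
  transition cycle as well was evaluated and rejected: after a `T_Low`
  change it mixes two recruitment states and biases `E2`.)
* **Volume reference.** `integrate_volume()` computes $V$ by cumulative
  trapezoidal integration of flow with a single reset at the start of the
  record, which is taken to begin at the relaxed end-expiratory state.
  Resetting at every breath start instead would subtract the true
  end-expiratory volume $c$ of each breath, which remaps
  $E_1 \to E_1 + 2 E_2 c$ and $P_0 \to P_0 + E_1 c + E_2 c^2$: `E2` is
  unaffected (it is invariant to a volume offset) but the other
  coefficients are not recoverable under that convention. Per-breath
  resets remain available for drift control on long noisy recordings.

Identifiability varies strongly along the titration grid: a short release
(`T_Low` = 0.2 s) produces a small volume excursion, so $V$ and $V^2$ are
nearly collinear and the `E2` standard error is roughly an order of
magnitude larger than at `T_Low` = 1.0 s. This heteroscedasticity is a
measured fact of the design, not of the noise, and the pipeline propagates
it rather than pretending all steps are equal. For the same reason the
stand-alone noisy-recovery experiment in the acceptance script uses
complete-exhalation cycles (`T_Low` = 1.0 s, expiratory flow reaches ~0),
where the full volume range is traversed.

Low-pass filtering (`lowpass_filter()`, zero-phase Butterworth,
fourth-order equivalent, default cutoff 20 Hz) is provided for real
recordings but is *not* applied inside the fitting pipeline: with white
sensor noise on the pressure channel only, least squares already averages
the noise optimally (filtering leaves the `E2` standard error essentially
unchanged — we measured this), while filtering the nonlinear regressor
channels biases the coefficients (about +1.7% on `E2` at a 20 Hz cutoff,
200 Hz sampling).

## The titration and the spline

`titrate_scenario()` runs the default protocol: `T_Low` from 0.2 s to
1.0 s in 0.05 s increments (17 candidates), three cycles per candidate, as
one continuous ventilation session — the subject is first ventilated for
40 warm-up cycles at the starting `T_Low`, and the lung state carries over
from step to step exactly as it would in an animal whose ventilator is
being adjusted. `run_titration()` collects per-step `E2` (steps whose
regression fails are marked missing and excluded; more than 25% missing
aborts the titration as unreliable).

`fit_e2_spline()` fits a degree-4 (quartic) penalized B-spline to the
`(T_Low, E2)` points. The degree matters: the recommendation is the
maximum of the curve's *second derivative*, and a cubic spline's second
derivative is piecewise linear, able to peak only at knots; a quartic
spline's second derivative is piecewise quadratic and can peak anywhere in
the range. Details of the fit:

* **Basis.** Order-5 B-splines with boundary knots at full multiplicity
  and interior knots at running means of four consecutive data sites (the
  de Boor averaging rule), giving a square, provably nonsingular
  interpolation problem with exactly one basis function per data point.
* **Penalty.** The integrated squared second derivative, assembled exactly
  by 3-point Gauss–Legendre quadrature per knot interval (second
  derivatives of a quartic are piecewise quadratic, so the quadrature is
  exact). Fits are solved by a stacked QR, numerically stable down to the
  interpolation limit.
* **Weights.** Each point's precision is `1 / se(E2)^2` from the
  regression, normalised to median 1 and clipped to `[0.05, 10]`: a noisy
  point cannot drag the curve, but it still anchors the local shape (a
  fully unanchored span lets the quartic develop spurious boundary
  curvature).
* **Smoothing level.** Chosen by weighted generalized cross-validation
  over a log-spaced grid of penalty weights, restricted to fits spending
  at most ~4 equivalent degrees of freedom — a titration curve has a
  single transition, so more flexibility is noise-chasing, and GCV's known
  small-sample failure mode is a spurious minimum at the interpolation
  end. Residual-matching rules (choose the penalty so RSS equals
  $m\hat\sigma^2$, with or without a degrees-of-freedom correction) were
  implemented first and rejected: they are degenerate at the interpolation
  limit of a square basis, and they collapse to interpolation whenever a
  draw's chi-square RSS fluctuation exceeds its expectation at every
  penalty level, which happened in roughly a quarter of noisy titrations
  and threw the recommendation to a grid endpoint.
* **Noiseless data are interpolated exactly.** The replicate-noise scale —
  the median `E2` standard error when precisions are supplied, otherwise a
  low-quantile estimate from second differences of the curve — decides
  between smoothing and interpolation. Noise below ~1% of the curve's
  range is immaterial for curvature localisation and is treated as zero.

`optimal_tlow()` evaluates the spline's second derivative on a dense grid
(step 0.001 s) across the titration range and recommends the argmax, with
ties broken toward the smaller `T_Low` (shorter release, less
derecruitment risk). If the maximum curvature is below
`1e-6 * max(range(E2), 0.001 * scale) / span^2` — a flat or linear curve —
no recommendation is made and `no_optimum_flag` is set; an explicit flag
is preferable to an arbitrary endpoint. The dense-grid argmax (rather than
root-finding on the third derivative) is deliberately simple and exactly
testable against brute-force evaluation.

## The lung simulator

`simulate_aprv()` provides ground-truth waveforms. An ideal pressure
source delivers the APRV square waveform (exponential approach to each
target with a 0.05 s rise time constant by default), and the
single-compartment lung responds with flow obtained in closed form from
the quadratic resistance, $\dot V = \mathrm{sign}(D)\,(-R_1 +
\sqrt{R_1^2 + 4 R_2 |D|})/(2R_2)$ for driving pressure $D$. Volume
advances by an *implicit* trapezoidal rule, iterated to convergence at
each step, so that the recorded pressure, flow, and volume samples are
mutually consistent with the equation of motion at every sample — a
cumulative-trapezoid re-integration of the recorded flow reproduces the
simulator's volume to round-off, and noiseless parameter recovery is exact
to numerical precision rather than to integration error. The default step
is 1 ms; halving it perturbs outputs by under $10^{-4}$ relative.

Recruitment dynamics emulate the clinical premise that a long release
permits alveolar collapse. The recruited fraction $r$ relaxes toward a
sigmoidal equilibrium in alveolar pressure (midpoint `p_crit`, scale `k`),
with separate opening and closing time constants, by an exact exponential
update each time step; effective elastances scale as $E_1/r$ and $E_2/r^2$
(open units share the delivered volume). Two aspects were settled by
simulation rather than assumption:

* **Breath-scale coupling.** With elastances tracking $r$ continuously, a
  long pressure hold traces quasi-static samples at `P_High` across a
  *range* of volumes while $r$ recovers, which least squares reads as
  negative curvature: the fitted `E2` comes out negative and falls with
  `T_Low` — the opposite of the physiology the titration relies on. The
  default coupling therefore freezes the elastances at each cycle start
  (`recruitment_model(coupling = "breath")`): units that close during one
  expiration stiffen the *next* breath. The continuous coupling remains
  available.
* **Time constants.** Reopening of collapsed units is slow —
  breath-to-breath, `tau_open` = 60 s — while closing at low pressure acts
  within a few releases (`tau_close` = 3 s). With `p_crit` = 4.5 cmH2O and
  `k` = 1.5, alveolar pressure during a release (initial decay time
  constant $R_1/E_1 \approx$ 0.27 s) only spends appreciable time below
  `p_crit` once `T_Low` exceeds roughly 0.4 s, so the default scenario's
  `E2` curve is flat at the true value for short `T_Low` and rises
  smoothly beyond it, with its curvature maximum near 0.58 s — a
  sigmoid-like curve of the kind the titration is designed to read. These
  are scenario choices for a plausible injured lung, not measured values;
  the lung itself defaults to `R1` = 8, `R2` = 4, `E1` = 30, `E2` = 15,
  `P0` = 0.

Sensor noise is additive, Gaussian, independent per channel, seeded, and
applied after simulation — so it perturbs what is *measured*, never the
lung's state, and repeated noise draws over one physical trajectory are
legitimate.

What the simulator does **not** emulate: multi-compartment heterogeneity,
gas exchange, hemodynamics, chest-wall partitioning, spontaneous effort,
ventilator flow limitation, or non-Gaussian/correlated sensor noise.
Passing tests therefore demonstrate that the estimation and titration
machinery is correct and stable under the stated model, not that the
recommended `T_Low` values transfer quantitatively to animals or patients.

## A worked run

```{r titration, eval = FALSE}
cfg <- simulation_config(
  settings = ventilator_settings(p_high = 23, t_high = 4,
                                 p_low = 0, t_low = 0.5),
  lung = lung_model(),                       # r1 8, r2 4, e1 30, e2 15
  recruitment = recruitment_model(enabled = TRUE),
  n_cycles = 3, dt = 0.001, seed = 1)
curve <- titrate_scenario(cfg)
curve
#> <titration_curve> 17 steps on [0.2, 1] s, 0 missing
#>   recommended T_Low 0.577 s (max curvature 118.3 cmH2O/L2/s2)
```

## Numerical choices and degenerate inputs

* Sampling: simulator default 1 ms (1 kHz); tolerances in the test suite
  are quoted at 200 Hz where an acquisition-rate context is intended.
* Breath detection: pressure threshold crossings at the midpoint of
  `p_high`/`p_low` with 10% hysteresis, robust to ~1 cmH2O noise; a
  ground-truth phase channel, when present, overrides detection.
* Rank-deficient regressions (e.g. zero flow and volume throughout) raise
  a classed error naming the unidentifiable columns; titration steps that
  fail are marked missing, never imputed.
* Fits with fewer than 25 samples, and negative resistance/elastance
  estimates, emit classed warnings rather than being silently accepted or
  constrained — constrained fitting is deliberately out of scope.
* Monotonicity of the noiseless default-scenario `E2` curve holds to
  within 0.1% of the curve's range (measured worst step −0.003 of a
  16-unit range); the per-step `E2` is a least-squares projection whose
  value carries a tiny wiggle from residual cross-cycle recruitment
  drift, so sign-exact monotonicity is not a meaningful target.
* All randomness is seeded; identical configurations reproduce
  bit-identical waveforms.

## Problem sizes used in the checks

The shipped verification (`tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) uses: 50 random lungs for the oracle-equivalence
and noiseless-recovery checks (3 cycles each at 1 ms); 100 noise seeds for
the noisy-`E2` experiment (200 Hz, 2 fitted cycles, σ = 1 cmH2O); 100
random curves for the curvature-argmax oracle; and 21 full titrations (one
noiseless, 20 at σ = 0.5 cmH2O) of 17 steps × 3 cycles at 1 ms, preceded
by 40 warm-up cycles each, for the end-to-end check. These sizes keep each
block at a few seconds to a few minutes on one core while leaving the
Monte-Carlo margins comfortable.

## Known limitations

* `E2` at short `T_Low` is intrinsically poorly identified; the weighting
  mitigates but cannot remove this.
* The recommendation localises the maximum of a smooth curvature profile;
  when the underlying curve's bend is broad, replicate titrations under
  noise scatter the recommendation by a few hundredths of a second.
* The spline's flexibility cap (~4 df) is right for single-transition
  curves; a titration curve with two genuine transitions would be
  oversmoothed.
* The simulator's recruitment parameters are plausibility choices; no
  animal data were used to calibrate them, and none are claimed to be
  reproduced.
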