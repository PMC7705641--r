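---
title: "Reservoir and excess pressure: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reservoir and excess pressure: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artres)
```

## The model

The arterial reservoir treats the large elastic arteries as a branching
network of `N` compliant vessel segments discharging through `K` terminal
resistances into the microcirculation. Outflow through terminus `k` stops
when local pressure reaches the zero-flow (critical closing) pressure
$P_{zf}$, taken common to all termini:

$$Q_k = \frac{P - P_{zf}}{R_k}.$$

The reservoir pressure $P_{res}$ is defined as a pressure waveform common
in shape along the tree but delayed at vessel $n$ by the wave transit time
$\tau(n)$ from the root. Substituting $P_{res}(t - \tau(n))$ into mass
conservation gives a scalar first-order delay-differential equation; since
measured aorto-iliac transit times in humans are under 80 ms — small
against a ~1 s cardiac period — a first-order Taylor reduction in
$\tau(n)$ collapses it to the Windkessel-form ODE

$$C\,\frac{dP_{res}}{dt} = Q_{in} - \frac{P_{res} - P_{zf}}{R},
\qquad C = \sum_n C_n,\quad \frac{1}{R} = \sum_k \frac{1}{R_k},$$

without assuming a spatially uniform pressure. The excess pressure is the
remainder, $P_{xs} = P - P_{res}$, enforced sample-by-sample so the
decomposition is exactly additive.

When aortic flow is not measured, the proximal-aortic proportionality
$Q_{in} = \zeta P_{xs}$ (with $\zeta$ the characteristic admittance,
$1/Z_c$ in three-element Windkessel terms) gives the pressure-only form

$$\frac{dP_{res}}{dt} + k_d (P_{res} - P_{zf}) = k_s (P - P_{res}),
\qquad k_s = \zeta / C,\quad k_d = 1/(RC).$$

In diastole ($Q_{in} = 0$) both forms reduce to a mono-exponential decay
towards the asymptote with time constant $RC$; the asymptote of a fit to
measured diastole is reported as $P_\infty$. Experimentally, $P_\infty$
from single-beat fits tends to sit well above directly measured $P_{zf}$
(capacitive discharge from downstream beds and the short fitted window
both push it up), which is why the package treats the choice of $P_{zf}$
as an explicit mode rather than silently equating the two (see below).

## Algorithms

**Pressure + flow** (`compute_pres_pq()`, pipeline `reservoir_pq()`): the
ODE is linear with constant coefficients, so it is integrated by an
exponential product rule: within each sampling interval the inflow is
taken piecewise-linear and integrated exactly against the decay kernel
$e^{-(t-s)/RC}$. The step is exact for piecewise-linear forcing,
second-order accurate for smooth forcing, and degenerates to the
closed-form mono-exponential whenever the inflow vanishes. The same
stepper drives the simulators, so simulator and analysis agree to
round-off on matched problems — which is what the two- and three-element
oracle checks in the test suite assert.

**Pressure only** (`compute_pres_p()`, pipeline `reservoir_p()`):

1. `detect_end_systole()` — end-systole is the global minimum of the
   smoothed pressure derivative (max $-dP/dt$), the standard pressure-only
   surrogate for the cessation of aortic flow (reported agreement in
   invasive animal data is sub-millisecond). Smoothing is Savitzky–Golay
   (local cubic) over a configurable window, 20 ms by default; derivatives
   are central differences. Ties resolve to the earliest sample for
   determinism.
2. `fit_diastolic_decay()` — Levenberg–Marquardt least squares of
   $P_\infty + (P_{es} - P_\infty)e^{-k_d(t - t_{es})}$ over the diastolic
   window, with several deterministic starts (asymptote guesses at 0.7,
   0.3 and 0 times the window minimum, slope starts from a log-linear
   regression) and the best SSE kept. No randomised restarts, so results
   are exactly reproducible.
3. `fit_ks()` — $k_s$ minimises the diastolic mismatch between $P$ and
   $P_{res}(k_s)$. This objective is **not** unimodal: it always has a
   degenerate basin as $k_s \to \infty$, where the reservoir simply tracks
   the measured pressure ($P_{xs} \to 0$, i.e. infinite characteristic
   admittance) and the diastolic mismatch also vanishes. On clean
   simulated data that spurious basin can be numerically deeper than the
   physical well, so a plain bounded minimiser (or a naive global grid
   argmin) returns the bracket bound. The implementation scans a
   log-spaced grid over $[10^{-3}, 10^{3}]$ s$^{-1}$, takes the *first*
   interior local minimum — the smallest admittance consistent with the
   data — and refines it by bounded scalar search between the bracketing
   grid points. If no interior minimum exists a `"k_s at bound"` warning
   is raised and the bound returned.

**Parameters that matter.**

| parameter | default | units | why |
|---|---|---|---|
| `smooth_window` | 0.02 | s | derivative fiducials are noise-sensitive; ~1/10 of systole blurs the derivative by a few ms without moving the global minimum onto another feature |
| diastolic guards | 0.03 / 0.03 | s | skip the end-systolic transition and the pressure perturbation at the onset of the next isovolumic contraction |
| `min_period` | 0.4 | s | shortest physiological beat admitted by the segmenter |
| $k_s$ bracket | $[10^{-3}, 10^{3}]$ | 1/s | generous bounds around physiological $\zeta/C$ |
| `P_res0` | pressure at the foot | mmHg | excess pressure is zero before ejection begins |

**Zero-flow pressure modes.** `pzf_mode = "fit"` (default) uses the fitted
$P_\infty$; `"fixed"` takes a user value (e.g. 0, as some groups assume);
`"measured"` takes a stopped-flow measurement and refits the decay with
the asymptote pinned there. The mode is recorded in every result because
the three choices give materially different $R$, $C$ and $P_{res}$ scaling,
and because $P_\infty$ is known to overestimate measured $P_{zf}$.
Negative or implausible fitted asymptotes ($P_\infty$ not below the window
minimum) are flagged, never clipped.

**Velocity input.** With flow velocity instead of volumetric flow, $k_d$,
$P_\infty$, $P_{res}$ and $P_{xs}$ are unchanged while `estimate_rc()`
returns per-area quantities (resistance × area, compliance / area); the
product $RC$ is invariant, which the tests assert. Note that the
mean-pressure resistance estimate on a vessel with nonzero characteristic
impedance returns the total input resistance $R + Z_c$; consequently the
compliance from $C = 1/(k_d R_{est})$ is biased low by the factor
$R/(R+Z_c)$. This is a property of the estimator, not a bug, and is why
parameter-recovery validation is phrased in terms of $k_d$, $P_\infty$ and
$k_s$.

## The synthetic-data generators

`half_sine_inflow()` ejects the stroke volume as a half-sine over systole
(default SV 70 mL, $T_{sys}$ 0.3 s, period 1 s, 1 kHz sampling — textbook
resting human values). The end of inflow defines the true end-systole used
to validate the fiducial detector. `simulate_windkessel()` produces two-
and three-element Windkessel pressures ($P = P_{wk} + Z_c Q_{in}$) with a
nonzero asymptote; defaults $R = 1.2$ mmHg·s/mL, $C = 1.4$ mL/mmHg,
$P_{zf} = 20$ mmHg give normotensive pressures (~104 mmHg mean) and a
diastolic time constant of 1.68 s. `simulate_delay_network()` solves the
un-reduced delay equation for a user-defined vessel tree by the method of
steps: zero-delay terms (always including the root compliance) advance
with the exact exponential step, delayed terms are read from the stored
history by linear interpolation, with a constant pre-history. Vessel
delays are capped by default at the 80 ms empirical transit budget, and
the solver refuses sampling intervals coarser than a quarter of the
smallest delay.

What the generators deliberately emulate: periodic steady state, a sharp
end-systolic derivative feature, exponential diastole with a nonzero
asymptote, transit-time dispersion of O(τ), and seedable additive Gaussian
measurement noise. What they do not emulate: wave reflections beyond the
lumped $Z_c$ picture, visco-elastic walls, pressure-dependent compliance
or resistance, multi-exponential or non-exponential diastolic decay,
respiratory modulation, or cuff-calibration error. Passing the validation
suite therefore demonstrates correctness of the algorithms on data obeying
the model's assumptions; it does not certify accuracy on clinical
recordings where those assumptions degrade (notably the mono-exponential
diastole, which experimental stopped-flow studies repeatedly find
imperfect).

## Numerical choices and degenerate inputs

- Product (exponential) integration everywhere a linear-in-state ODE is
  solved; plain trapezoid is used for output integrals (indices, volumes).
  Halving `dt` cuts quadrature error about fourfold.
- The delay solver shares the stepper arithmetic with the Windkessel
  simulator, so a single zero-delay vessel reproduces the lumped solution
  to round-off rather than to discretisation accuracy.
- Ties in extrema resolve to the earliest sample; all index bookkeeping is
  1-based inside R and 0-based in machine-readable CLI output.
- Constant pressure, monotone rising pressure, windows with fewer than 10
  samples, non-decaying diastole and empty study tables all raise typed
  errors ("diastolic fit failed", "no end-systole detectable", "no beats
  found", "insufficient studies") rather than returning garbage.
- Irregularly timestamped input is linearly resampled onto the median
  sampling interval at ingest, since every quadrature above assumes a
  uniform grid.

## Meta-analysis machinery

Study-level synthesis of zero-flow pressure (and its difference from mean
circulatory filling pressure) uses DerSimonian–Laird pooling: the
closed-form moment estimator of the between-study variance, inverse
random-effects-variance weights, and normal-approximation confidence
intervals — the historical default of mainstream statistics packages, and
fully formula-specified so it can be hand-verified (a two-study hand
oracle is frozen in the tests; `metafor` serves as an independent
cross-check, never as the implementation). Prediction intervals use the
Higgins form with $t_{k-2}$; the Egger test is the classic unweighted
regression of standardized effect on precision; meta-regression uses the
method-of-moments residual-heterogeneity estimator with $t_{k-2}$ slope
tests; subgroup heterogeneity compares DL-pooled subgroup means by a
chi-square statistic. Paired differences assume within-study independence
of the two arms (correlations are rarely reported), which is conservative
for positively correlated arms; the result carries a note saying so. SDs
are converted to SEs at ingest; range/4 conversion exists but is opt-in.

A known limitation, measured rather than hidden: with ~20 heterogeneous
studies, DL z-intervals under-cover slightly (the calibration simulation
in the acceptance script reports the achieved coverage, about 93% at the
default conditions). A Knapp–Hartung adjustment would restore nominal
coverage but is a different estimator from the one implemented here.

## Problem sizes used in validation

The shipped validation suite runs on 10–12-beat, 1 kHz simulations
(10–12k samples), a 24-point factorial Windkessel sweep, three-vessel
delay networks at three transit scalings, and 1000-replicate meta-analysis
calibrations — sizes chosen so every property is exercised at realistic
resolution while the whole suite stays fast enough to run on every change.

## Known limitations

- Single-beat analysis assumes the beat is in (quasi-)periodic steady
  state; strong beat-to-beat variation violates the cycle-average used by
  `estimate_rc()`.
- The pressure-only method inherits the proportionality assumption
  $Q_{in} \propto P_{xs}$, which degrades away from the proximal aorta and
  in pathology with strong early reflections.
- $P_\infty$ is an extrapolated asymptote, not a measurement of $P_{zf}$;
  the package exposes the distinction but cannot resolve it from a single
  beat.
- No multi-exponential diastolic models, no wave-intensity or
  forward/backward wave separation, no distributed 1-D propagation — all
  outside the lumped/delayed-reservoir scope of this package.
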