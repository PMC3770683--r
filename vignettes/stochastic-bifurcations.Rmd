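---
title: "Noise-shifted bifurcations in one-variable gene circuits: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-shifted bifurcations in one-variable gene circuits: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model class and its assumptions, the analytic machinery, the numerical
choices, the design decisions that were genuinely open, and the limits of
what the tests demonstrate.

## The model class and its assumptions

`stochbif` treats one-variable gene regulatory circuits of the
production–degradation form: molecule number `n` is produced at rate
`Ω g(n/Ω)` and degraded at rate `n`, where `g` is the gene regulatory
function, `Ω` the dimensionless cell volume and all rates are measured in
units of the degradation rate (time unit: one protein lifetime;
concentration unit: the half-maximum activation concentration of the
reference switch). Three descriptions of the same circuit coexist in the
package, in decreasing order of resolution:

1. **Birth–death master equation** over counts — exact, solved in closed
   (product) form at stationarity by detailed balance
   (`birth_death_stationary()`).
2. **Itô chemical Langevin equation** for the concentration `x = n/Ω`:
   `dx = f dt + ε √B dW` with `f = g − x`, `B = g + x` and
   `ε = Ω^(−1/2)` — valid when molecule numbers are not too small; this is
   where the analytic theory lives (`build_langevin()`,
   `stationary_density()`).
3. **Deterministic rate equation** `dx/dt = g(x) − x` — the `ε → 0` limit.

The reference model is the auto-activating switch,
`g(x) = a + b xʰ/(1 + xʰ)`: a protein oligomer binds its own promoter and
activates expression. For suitable `(a, h)` the deterministic system is
bistable for `b` between two saddle-node (fold) points, the phase-space
picture behind the "epigenetic landscape" metaphor: phenotypes are density
modes.

Key assumptions inherited from this formulation: one slow variable (the
theory requires the explicit stationary solution, which exists only in one
dimension), intrinsic noise only (no extrinsic parameter fluctuations), no
transcriptional/translational bursting (production advances in single
steps), and Itô interpretation of the chemical Langevin equation.

## Stochastic bifurcation points

The stationary density `Ps(x) ∝ B^(−1) exp[(2/ε²)∫ f/B]` changes modality
where an extremum appears or disappears. Extrema solve
`Φ(x, b) = f − (ε²/2) ∂B/∂x = 0`; a *stochastic bifurcation point*
additionally satisfies `∂Φ/∂x = 0`. The package computes these points two
ways, deliberately independent of each other:

- **Continuation** (`stochastic_bifurcation_solve()`): a 2-D Newton solve of
  `(Φ, ∂Φ/∂x) = 0`, seeded at the deterministic fold (`ε = 0`, where the
  conditions reduce to `f = ∂f/∂x = 0`) and path-followed in `s = ε²` with
  adaptive steps (initial `Δs = 10⁻⁴`, growth ×1.6 on success, halving on
  Newton failure, floor `10⁻¹⁰` after which the branch is reported lost).
  Residuals below `10⁻¹²`.
- **Perturbative series** (`shift_series()`): substitute
  `x = x0 + x1 s + x2 s²`, `b = b0 + b1 s + b2 s²` into the two conditions
  and collect powers of `s`. The expansion parameter is the noise
  *intensity* `s = ε²`, not `ε`: with this convention order 0 reproduces the
  deterministic fold conditions and each order yields a linear 2×2 system.
  Order 1 has the closed form `b1 = Bₓ/(2 f_b)`,
  `x1 = (Bₓₓ/2 − f_{xb} b1)/f_{xx}`; order 2 is obtained by the same
  collection carried one power further (the coefficients are assembled
  generically from partial derivatives of `f` and `B` up to third order
  rather than transcribed as closed formulas, and are validated against the
  continuation solution in the tests: a quartic fit of `b*(s)` over
  `s ∈ [10⁻⁴, 10⁻²]` recovers `b1` and `b2` to better than 1%).

At a fold `∂g/∂x = 1`, hence `∂B/∂x = 2` and `b1 = 1/(∂g/∂b)`: the sign of
the shift is the sign of the control parameter's regulatory role. The
package ships both an activator-controlled switch (`hill_activator()`,
`b1 > 0` on both folds: noise *delays* the bifurcations and widens the
bistable window) and an inhibitor-controlled variant (`hill_inhibitor()`,
`g = a + (c − b)xʰ/(1+xʰ)`, `∂g/∂b < 0`, `b1 < 0`). The inhibitor is built
this way — the control parameter suppressing the feedback strength inside a
bistable circuit — because a plain decreasing `g` admits no fold at all
(`∂f/∂x < 0` everywhere), so "noise advances the bifurcation of an
inhibitor" can only be exhibited in a model that has a bifurcation.

Degenerate expansion points (`∂f/∂b = 0` or `∂²f/∂x² = 0`, codimension-2)
raise explicit errors rather than returning garbage coefficients.

## Colored noise

Real intrinsic fluctuations have short but non-zero memory. The package
models them with an Ornstein–Uhlenbeck (OU) process `ζ(t)` of correlation
time `τ` and white-noise-limit intensity `ε` (stationary variance
`ε²/(2τ)`). The colored counterpart of the white-noise system is

    dx/dt = f(x) − (ε²/4) ∂B/∂x + √B(x) · ζ(t).

The drift correction `−(ε²/4)∂B/∂x` is the Itô→Stratonovich conversion
term: by the Wong–Zakai theorem the `τ → 0` limit of a multiplicative OU
drive is the *Stratonovich* equation, and with this drift that limit is
exactly the Itô white-noise system above — verified in the tests by a
Kolmogorov–Smirnov distance of order 10⁻² between the `τ = 0.01` stationary
histogram and the white-noise analytic density. In the opposite limit
`τ → ∞` at fixed `ε` the OU variance vanishes and the dynamics follow the
corrected drift alone, i.e. the extremum condition with the noise intensity
halved; the first-order shift coefficients are therefore exactly half their
white-noise values (`colored_longtau_shift()`), lessened but with the same
sign. Intermediate `τ` has no analytic solution and is handled only by
simulation (`colored_langevin()`: Heun predictor–corrector on the state —
Stratonovich-consistent — with the OU value held within a step and updated
by its exact discrete-time recursion between steps).

## Simulation engines and the synthetic fixtures

Four engines, all bit-reproducible from an integer seed (`mt19937_64` with
explicit 53-bit uniforms and a Box–Muller normal, so results do not depend
on standard-library internals): Euler–Maruyama (Itô), the colored Heun
integrator, Gillespie SSA for the simple birth–death circuit, and Gillespie
SSA for a detailed switch that resolves the promoter explicitly (binding of
`h` free monomers in one cooperative event, sequestering them; production at
`aΩ` per unbound and `(a+b)Ω` per bound promoter copy; unbinding releases
the monomers). Under fast binding (`koff ≫ 1`) the detailed model's
quasi-steady-state reduction is the simple switch with `keq = 1`; the tests
confirm the stationary means agree to better than 5% at a monostable point,
and the clamped-protein occupancy reproduces the two-state equilibrium
`keq xʰ/(1 + keq xʰ)`. Only the sequestration reading of the binding event
is implemented; a pre-equilibrated oligomer pool is a plausible alternative
chemistry, but there is no independent reference to test it against, so it
was left out rather than shipped untested.

Euler–Maruyama handles the `x = 0` boundary by reflection (`x ← |x|`),
which preserves the zero-flux boundary of the stationary density better
than absorbing or clamping; the additive-noise tests that need an unbounded
domain disable it. Steps `dt ≥ 0.1` are rejected outright (explicit-scheme
stability guard); the default `dt = 10⁻³` is two orders below the
deterministic relaxation time.

The test fixtures are generated in code, never stored: Gaussian mixtures
with known component locations for the peak detector, a two-state telegraph
signal with known exponential dwell means for the dwell estimator, and the
engines themselves for everything else. These fixtures emulate the
*structure* of real single-cell data (bimodal population snapshots,
switching time series) but none of its nuisance features — measurement
noise beyond additive Gaussian, cell-cycle effects, extrinsic variability,
bursting. Passing tests therefore demonstrate correctness of the
algorithms, not robustness to real-data artifacts.

## Landscape pipeline

`empirical_density()` histograms the post-burn-in samples (burn-in removes
the leading fraction of *samples*: 10% of a 1000-sample trajectory leaves
exactly the last 900), weighting event-recorded SSA output by holding time
and grid-recorded output uniformly. `gaussian_peak_detect()` smooths with a
Gaussian kernel, scans for local maxima above a relative prominence
threshold (default 10⁻³ of the global maximum), drops candidates with
integrated mass below `min_mass` (default 10⁻⁴), and refines each survivor
by a local Gaussian least-squares fit (quadratic in the log-density over ±2
bandwidths). Because the low state's probability collapses rapidly beyond
the deterministic fold, where the *simulated* branch of a bifurcation
diagram ends is governed by these thresholds — they are reported settings,
not internals. Two caveats discovered in validation and documented rather
than papered over:

- The default bandwidth (Silverman's rule, floored at two grid steps)
  treats samples as independent; strongly autocorrelated trajectory
  histograms are then under-smoothed and a single mode can split. For
  trajectory data pass a bandwidth near the expected mode width, or raise
  `min_mass` to suppress sparse-tail artifacts.
- `dwell_times()` assigns states hysteretically (enter high only above the
  upper threshold, low only below the lower one). The default band from
  `hysteresis_band()` places each threshold 25% of the way from the
  unstable extremum toward the *adjacent* mode. A symmetric fraction of the
  full inter-mode distance was rejected: for the reference switch (modes
  near 0.06 and 2.3, unstable point near 0.45) it would push the lower
  threshold below zero and the low state could never be entered.

## Numerical choices

- Fixed points: `g(x) = x` is converted to polynomial form for the Hill
  family and solved with companion-matrix root finding (`polyroot`), roots
  filtered at imaginary-part tolerance 10⁻⁹ and polished by Newton to
  residuals below 10⁻¹²; non-polynomial models use a sign-scan plus
  `uniroot`. Folds: fixed-point counts are scanned over the control range,
  each transition bisected and handed to a damped 2-D Newton on
  `(f, ∂f/∂x)`.
- Stationary density: uniform grid (4001 points) on `[0, x_max]` with
  `x_max` three times the largest fixed point, extended ×1.5 until the
  unnormalized tail is below 10⁻¹² of the peak; the exponent accumulates by
  cumulative trapezoid and normalization happens in log space
  (log-sum-exp), so `Ω` in the hundreds does not underflow.
- Master equation: the product form is accumulated as a cumulative sum of
  log-ratios and normalized in log space; the truncation starts at
  `⌈10 Ω g_sat⌉ + 50` and doubles until the boundary probability is below
  10⁻¹⁰ of the peak *and* the birth/death flux ratio at the boundary is
  contracting, erroring at a hard cap of 10⁶ states.
- Hill derivatives (needed to fourth order by the series machinery) are
  evaluated from symbolically differentiated expressions, with exact series
  limits at `x = 0` where the raw expressions hit `0·∞`. For user-supplied
  `g` without analytic derivatives, central finite differences are used
  with steps that *grow with the derivative order* (≈ machine-ε^(1/(k+2)),
  i.e. 6×10⁻⁶ for first up to 2.5×10⁻³ for fourth): a fixed 10⁻⁶ step
  would lose all significant digits to round-off at orders 3–4.
- All series and fold computations are floating point; near-degenerate
  folds are guarded by explicit conditioning checks rather than extended
  precision.

## Problem sizes in the checks

The automated checks run on one CPU in a few minutes total and use:
Euler–Maruyama runs of `t = 10⁵` (10⁸ steps) for histogram–density
agreement at `Ω = 50`; SSA runs of `t = 2×10⁵` (≳10⁶ events) at `Ω = 12.5`
for agreement with the exact law; colored-noise runs of `t = 10⁴` at
`dt = 2×10⁻⁴` for the `τ → 0` limit; continuation ladders over
`s ∈ [10⁻⁴, 10⁻²]`; and an 11-model randomized family of bistable Hill
circuits for the order-structure property. These sizes were chosen so the
statistical error of each stochastic check sits a factor of a few below its
acceptance tolerance.

## Known limitations

- **Low-state detectability near the fold.** Under the default parameters
  (`a = 0.1`, `h = 2`) the equilibrium low-state occupancy just above the
  deterministic upper fold at `Ω = 12.5` is only ≈ 2% (exact master
  equation; confirmed by long SSA). The volume *contrast* — detectable
  low-state residence at `Ω = 12.5`, none at `Ω = 500` — is robust, but any
  detectability criterion demanding ≥ 5% occupancy there cannot be met by
  these study conditions; one acceptance expectation records this gap
  deliberately.
- The analytic machinery is strictly one-dimensional; multi-variable
  circuits are out of scope by construction.
- Bursting and extrinsic noise are not modeled; real circuits with bursty
  expression will show stronger noise at equal volume, so the volume scale
  here should not be read as a literal cell-size calibration.
- Mixing limits simulation-based checks deep inside the bistable window at
  large `Ω` (mode-hopping times grow exponentially with `Ω`); the
  analytic and exact-master routes have no such limit and are the
  recommended tools there.
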