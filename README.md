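# stochbif

Intrinsic biochemical noise does not just blur the phase portrait of a gene
circuit — it moves its bifurcation points. For one-variable regulatory
systems described by a chemical Langevin equation, `stochbif` quantifies that
displacement: it computes the stationary probability density and its
extrema, locates the *stochastic* bifurcation points (where the density
changes modality) by numerical continuation, expands their noise-induced
shift perturbatively in the noise intensity, solves the underlying
birth–death master equation exactly, and simulates the dynamics with
white-noise, colored-noise and Gillespie engines. The package is aimed at
people studying phenotypic bistability and noise-driven changes of the
epigenetic landscape — the reference model throughout is the genetic
auto-activating switch.

## Model

In dimensionless units (concentration in units of the half-maximum
activation concentration, time in units of the inverse degradation rate) the
auto-activating switch is

    dx/dt = g(x) - x,      g(x) = a + b * x^h / (1 + x^h)

with basal rate `a`, maximum production rate `b` (the control parameter) and
cooperativity `h`. For volumes `Ω` the chemical Langevin equation is the Itô
SDE

    dx = f(x) dt + ε sqrt(B(x)) dW,    f = g - x,  B = g + x,  ε = Ω^(-1/2)

whose stationary density is `Ps(x) ∝ B(x)^(-1) exp[(2/ε²) ∫ f/B dy]`.
Density extrema solve `Φ(x) = f - (ε²/2) B'(x) = 0`; a stochastic
bifurcation point `(x*, b*)` additionally satisfies `∂Φ/∂x = 0`. Expanding
`b* = b0 + b1 ε² + b2 ε⁴ + …` around the deterministic fold gives, at first
order,

    b1 = B'/(2 ∂f/∂b),    x1 = (B''/2 - ∂²f/∂x∂b * b1) / ∂²f/∂x²

(all evaluated at the fold). At a fold `∂g/∂x = 1`, so `sign(b1) =
sign(∂g/∂b)`: when the control parameter promotes production, noise delays
the bifurcation; when it inhibits production, noise advances it. For the
switch both folds move to higher `b` and the bistable region widens — the
low-expression state survives where the deterministic system is already
monostable (*stochastic stabilization*). For Ornstein–Uhlenbeck (colored)
fluctuations with long correlation time the shift is halved but keeps its
sign.

The exact stationary law of the equivalent birth–death process (birth rate
`Ω g(n/Ω)`, death rate `n`) follows from detailed balance and validates the
Langevin results; a detailed model that resolves promoter binding/unbinding
explicitly is simulated with the Gillespie algorithm.

## Worked example

```r
library(stochbif)

model <- hill_activator(a = 0.1, h = 2)
deterministic_bifurcation_points(model)
#> <bifurcation_points> bistable window b in ( 1.7872302 , 2.604365171 )
#> <bifurcation_point> lower branch [deterministic]: b* = 1.7872302, x* = 0.8788850662
#> <bifurcation_point> upper branch [deterministic]: b* = 2.604365171, x* = 0.2091488484

shift_series(model, "upper", order = 2)
#> <shift_series> upper branch, white noise, order 2 (powers of s = epsilon^2)
#>   b*:   2.6043652 + s* 23.8606747 + s*263.4977331
#>   x*:  0.20914885 + s*-1.80210454 + s* 2.35149010

spec <- build_langevin(model, Omega = 50)
stochastic_bifurcation_solve(spec, "upper")
#> <bifurcation_point> upper branch [continuation]: b* = 3.217432544, x* = 0.1737564714
#>   epsilon = 0.1414214
```

Reading: deterministically the switch is bistable for `b` in (1.787, 2.604).
At cell volume `Ω = 50` (noise intensity `ε² = 0.02`) the upper fold has
moved from `b = 2.604` to `b = 3.217` — the low state remains a detectable
phenotype over a control-parameter range about 75% wider than the
deterministic window, and the first-order coefficient `b1 = 23.9` says the
effect grows steeply as the fold approaches the axis. The exact master
equation confirms it:

```r
d <- birth_death_stationary(model, b = 2.7, Omega = 12.5)  # b above the fold
discrete_modes(d)
#> [1]  1 29
```

— a bimodal molecule-count distribution where the deterministic system has a
single (high) state.

Trajectory-level tools mirror what one measures in simulations or
experiments:

```r
traj <- ssa_simple(model, b = 2.4, Omega = 12.5, n0 = 22,
                   t_end = 1e4, seed = 1, record_dt = 0.05)
dens <- empirical_density(traj, scale = 1 / 12.5)
gaussian_peak_detect(dens, bandwidth = 0.15)  # bandwidth ~ mode width
#>   location    height     width
#> 1 0.000049 0.3768614 0.1500000
#> 2 1.907468 0.5889563 0.6213371
```

Both phenotypic modes are recovered (the analytic density maxima sit at
0.057 and 1.94). The bandwidth is a first-class, reported setting: the
default Silverman rule treats the samples as independent and under-smooths
strongly autocorrelated trajectory histograms, so for trajectory data choose
it near the expected mode width.

A command-line wrapper with the same functionality ships in
`inst/cli/stochbif.R`:

```sh
Rscript inst/cli/stochbif.R bifurcate --omega 50 --out_dir out/
Rscript inst/cli/stochbif.R simulate --engine ssa-simple --seed 7 --out_dir out/
```

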