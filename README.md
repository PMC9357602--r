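# turingdelay

Gene expression is slow: transcription and translation introduce delays of
minutes to hours, on the same scale as fast developmental patterning events.
`turingdelay` is an R package for asking what such delays — fixed, or
continuously distributed to reflect the stochasticity of expression — do to
diffusion-driven (Turing) pattern formation in two-species
reaction–diffusion systems. It is aimed at mathematical and systems
biologists who want a tested pipeline for delayed linear stability analysis
and delay-PDE simulation rather than one-off scripts.

## The model

Two morphogens on the unit interval obey

    u_t = (eps^2/L^2) u_xx + f(u, v, F),    v_t = (1/L^2) v_xx + g(u, v, G),

where `F = ∫ K(s) F(u(t−s), v(t−s)) ds` is a reaction step weighted by a
delay kernel `K` on a positive-delay window. Kernels: Dirac (fixed delay
τ), symmetric truncated Gaussian (τ, σ), and skewed truncated Gaussian
(μ, ω, ρ) with Owen's-T-based truncation constants and a closed-form
truncated mean. Kinetics: the ligand-internalisation (LI) Schnakenberg
variant and two Gierer–Meinhardt variants (GM1, GM2) that differ in which
terms are delayed.

Linearisation in the Neumann basis `cos(kπx)` yields the transcendental
dispersion relation

    λ² + α_k λ + β_k + (γ_k λ + δ_k) E(λ) + χ_k E(λ)² = 0,
    E(λ) = ∫ K(s) e^{−λs} ds,

whose rightmost root per wavenumber decides stability. The package finds it
by delay continuation from the zero-delay quadratic plus a bisection-refined
real-axis scan, with every reported root residual-checked; on top of that
sit Turing-space scans over the kinetic plane `(a, b)`, a
distributed-vs-fixed discrepancy statistic, a method-of-lines delay-PDE
simulator (stiff `deSolve` integration, Simpson quadrature of the delay
integral), and time-to-pattern metrics with cosine-mode analysis.

## Worked example

```r
library(turingdelay)

m <- rd_model("LI", a = 0.1, b = 0.9)   # eps^2 = 0.001, L^2 = 4.5
steady_state(m)
#>   u   v
#> 1.0 0.9

# undelayed dispersion: Turing-unstable, fastest-growing mode k = 4
max_growth_rate(m, delay_kernel("dirac", tau = 0))
#> <dispersion_result> max Re(lambda_k) = 0.7160056 at k = 4 over k in [0, 50]

# a delay of 1 slows the instability roughly sixfold...
max_growth_rate(m, delay_kernel("dirac", tau = 1))$max_re
#> [1] 0.1202535

# ...and a distributed delay with the same mean barely differs
kg <- delay_kernel("gaussian", tau = 1, sigma = 0.99 / 3)
max_growth_rate(m, kg)$max_re
#> [1] 0.1208912

# simulated time-to-pattern grows linearly in the mean delay
sw <- tau_sweep(m, tau_grid = seq(1, 16, 1), sigma_IC = 1e-5,
                threshold = 0.1, seed = 1, t_max = 1400)
c(slope = sw$slope, r_squared = sw$r_squared)
#>      slope  r_squared
#> 68.9708272  0.9999999
```

The first two results say: at `(a, b) = (0.1, 0.9)` the homogeneous state is
stable to uniform perturbations but mode 4 grows, so a striped pattern
forms; a mean delay of one nondimensional time unit cuts the growth rate
from 0.72 to 0.12, and replacing the fixed delay by a wide symmetric
distribution with the same mean shifts it only in the third decimal. The
sweep quantifies the practical cost: every added unit of delay postpones
patterning by ~69 time units at these parameters.

Configured analyses can also be run from a shell via the thin wrapper
`inst/cli/turingdelay.R`:

```sh
Rscript inst/cli/turingdelay.R --config inst/extdata/example_config.yaml --out out/
```

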