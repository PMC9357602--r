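---
title: "Methods: Turing instabilities under fixed and distributed gene-expression delays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Turing instabilities under fixed and distributed gene-expression delays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turingdelay)
```

## The model

Gene expression — transcription, translation, transport — takes time, and in
fast developmental patterning events that time is not negligible. The package
studies two-morphogen reaction–diffusion systems on the unit interval in
which the gene-expression step of the kinetics acts with a delay:

$$u_t = \frac{\epsilon^2}{L^2} u_{xx} + f(u, v, \mathcal F), \qquad
  v_t = \frac{1}{L^2} v_{xx} + g(u, v, \mathcal G),$$

where $\mathcal F = \int_{\tau_1}^{\tau_2} K(s)\,F(u(t-s), v(t-s))\,ds$ is
the delayed reaction step weighted by a probability kernel $K$ of delay
times (and likewise $\mathcal G$). Three kinetics are implemented:

* **LI** — the ligand-internalisation Schnakenberg (activator-depleted)
  variant, with the delay only in the activator's autocatalysis
  ($F = u^2v$): $f = a - u - 2u^2v + 3\mathcal F$, $g = b - u^2v$; steady
  state $(a+b,\, b/(a+b)^2)$.
* **GM1** — Gierer–Meinhardt with the whole $u^2/v$ term and the inhibitor
  production $u^2$ delayed.
* **GM2** — as GM1, but the inhibitor in $u^2/v$ is instantaneous; steady
  state $((a+1)/b,\,((a+1)/b)^2)$ for both GM variants.

$\epsilon^2$ (default $10^{-3}$) is the activator/inhibitor diffusion ratio
and $L^2$ (default $4.5$) the nondimensional domain-size scaling; both are
dimensionless, as are $a$, $b$ and all times.

## Delay kernels

Three kernel families cover the modelling spectrum from deterministic to
strongly skewed delays. All are truncated to $[\tau_1, \tau_2]$ with
$\tau_1 > 0$ so that only positive delays occur; the half-width multiplier
is $n = 3$ throughout.

* **Dirac** ($K = \delta(s - \tau)$): the fixed delay, $E(\lambda) =
  e^{-\lambda\tau}$ exactly.
* **Symmetric truncated Gaussian** $(\tau, \sigma)$ on
  $[\tau - 3\sigma, \tau + 3\sigma]$, renormalised by
  $\Phi_c = 1/(\Phi(3) - \Phi(-3))$. Admissibility requires
  $\sigma < \sigma_{\max} = \tau/3$.
* **Skewed truncated Gaussian** $(\mu, \omega, \rho)$: density
  $\propto \exp(-z^2/2)\,\Phi(\rho z)$ with $z = (s-\mu)/\omega$, truncated
  to $[\mu - 3\omega, \mu + 3\omega]$. The truncation constant uses the
  skew-normal cdf $\Psi(x, \rho) = \Phi(x) - 2T(x, \rho)$ with Owen's
  $T$ evaluated by composite Simpson quadrature (100,001 nodes by default —
  dense, but the function is only needed at the two window ends).

The mean of the truncated skew kernel has a closed form. Integrating
$s\,K_S(s)$ by parts over the standardized window $[\alpha, \beta] = [-n, n]$
gives

$$\tau = \mu + \omega\,\Psi_c\Big[2\varphi(\alpha)\Phi(\rho\alpha)
  - 2\varphi(\beta)\Phi(\rho\beta)
  + \tfrac{2\rho}{\hat\rho\sqrt{2\pi}}\big(\Phi(\hat\rho\beta) -
  \Phi(\hat\rho\alpha)\big)\Big], \qquad \hat\rho = \sqrt{1+\rho^2},$$

with $\varphi$, $\Phi$ the standard normal pdf and cdf. The suite verifies
this form against direct Simpson quadrature of the defining integral to
$10^{-6}$ across parameter sweeps; note that the boundary terms carry the
*unnormalised standardized* density — versions of this formula that reuse
the truncated pdf (which already contains $\Psi_c$ and $1/\omega$) do not
integrate-check. `location_from_mean()` inverts the relation for
$\mu(\tau)$, optionally solving jointly with the coupling
$\omega = c\,\mu/3$; with $\rho = \pm 10$ and mean 1 the joint solve at the
admissibility boundary gives $\omega_{\max} = 0.2640$ ($\rho = +10$) and
$0.4519$ ($\rho = -10$) — positive skew pulls the location, and with it the
admissible scale, below the mean.

## Linear stability and the transcendental dispersion relation

Linearising about the steady state and expanding in the Neumann eigenbasis
$\cos(k\pi x)$ yields, per integer wavenumber $k$,

$$\mathcal D_k(\lambda) = \lambda^2 + \alpha_k\lambda + \beta_k +
 (\gamma_k\lambda + \delta_k)\,E(\lambda) + \chi_k\,E(\lambda)^2 = 0,$$

with $E(\lambda) = \int K(s) e^{-\lambda s} ds$ the kernel transform and
coefficients assembled from the instantaneous and delayed Jacobians plus the
diffusive terms $(\epsilon^2/L^2)k^2\pi^2$, $(1/L^2)k^2\pi^2$
(`dispersion_coefficients()`; cross-checked in the tests against a
finite-difference Jacobian assembly). $\chi_k = 0$ for LI and GM2.

$\mathcal D_k$ is transcendental; the rightmost root governs stability.
`rightmost_root()` combines two complementary searches:

1. **Delay continuation.** The two explicit roots of the zero-delay
   quadratic are continued in the kernel's mean delay (all location/scale
   parameters scaled together) in steps of at most $0.05$, with a damped
   complex Newton correction at each step (step modulus capped at 2;
   convergence to $|\mathcal D_k| < 10^{-10}$ relative to the coefficient
   scale, roots accepted below $10^{-8}$). The starting roots are nudged
   $\pm 10^{-6}i$ off the real axis — a real starting pair that collides
   and moves into the complex plane is otherwise unreachable by real
   Newton arithmetic. Branches driven below $\Re\lambda = -30$ are frozen;
   they cannot contend for the rightmost root, which is guarded by:
2. **A real-axis scan.** Sign changes of the real-valued
   $\mathcal D_k$ on $\lambda \in [-20, 20]$ (step $10^{-2}$ pointwise,
   $5\times10^{-2}$ in grid scans) are refined by bisection. On the real
   axis the gaussian transform uses its error-function closed form; complex
   evaluations use fixed-node Simpson quadrature of the kernel integral
   (101 nodes by default), cross-validated against the closed form on the
   real axis.

The engine was validated against dense-grid Newton sweeps (hundreds of
starting points per $(a, b, k)$) at representative points of the parameter
window, and against the quadratic formula at zero delay to $10^{-10}$ over
hundreds of random parameter sets. Only roots passing the residual
tolerance are ever reported; a failed search is an error, never a silent
wrong root.

`max_growth_rate()` scans integer $k \in [0, 50]$ (ties towards the smaller
$k$); `turing_space_scan()` evaluates the field over an $(a, b)$ grid and
extracts the two marginal-stability contours ($\Re\lambda_0 = 0$;
$\max_{k\neq0}\Re\lambda_k = 0$) by linear interpolation of sign changes,
with contour coincidence measured by Hausdorff distance. Because
$\mathcal D_k(0) = \beta_k + \delta_k + \chi_k$ is kernel-independent
($E(0) = 1$), the $k \neq 0$ marginal line of the LI model — whose marginal
roots are real — cannot move with the delay; the suite confirms the scanned
contours at $\tau \in \{0, 0.5, 1.5\}$ coincide within one grid cell.

### Grid sensitivity of the discrepancy statistic

`distributed_vs_fixed_discrepancy()` reports
$\max_{(a,b)}\,|\max_k\Re\lambda_k^{\text{dist}} -
\max_k\Re\lambda_k^{\text{fixed}}|$ over a parameter window, the summary
used to argue that a distributed delay is linearly indistinguishable from a
fixed delay with the same mean. Two caveats discovered while validating it:

* The field $\max_k \Re\lambda_k$ is smooth in most of the window but the
  *difference* field concentrates near the lower window edge (small $b$),
  where the homogeneous mode $k = 0$ dominates and two real roots nearly
  collide; the reported maximum there grows noticeably with grid
  refinement. At the default $71\times101$ grid the
  $(\epsilon^2, \tau) = (10^{-3}, 0.2)$ window maximum is
  $2.8\times10^{-3}$, attained at $(a, b) \approx (0.52, 0.04)$, while a
  $0.1$-step grid (which misses that edge region) gives
  $1.2\times10^{-3}$. Both are honest values of the same statistic at
  different resolutions; grid shape is therefore an explicit argument and
  recorded with the result.
* Excluding the homogeneous mode ($k \in [1, 50]$) removes the edge effect
  entirely; the statistic is then resolution-robust. The default keeps
  $k = 0$ because the Turing-space analysis needs the homogeneous line.

Either way the discrepancy is $O(10^{-3})$ for mean delays up to 1 —
three orders below the unit scale of the growth rates — which is the
substantive conclusion: at the level of linear theory, only the mean of the
delay distribution matters.

## The delay-PDE simulator

`simulate_rd()` discretises space by the three-point Laplacian on $m$
equally spaced points (Neumann boundaries via reflected ghost points,
boundary row $2(f_2 - f_1)/dx^2$, which conserves the trapezoid-weighted
mass exactly; the mixed case clamps the activator to zero at both ends).
The distributed-delay integral uses composite Simpson quadrature with 51
fixed nodes across the truncation window, with the discrete weights
renormalised to sum to one so that constant histories are reproduced
exactly. Time integration is delegated to the stiff solver of
**deSolve** (`dede`, with an internally generated banded Jacobian of
bandwidth 2 on the interleaved state): a delay method-of-lines system is
exactly what that solver's dense history interpolation is built for, so the
package does not hand-roll an IMEX stepper; solution fidelity is instead
enforced by invariants — steady-state preservation, mass conservation,
grid/tolerance refinement stability, and agreement of the simulated
dominant-mode growth rate with the dispersion root to 5%, which in practice
holds to $10^{-4}$ relative in the small-domain regime. Runs can terminate
early, via the solver's root-finding, once the activator deviation crosses
a threshold (used by the time-to-pattern sweeps) and abort if any field
exceeds $10^6$ in magnitude.

History functions cover $[-\tau_2, 0]$: constant (equal to the initial
fields, the default) or oscillatory (steady state modulated by
$1 + r(x)\sin(wt)$ with $r(x)$ a seeded Gaussian field; $w \in \{1, 10\}$
and $r$-scale equal to $\sigma_{IC}$ are the package defaults, as no
canonical values exist for this robustness check).

## Pattern metrics

*Time to pattern* $T^\star$ is the first time
$\max_x|u - u_\star|$ exceeds a threshold $u_{T^\star}$, refined by linear
interpolation between output samples. The linear-theory prediction uses the
dominant-mode amplitudes $A_k$ (type-I discrete cosine transform, i.e. the
$\cos(k\pi x)$ Neumann basis, normalised so a pure mode returns its
amplitude): $T = \ln(A_k(T^\star)/A_k(0)) / \Re\lambda_k$. The real part is
used because it sets the amplitude growth; in the small-domain regime
($L^2 = 0.2$) the dominant root is real anyway. Simulated sweeps over
$\tau$ (identical seeded initial perturbations per delay) are summarised by
an ordinary least-squares line; across LI and both GM variants these fits
give $R^2 > 0.999$ with strongly positive slopes — each unit of mean delay
adds tens of time units to the patterning onset.

*Spike counting* needs a convention, since a profile on $[0, 1]$ with
Neumann boundaries is half a period of its even periodic extension.
Peaks are therefore detected on that extension: boundary maxima count as
whole peaks (not half-peaks) and the count is independent of the pattern's
phase — $1 + 0.5\cos(4\pi x)$ and $1 - 0.5\cos(4\pi x)$ both count 4.
A peak must have prominence (height above its higher flanking valley)
exceeding 20% of the field range, which suppresses grid-scale ripples in
the flat valleys between spikes.

Two honest observations about the four-spike regime
($(a,b) = (0.1, 0.9)$, $\tau = 1$, $\sigma_{IC} = 0.01$): the linear
dispersion argmax is $k = 4$, and the simulated patterns pass through a
four-spike state once established ($t \approx 70$, four of five seeds).
They do not stay there: by $t \gtrsim 100$ the spikes slowly coarsen to
2–4 (most often 3), and the coarsening is unchanged under 1000-fold
tighter solver tolerances and at $m = 500$, while the undelayed model
freezes at seed-dependent counts of 2–4. The asymptotic spike count at
these parameters is thus not a robust "4" in this implementation; the
four-spike description fits the established-but-young pattern and the
linear prediction.

## Synthetic scenarios

All inputs are generated in code. `random_ic()` draws multiplicative
Gaussian perturbations of the steady state ($\sigma_{IC} \in
\{10^{-5}, 10^{-3}, 10^{-2}, 10^{-1}\}$ across the study regimes; seeded
Mersenne-Twister, caller RNG state restored, algorithm recorded in the
result's attributes so equal seeds give bit-identical fields across
platforms). `structured_ic_surrogate()` provides a deterministic
single-mode perturbation (species out of phase) as a clearly labelled
*synthetic surrogate* for structured initial data defined only in external
appendices; it is used for qualitative robustness comparisons, never for
quantitative targets. Presets (`list_presets()`) freeze the parameter
blocks of every simulated regime.

What the generator emulates — and what it does not: spatially white
Gaussian multiplicative noise around a homogeneous state, constant or
mildly oscillatory prehistory. Real gene-expression noise is neither white
in space nor stationary, and real domains grow; passing tests therefore
demonstrate internal consistency of the analysis pipeline under its stated
assumptions, not biological realism of the initial data.

## Problem sizes and numerical defaults

Tests and examples run at desk scale, chosen as the coarsest sizes at which
every validated quantity is stable: $m = 200$ grid points for simulations
($m = 500$ reproduces the same spike physics; the convergence test checks
$<1\%$ change under refinement), solver tolerances
`atol = 1e-9, rtol = 1e-8`, dispersion scans on $71\times101$ parameter
grids with $k \in [0, 50]$, contour comparisons at $29\times41$, and
$\tau$-sweeps over the full stated delay ranges with per-run caps generous
enough that every patterning delay crosses its threshold. Degenerate
parameter points (e.g. $a = b = 0$, where no positive steady state exists)
are carried as `NA` and excluded from grid maxima. Ties in
$\operatorname{argmax}_k$ go to the smallest $k$ for determinism.

## Known limitations

* One spatial dimension, static domain, two species; no Turing–Hopf
  interaction analysis (the bottom-left corner of the LI window can mix
  both instabilities and its nonlinear dynamics are out of scope).
* The rootfinder reports the rightmost root among continued branches and
  real-axis candidates; delay-born *complex* roots far from both families
  would be missed, though dense-start Newton sweeps found none in the
  parameter windows studied.
* For mean delays beyond $\approx 2$ the continuation is increasingly
  expensive (and the underlying multi-scale rootfinding genuinely harder);
  time-to-pattern work at large $\tau$ therefore relies on simulation, not
  linear theory.
* Eigenvector amplitudes of the linearisation and amplitude equations are
  not computed; gamma/exponential kernels and kernel sampling are not
  implemented.
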