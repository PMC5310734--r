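---
title: "Methods: exact Poisson mixtures for transcription with upstream drives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact Poisson mixtures for transcription with upstream drives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txdrive)
```

## 1. Model and exact solution structure

We model a single gene product in one cell as a birth–death process:
molecules are produced at rate $\mu(t)$ and each decays at rate
$\lambda(t)$. Both rates are *upstream drives*: they may vary in time and
differ across cells (promoter switching, signalling inputs, coupled cellular
oscillators). The chemical master equation for the copy number $N(t)$,
conditioned on one realisation of the drives, is solved exactly by

$$N(t) \mid \mu(\cdot), \lambda(\cdot), N(0)=n_0 \;\sim\;
  \mathrm{Binomial}\!\left(n_0,\, e^{-\int_0^t \lambda}\right) \ast
  \mathrm{Poisson}(\chi(t)),$$

where $\ast$ is convolution and the **effective drive** $\chi$ obeys the
linear random differential equation

$$\dot\chi = \mu(t) - \lambda(t)\,\chi, \qquad \chi(0)=\chi_0 .$$

After the initial molecules have decayed (or when $n_0 = 0$, taking
$\chi_0 = 0$), the conditional law is exactly Poisson. The population
distribution is then a **Poisson mixture** over the cross-cell density
$f_X(x,t)$ of $\chi(t)$:

$$P(n,t) = \int \frac{x^n e^{-x}}{n!}\, f_X(x,t)\, dx .$$

Two structural consequences are used throughout the package and its tests:
the moment laws $\langle N\rangle = \langle X\rangle$ and
$\mathrm{Var}\,N = \langle X\rangle + \mathrm{Var}\,X$, so the ensemble Fano
factor is $1 + \mathrm{Var}\,X/\langle X\rangle \ge 1$, with equality
exactly for a synchronous (deterministically driven) population.

`solve_effective_drive()` propagates $\chi$ exactly through
piecewise-constant rate segments ($\chi = \mu/\lambda + (\chi_0 -
\mu/\lambda)e^{-\lambda h}$ per segment) and falls back to a stiff ODE
integrator (`deSolve::lsoda`, rtol $10^{-10}$, with `tcrit` pinned to the
final output time so the integrator never steps past the solved range) for
general rate paths.

## 2. Promoter architectures and their mixing densities

### Random telegraph (two-state) promoter

With switching rates $k_\mathrm{on}, k_\mathrm{off}$, transcription rate $m$
in the active state and degradation $\lambda$, the stationary effective
drive is $X = (m/\lambda) B$ with
$B \sim \mathrm{Beta}(k_\mathrm{on}/\lambda,\, k_\mathrm{off}/\lambda)$.
The mixture is the Poisson–Beta law; `poisson_beta_pmf()` evaluates it via a
confluent hypergeometric series *after* the Kummer transform
$\,_1F_1(a,b,-z) = e^{-z}\,_1F_1(b-a,b,z)$, which makes every term of the
series positive: the evaluation is cancellation-free in log space and needs
no arbitrary-precision arithmetic.

### Refractory (three-state cyclic) promoter

The promoter cycles active $\to$ refractory$_1$ $\to$ refractory$_2$ $\to$
active. In the scaled variable $y = \lambda x / m$ the stationary per-state
densities satisfy a linear ODE system with regular singular points at both
endpoints (endpoint exponents set by the scaled rates). Rather than using
special-function representations, `refractory_stationary_density()`:

1. integrates the two-dimensional basis of the system in the logit variable
   $\tau = \log(y/(1-y))$ (the system is polynomial there), starting from
   Frobenius-series expansions at $y \to 0$ and renormalising per segment
   against overflow, while quadrature states accumulate the per-state
   integrals alongside;
2. fixes the two integration constants from the integral conditions
   $\int f_s\,dy = \pi_s$ (the chain's stationary occupancies);
3. equips the returned density with its *own quadrature rule*: the $\tau$
   solve grid mapped back to $x$, trapezoid weights in $\tau$ (where the
   integrand is smooth and decays exponentially), and the exact per-basis
   Frobenius tail integrals folded into the end weights.

Step 3 matters: the density has integrable power-law singularities at both
support ends, and no single Gauss–Jacobi weight pair can absorb *two*
different left exponents — a residual $y^{|a_1-a_2|}$ term degrades Gauss
rules to roughly first-order convergence. Integrating in $\tau$ instead
gives occupancies, moments, and mixture probabilities accurate to
$\sim 10^{-9}$, verified against the truncated master equation.

### Entrained sinusoidal populations

For cells entrained to a common frequency $\omega$ with phase dispersion,
the steady-periodic effective drive of a cell at phase $\phi$ is the
sinusoid $A + B\sin(\omega t + \phi - \psi)$ with $A = m/(2\lambda)$,
$B = (m/2)/\sqrt{\lambda^2+\omega^2}$ and $\psi = \arctan(\omega/\lambda)$:
the transcriptional filter attenuates by $\sqrt{\lambda^2+\omega^2}$ and
delays by $\psi/\omega$. A population with fully wrapped phases has the
arcsine density on $[A-B, A+B]$; partial entrainment densities are built by
counting and inverting the monotone branches of the phase map. When the
drive instead targets *degradation*, the steady-periodic orbit has no closed
form; it is computed by a one-period Runge–Kutta map whose affine fixed
point gives the periodic solution, and the density follows by
monotone-segment inversion of the orbit (square-root endpoint
singularities).

For partially synchronised oscillator populations the package includes a
mean-field Kuramoto integrator; each oscillator's phase is mapped to a
transcription-rate path, effective drives are propagated per cell by the
exact exponential integrator, and the pooled snapshot yields the mixing
density. This is orders of magnitude cheaper than stochastic simulation of
every cell and is validated against exactly that in the tests.

## 3. Numerical choices

**Singularity-aware quadrature.** Mixing densities routinely behave like
$(x-\mathrm{lo})^{p_L-1}(\mathrm{hi}-x)^{p_R-1}$ at their support ends. A
`drive_density` can declare these exponents; integrals against it then use a
240-node Gauss–Jacobi rule (Golub–Welsch on the Jacobi recurrence, cached)
whose weight function absorbs the singular factors exactly. This attains
machine precision where adaptive quadrature or double-exponential rules
saturate near $10^{-6}$ in double precision. Without declared exponents,
`stats::integrate` is used and accepted only when it reports convergence; a
tanh–sinh rule and finally the stored grid weights act as fallbacks. A
density may also carry an explicit node/weight rule (`prefer_grid`), used
for the refractory density ($\tau$-space rule) and for phase-marginal
modulated-telegraph densities, whose Beta-edge singularities sit *inside*
the support and are represented by exact cell-averaged masses
(`pbeta` differences) instead of pointwise values.

**Finite-volume Fokker–Planck–Kolmogorov solver.** The multistate drive
density field solves a hyperbolic system (state-wise advection in $x$ plus
Markov switching). `fpk_*` discretise it with conservative first-order
upwind fluxes on a uniform grid; the semi-discrete system is linear, and
transients use explicit RK4 under a CFL limit (exactly mass-conserving),
while steady states replace one row of the sparse generator with the
normalisation constraint and solve directly. First-order accuracy means the
error scales like $1/n_\mathrm{cells}$; the default 8192 cells puts the
total-variation error against the master equation near $2.5\times10^{-4}$
in under a second.

**Truncated master equation oracle.** An independent cross-check: the joint
(copy number, promoter state) generator is assembled sparsely, truncated at
a copy-number ceiling that is automatically enlarged until the boundary mass
is below $10^{-10}$, and solved directly (stationary) or by the matrix
exponential (transient).

**Exact stochastic simulation.** `ssa_timevarying()` uses thinning with
per-window rate bounds. For rate paths known only on a grid the supremum is
taken as the grid maximum plus the maximum between-node increment (a
bounded-variation safety margin), and every acceptance test re-checks the
bound at the proposed time, so a too-tight bound raises an error rather than
silently biasing the sample.

**Reproducibility.** All stochastic functions take explicit seeds; CLI
outputs embed the resolved configuration (minus the output path) in their
headers, so runs are byte-for-byte reproducible from their own metadata.

## 4. Design decisions and limitations

- Exactness is pushed as far as structure allows (piecewise-exponential
  propagation, closed-form mixtures, singularity-absorbing quadrature);
  genuinely numerical steps (FPK discretisation, ODE integration, histogram
  densities from sampled paths) carry stated accuracy scalings and are
  cross-validated against at least one independent route in the tests.
- The refractory basis integration can lose independence when the two
  left endpoint exponents differ by much more than one (the dominant basis
  solution numerically contaminates the other); the standard rate regimes
  validated in the tests are far from this edge.
- The FPK solver is first-order; a limited second-order scheme was left out
  for simplicity, with resolution (not order) used to reach target accuracy.
- Histogram densities from sampled drive paths converge like
  $n^{-1/2}$ in the number of cells; the Kuramoto acceptance comparison
  budgets its tolerance accordingly.
- Fano factors of mixtures are never below 1 by construction; apparent
  sub-Poissonian values from data would indicate mechanisms outside this
  model class (e.g. feedback), not a fitting failure.

```{r}
# one end-to-end consistency check, kept tiny for the vignette
model <- rt_promoter(0.6, 0.4, 8, 1)
mix <- poisson_mixture(rt_stationary_density(model))
cme <- cme_truncated_solve(model)
tv_distance(mix$dist, cme)
```
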