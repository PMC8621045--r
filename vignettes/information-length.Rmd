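---
title: "Information length, non-equilibrium thermodynamics and geodesics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information length, non-equilibrium thermodynamics and geodesics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infolength)
```

## The model

`infolength` works with a probability density `p(x, t)` of one stochastic
variable evolving in time, and asks the dimensionless question: *through how
many statistically distinguishable states does the density pass?* The
instantaneous answer is the information rate

$$\Gamma^2(t) \;=\; \int \! dx\, p\,(\partial_t \ln p)^2 \;=\; 4\!\int\! dx\,
(\partial_t \sqrt{p}\,)^2 ,$$

a Fisher information in which time plays the role of the parameter. Its
inverse, $\tau = 1/\Gamma$, is the characteristic time over which the density
becomes distinguishable from its past self. Integrating the rate gives the
information length

$$L(t) \;=\; \int_0^t \Gamma(t_1)\, dt_1 ,$$

a path-dependent distance in the statistical manifold: unlike the endpoint
distances (Wootters angle, Kullback–Leibler and Jensen divergences, squared
L2 norm — all provided in `distance_report()`), $L$ depends on the entire
evolution. It is dimensionless, non-decreasing, invariant under
time-independent monotone changes of the coordinate $x$, and saturates to a
constant $L_\infty$ when the process reaches a stationary state.

The reference dynamics throughout is the overdamped Langevin model

$$\dot{x} = -\gamma(t)\,[x - v(t)] + \xi, \qquad
\langle \xi(t)\,\xi(t')\rangle = 2 D(t)\,\delta(t - t'),$$

whose density obeys the Fokker–Planck equation
$\partial_t p = -\partial_x(f p) + D\,\partial_x^2 p = -\partial_x J$ with
current $J = f p - D \partial_x p$. A Gaussian initial condition
$(x_0, \beta_0)$ stays Gaussian, with mean $y(t)$ and inverse temperature
$\beta(t) = 1/(2\sigma^2)$ given by exact quadrature formulas
(`ou_propagate()`). For the Gaussian family the rate has the closed form

$$\Gamma^2 = 2\beta\,\dot{y}^2 + \frac{\dot\beta^2}{2\beta^2}
          = \frac{2\dot\sigma^2 + \dot{y}^2}{\sigma^2},$$

which is the single source of truth for every analytic check in the package
(the Fisher metric used by `parametric_rate_and_bounds()` is fixed to the
consistent $g_{yy} = 2\beta$, $g_{\beta\beta} = 1/(2\beta^2)$).

## Numerical choices

**Grid and quadrature.** All densities live on a uniform grid
(`grid1d()`); every integral is a composite trapezoid sum. For the smooth,
rapidly decaying integrands arising here the trapezoid rule converges much
faster than its generic second order, so 1024–4096 nodes spanning eight
standard deviations put quadrature errors far below the tolerances quoted
in the tests. `gaussian_to_grid()` refuses grids narrower than six standard
deviations around the mean — truncation would silently bias the moments.

**Zero handling and logarithms.** Entropy integrands use the convention
$0 \ln 0 = 0$. The divergences work with log-densities (`grid_pdf`'s `lp`
field, filled analytically by `gaussian_to_grid()`), so that tail ratios
remain meaningful even where the density itself underflows double
precision; a *true* zero of the reference density under the support of the
first argument still yields the honest answer `Inf`. The Wootters inner
product is clipped to $[0, 1]$ before `acos`. The squared-norm convention is
used for the L2 distance; take `sqrt()` if the rooted norm is wanted.

**Time differentiation.** The numeric rate estimator uses the amplitude
form $4\int(\partial_t\sqrt{p})^2 dx$ — not $(\partial_t p)^2/p$ — so that
vanishing densities never enter a denominator. Time derivatives are central
differences on a uniform snapshot grid (second-order one-sided stencils at
the ends); a step irregularity beyond 1% is an error rather than a silent
accuracy loss. Refining the snapshot step by two moves $\Gamma$ by less
than 0.3%.

**Fokker–Planck solver.** `fp_solve()` uses a conservative finite-volume
discretization with exponentially fitted (Chang–Cooper) face weights and
Crank–Nicolson stepping. The face weights make the discrete stationary
state exact and keep the density positive; the flux form conserves the
discrete mass to rounding (the tests demand $10^{-8}$), and zero-flux
boundaries make the (physically irrelevant) boundary condition immaterial
as long as the boundary density stays below $10^{-12}$. Moments converge at
second order in the spacing: 2048 nodes on a 25-unit domain give relative
moment errors of a few $10^{-4}$, 4096 nodes a few $10^{-5}$ (this is the
resolution the oracle-triangle test uses for its $10^{-4}$ contract).

**Stochastic simulator.** `langevin_simulate()` is plain Euler–Maruyama
with per-step noise variance $2D\,dt$ and default
$dt = \min(10^{-3},\, 0.01/\gamma)$; ensembles are reproducible from a
single seed. Empirical densities are histograms with bins centered on the
analysis grid.

**Thermodynamics.** With $k_B = 1$ and $D$ as the effective temperature,
`thermo_gaussian()` (closed forms) and `thermo_numeric()` (grid quadrature)
return entropy $S$, the split $\dot S = \dot S_T - \dot S_m$ into total
production $\dot S_T = \int J^2/(Dp)\,dx \ge 0$ and flow
$\dot S_m = \int J f/D\, dx$, heat $\dot Q = D\dot S_m$, internal energy
$U = \langle V\rangle$, power $\dot W = \langle\partial_t V\rangle$, free
energy $F = U - DS$ with dissipated power $\dot W_D = D\dot S_T \ge 0$, the
relative entropy $K[p\,|\,p_s]$ to the frozen-parameter stationary state
(satisfying $F - F_s = D K$), and the fluctuation speed $c = \sigma\Gamma$.
A time-varying $D$ disables the free-energy outputs with an explicit error
instead of misreporting them; $\dot S_T$'s integrand is evaluated only
where $p > 10^{-14}$. The identity $\Gamma^2 = (D/\sigma^2)\dot S_T +
\dot S^2$ ties the information rate to entropy production; the
proportionality $\Gamma^2 \propto \dot S_T$ holds *only* when the variance
is frozen, and the package tests both the identity and the failure of the
shortcut.

On a numerically differentiated trajectory the closure residuals
($\dot S$ vs. $\dot S_T - \dot S_m$, $\dot U$ vs. $\dot W - \dot Q$) are
limited by the snapshot spacing when the snapshots are exact (the tests
reach $10^{-6}$ with analytically sampled snapshots at
$\Delta t = 2.5\times10^{-4}$) and by the solver's spatial discretization
when they come from `fp_solve()` (a few $10^{-4}$ at 2048 nodes — hence the
1% contract on the solved pipeline).

## Geodesics and control

In the half-plane coordinates $z = y/\sqrt2$, $\sigma$, the Gaussian family
carries twice the hyperbolic metric of the Poincaré upper half-plane, so
minimum-$L$ paths between two Gaussian states are circular arcs centered on
the $\sigma = 0$ axis, traversed at constant $\Gamma$. `solve_geodesic()`
is purely constructive — center and radius from the two endpoints, length
from the hyperbolic distance
$L = \sqrt2\,\mathrm{acosh}[1 + (\Delta z^2 + \Delta\sigma^2)/(2\sigma_0\sigma_F)]$
— and the Euler–Lagrange constants ($\beta\dot y = c$,
$\dot\beta^2 = -4c^2\beta + \alpha\beta^2$, $\Gamma = \sqrt{\alpha/2}$)
are *verified* against the construction rather than solved for by
root-finding, so a convention error anywhere would be self-detected. Pure
variance changes are the vertical-geodesic branch
($L = \sqrt2\,|\ln(\sigma_F/\sigma_0)|$), entered when the endpoint means
agree to $10^{-12}$ relatively, which keeps the two branches numerically
continuous.

`synthesize_controls()` inverts the moment dynamics to get the protocol
realizing a geodesic at fixed damping: $v = y + \dot y/\gamma$ and
$D = \gamma\sigma^2 + \tfrac12 d\sigma^2/dt$. Since
$-\dot\sigma/\sigma \le \Gamma/\sqrt2$ along a geodesic, the protocol is
feasible ($D \ge 0$) whenever $\gamma$ exceeds
$\max_t(-\dot\sigma/\sigma)$; an infeasible request fails with that
threshold in the message. Only constant-$\gamma$ synthesis is validated;
time-varying damping is left to the caller via the general
`process_spec()`. Minimality is checked variationally: 200 random smooth
endpoint-preserving perturbations of the mean and log-width never shorten
the path, and time-reparametrizing the same track preserves $L$ while
strictly increasing $\int\Gamma^2 dt$ (the Cauchy–Schwarz equality case
singles out constant speed).

## Scenarios and the synthetic-data choices

The scenario registry fixes the study configurations once:

* `scenario_relaxation()` — O-U relaxation at $\gamma = 1$, $D = 0.5$,
  started at the equilibrium variance ($\beta_0 = \gamma/2D$), $x_0$ swept
  over $1\ldots10$, horizon $t = 25$ (25 relaxation times, enough for
  $\Gamma < 10^{-8}$). Then $L_\infty = |x_0|/\sigma$ exactly — the linear
  attractor geometry — while the endpoint divergences grow super-linearly
  (convexity signs are reported).
* `scenario_dichotomous()` — two components exchanging mass by telegraph
  switching, both with drift $-\gamma x$; the switching rate $r = 1$ (of
  the order of the damping, so the coupling is strong but not averaged
  out), $x_0 \in \{1..8\}$, horizon $t = 12$. These values are this
  package's choice — the qualitative signature checked (near-coincident
  per-component $L_\infty$ curves, grossly different endpoint distances)
  is robust to them. With equal drifts the total density solves the plain
  O-U equation, which the tests pin against the analytic two-Gaussian
  mixture at $L_1 < 10^{-3}$.
* `scenario_geodesic_control()` — mean transfer $0 \to 2$ with equal
  endpoint widths $\beta_0 = \beta_F \in \{0.3, 3\}$ at $\gamma = 1$. The
  transfer time defaults to $T = L$, i.e. unit information rate; this keeps
  the synthesized $D(t) = \sigma^2(\gamma - \Gamma\tanh u/\sqrt2)$ strictly
  positive at $\gamma = 1$ and makes the two width cases directly
  comparable. The full loop — solve, synthesize, forward-solve with
  `fp_solve()`, re-estimate $\Gamma$ from the snapshots — must return a
  constant rate within 1% and the characteristic broaden-then-narrow width
  history.

What the generator does *not* emulate: non-Gaussian initial conditions,
nonlinear drifts (accepted by `fp_solve()` but without analytic oracles),
multiplicative noise, and estimation noise in densities inferred from
finite data. Passing tests therefore demonstrate the correctness of the
estimators and solvers on exactly-known ground truth, not robustness to
density-estimation error.

## Known limitations

* One spatial dimension only; no Wasserstein/optimal-transport distances.
* Forward/reverse-protocol functionals (the protocol-reversal route to
  dissipated work) are out of scope; the irreversible work is exposed only
  through the stationary-reference relative entropy, which needs no
  reversed protocol.
* The stationary free energy is held constant whenever $\beta_s$ is
  constant (the frozen-parameter convention); other conventions for
  tracking $F_s$ under a moving center change $W_{\rm irr}$ by a boundary
  term.
* KL divergences between densities with effectively disjoint numerical
  supports are reported as `Inf`; use the Wootters or L2 distances there.
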