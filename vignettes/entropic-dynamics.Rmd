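---
title: "Entropic replicator dynamics: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropic replicator dynamics: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocontinuum)
```

## The model

The state of the system is a probability distribution
$p = (p_1, \dots, p_n)$ over $n \ge 2$ discernible state types of the
biological continuum — equivalently, the type proportions of a competing
population.  Its evolution is the replicator equation

$$\dot p_i = \big(f_i(p) - \langle f(p)\rangle\big)\, p_i,
  \qquad \langle f(p)\rangle = \sum_i p_i f_i(p),$$

the normalization $p_i = P_i / \sum_j P_j$ of the Lotka–Volterra growth
law $\dot P_i = f_i P_i$ (the quotient rule makes the two routes
equivalent, and `simulate_lv_normalized()` exercises that equivalence
numerically).  The fitness landscape $f$ may be constant, linear in $p$
through a payoff matrix ($f_i(p) = (Ap)_i$), or an arbitrary registered
function of $p$; frequency-dependent fitness is always evaluated at the
*normalized* state, which resolves the ambiguity between abundance- and
fraction-valued arguments in the two formulations.

Along the flow we track the entropic observables in nats:

* Shannon entropy $S(p) = -\sum_i p_i \ln p_i$, with the exact rate
  obtained by substituting the replicator equation,
  $\dot S = -\sum_i (f_i - \langle f\rangle) p_i \ln p_i$;
* relative information against a fixed target state $q$,
  $I(q, p) = \sum_i q_i \ln(q_i/p_i)$, with exact rate
  $\frac{d}{dt} I(q,p) = \sum_i f_i(p)\,(p_i - q_i)$.

Two conventions deserve a note.  First, $I(q,p)$ sums over the *target*
$q$: it is the divergence whose second-order expansion gives the Fisher
metric and whose descent certifies convergence toward $q$.  Second, the
exact rate formula contains no logarithms: because $q$ is constant,
$\dot I = -\sum_i q_i \dot p_i / p_i$, and the replicator substitution
collapses this to $\sum_i f_i(p)(p_i - q_i)$ — the chain rule confirms
that evaluating $f$ at the current $p$ keeps this exact even for
frequency-dependent landscapes.  Both identities are verified in the test
suite by second-order finite differences on refined grids.

### Classical consequences the package checks

* **Fisher's fundamental theorem.**  For constant $f$,
  $\frac{d}{dt}\langle f\rangle = \mathrm{Var}_p(f)$: mean fitness rises
  at the rate of its own variance.  `fitness_variance()` and the
  trajectory's finite-differenced mean fitness agree to the grid's
  truncation order.
* **Lyapunov behaviour of $I(q, p(t))$.**  With constant fitness and
  $q$ the dominant vertex, $\dot I = \langle f\rangle - f_{\max} \le 0$
  everywhere, so $I$ decays monotonically (`lyapunov_analysis()`).  For
  the antisymmetric rock–paper–scissors payoff and the uniform interior
  equilibrium $q$, $\dot I = p^\top A p - q^\top A p \equiv 0$, so $I$ is
  an orbit invariant; the integrator preserves it to ~$10^{-11}$ over
  $t \in [0, 50]$.
* **Potential games.**  For symmetric $A$, the replicator flow is the
  natural-gradient ascent of $V(p) = \tfrac12 p^\top A p$ under the
  Shahshahani metric; `replicator_is_natural_gradient_check()` verifies
  the monotone ascent trajectory-by-trajectory.

## The action functional

With kinetic information $\dot I = \sum_i f_i (p_i - q_i)$ and potential
information $I(q, p)$, the Lagrangian integrand is their difference and

$$\mathrm{ACTION} \;=\; \int_{t_0}^{t_1}
  \Big[\textstyle\sum_i f_i(p)(p_i - q_i) - \sum_i q_i \ln(q_i/p_i)\Big]\,dt .$$

The integral is taken over the simulated trajectory's time span with
composite-trapezoid quadrature.  No variational optimization over paths
is performed: the trajectory already arises from the replicator flow, and
the action is computed as a diagnostic functional along it.  (An
exploratory, non-asserting perturbation check lives in the test suite;
whether the replicator path is extremal among perturbed paths is an open
modelling question we deliberately do not claim.)  Quadrature error is
$O(\Delta t^2)$; `action_integral()` warns (`GridTooCoarse`) when
coarsening the grid by a factor of two moves the value by more than
$10^{-4}$ relative, the trapezoid estimate of that error.

## Information geometry

The geometry module implements the standard constructions for the two
manifolds in play:

* the categorical simplex with the Fisher/Shahshahani metric
  $g_{ij} = \delta_{ij}/p_i$ (applied to tangent vectors summing to 0);
* the Gaussian location–scale manifold in $(\mu, \sigma)$ coordinates
  with $g = \mathrm{diag}(1/\sigma^2,\, 2/\sigma^2)$.  $\sigma$ is the
  standard deviation; the coordinate pair is the usual mean–spread
  parameterization of a distribution-valued state.

Both metrics are cross-checked against the model-free definition — the
second-order expansion $KL(x \,\|\, x+\delta) \approx
\tfrac12 \delta^\top g(x) \delta$ — at seeded random points.  The
Fisher–Rao geodesic distance uses the hyperbolic half-plane closed form
$$d = \sqrt{2}\,\mathrm{arccosh}\!\Big(1 +
  \frac{(\Delta\mu)^2/2 + (\Delta\sigma)^2}{2\sigma_a\sigma_b}\Big),$$
validated in the tests by an independent geodesic *shooting* oracle that
integrates the geodesic ODE of the metric at unit speed and root-finds
the departure angle — the two routes agree to $10^{-6}$.

`natural_gradient_flow()` iterates
$x \leftarrow x - \mathrm{step}\cdot g(x)^{-1}\nabla V(x)$ with central
finite-difference gradients (relative step $10^{-6}$, so arbitrary user
objectives are supported) and a backtracking line search (up to 30 step
halvings), which guarantees non-increasing objective values.  On the
simplex the natural-gradient step takes the replicator-like form
$p_i(\partial_i V - \sum_j p_j \partial_j V)$ and each iterate is
re-projected onto the interior of the simplex; finite-difference probes
are evaluated on the renormalized point, which leaves the tangential
gradient component — the only one the step uses — unchanged.  The flow
stops cleanly when the natural-gradient norm falls below `grad_tol`
(flat objectives therefore stay at their start) and raises `StalledFlow`
only when a significant gradient admits no decrease at the minimum step.

## Numerical choices

* **Integrator.** `deSolve`'s `lsoda` with defaults
  `rtol = 1e-8`, `atol = 1e-10`.  The right-hand side renormalizes its
  argument and the output states are clipped to $[0,1]$ and renormalized,
  so reported states sit on the simplex to machine precision; the
  replicator field itself conserves $\sum_i p_i$ analytically, so this
  projection corrects only solver drift.
* **Boundary convention.** Probabilities exactly 0 are legal states.
  All logarithms use $\max(p_i, \texttt{prob\_floor})$ with
  `prob_floor = 1e-12`, and entropy sums apply the limit
  $0\ln 0 = 0$.  `kl_divergence()` returns `Inf` with a
  `SupportMismatch` warning when $q$ has mass where $p$ is below the
  floor.
* **Abundance overflow guard.** The Lotka–Volterra route integrates
  interval-by-interval on the output grid and rescales the counts by
  their sum whenever the total leaves $[10^{-12}, 10^{12}]$; rescaling
  is invisible after normalization.
* **Equilibria.** All $n$ vertices are exact fixed points and reported
  always.  Interior equilibria are sought only for linear landscapes,
  where they solve a linear system; the solve is declared singular (and
  flagged) when the system's reciprocal condition number drops below
  $10^{-12}$.  A constant landscape with range below $10^{-12}$ is
  flagged neutral — every point is fixed — and ties within that
  tolerance also disable the "unique fittest type" fixation diagnostic.
* **Problem sizes.**  The shipped checks use 2–6 types, output grids of
  101–2001 points (and a 4001-point quadrature reference), 50 random
  landscapes for conservation sweeps and 100 for potential-game and
  metric-oracle sweeps; these sizes make every property's expected
  signal (e.g. the $4\times$ error contraction under grid halving)
  cleanly resolvable above solver noise.

## What the random-scenario generator emulates

`generate_random_scenario()` draws the initial state from a flat
Dirichlet distribution (uniform on the simplex — no preferred type) and
landscapes with standard-normal entries, symmetrized $(M + M^\top)/2$
for potential games or antisymmetrized $(M - M^\top)/2$ for zero-sum
games.  Unit-variance fitness on an $O(1)$ time span puts the dynamics
in the regime where selection, cycling and fixation all occur within the
simulated window.  These fixtures emulate the *mathematical* conditions
of the theory — smooth landscapes, exact normalization, no noise.  They
do not emulate demographic stochasticity, mutation, measurement error or
model misspecification, so the passing property suite certifies the
deterministic information dynamics, not the behaviour of inference on
noisy biological data.

## Known limitations

* Finite type spaces only; no continuous-state (infinite-type)
  distributions.
* Deterministic dynamics only: no Moran/Wright–Fisher sampling noise and
  no mutation–selection balance.
* Equilibrium finding for custom (nonlinear) landscapes is out of scope;
  only vertices would be reported and the package refuses rather than
  mislead.
* The action is a diagnostic along the simulated path; Euler–Lagrange
  path optimization and Hamiltonian reformulations are not implemented.
* The geometry module covers the categorical and Gaussian families;
  general exponential-family geometry, $\alpha$-connections and
  curvature tensors are not provided.

## A compact session

```{r example}
sc <- scenario(constant_fitness(c(1, 0)), p0 = c(0.5, 0.5), q = c(1, 0),
               t_span = c(0, 10), n_points = 201)
traj <- simulate_replicator(sc)
summary(traj)
lyapunov_analysis(traj, c(1, 0))
action_integral(traj)
```
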