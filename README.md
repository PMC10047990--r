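# biocontinuum

Entropic replicator dynamics and information geometry for biological
state spaces.

## What this package is for

A living system can be described by a probability distribution
p = (p₁, …, pₙ) over the discernible state types of its *biocontinuum* —
the information state space spanning the organism and everything it
exchanges matter, energy or information with.  Adaptation reshapes that
distribution by selection: each type's share grows in proportion to its
fitness excess over the population mean, the classic replicator equation

    dpᵢ/dt = (fᵢ(p) − ⟨f(p)⟩) pᵢ,      ⟨f(p)⟩ = Σᵢ pᵢ fᵢ(p),

which is the normalization of the Lotka–Volterra growth law
dPᵢ/dt = fᵢ Pᵢ.  The package simulates these dynamics for constant,
payoff-matrix (frequency-dependent) and custom fitness landscapes and
tracks the information-theoretic observables that make the dynamics
*entropic*:

* Shannon entropy S(p) = −Σ pᵢ ln pᵢ and its exact production rate
  Ṡ = −Σ (fᵢ − ⟨f⟩) pᵢ ln pᵢ (nats/time);
* relative information I(q, p) = Σ qᵢ ln(qᵢ/pᵢ), the Kullback–Leibler
  divergence between a fixed target state q and the current state, with
  its exact rate dI/dt = Σ fᵢ (pᵢ − qᵢ); I(q, p(t)) serves as a Lyapunov
  function of the flow (and as a conserved orbit invariant for zero-sum
  games);
* the information ACTION ∫ [Σ fᵢ(pᵢ − qᵢ) − Σ qᵢ ln(qᵢ/pᵢ)] dt — the
  time integral of a Lagrangian whose kinetic term is dI/dt and whose
  potential term is I itself;
* the information geometry shaping the trajectories: the Fisher
  (Shahshahani) metric diag(1/pᵢ) on the simplex, the Fisher metric
  diag(1/σ², 2/σ²) on the Gaussian (µ, σ) manifold, the closed-form
  Fisher–Rao geodesic distance, and natural-gradient descent flows
  x ← x − step · g(x)⁻¹ ∇V(x).

It is aimed at researchers in evolutionary dynamics, theoretical/systems
biology and information physics who want a small, well-tested simulator
for these quantities, with scenario definitions in JSON and trajectories
exported as CSV.

## Worked example: a selective sweep

Two types, constant fitness f = (1, 0), started from the uniform state,
with the dominant vertex q = (1, 0) as target:

```r
library(biocontinuum)

sc <- scenario(constant_fitness(c(1, 0)), p0 = c(0.5, 0.5), q = c(1, 0),
               t_span = c(0, 10), n_points = 201)
traj <- simulate_replicator(sc)
summary(traj)
#> Replicator trajectory: 201 points, 2 types, t in [ 0 , 10 ]
#>   initial state: 0.5 0.5
#>   final state:   1.00e+00 4.54e-05
#>   entropy range: 0.000499378 0.693147181 nats
#>   max |sum(p) - 1|: 1.11e-16
#>   final I(q,p): 4.53989e-05 nats
```

The fitter type sweeps to fixation (p₁(t) = e^t/(e^t + 1), so
p₂(10) = 4.54·10⁻⁵); entropy falls from its uniform maximum ln 2 toward 0,
and the remaining information to be learned I(q, p) decays monotonically —
the Lyapunov property:

```r
lyapunov_analysis(traj, c(1, 0))
#> <Lyapunov report> I(q, p(t)) over 201 points
#>   monotone non-increasing: TRUE  (max positive increment 0.000e+00 nats)
#>   conserved: FALSE
#>   I(0) = 0.693147, final I = 4.53989e-05 nats

action_integral(traj)
#> <action result> over 201 grid points, t in [ 0 , 10 ]
#>   action: -1.5156796 nats
#>   final potential I(q,p): 4.53989e-05 nats
```

The action is negative because both the kinetic term (information being
assimilated, dI/dt ≤ 0 here) and minus the potential (information still
missing) are negative along the approach to the goal state.

Equilibria of a rock–paper–scissors payoff, including the interior
equal-fitness point:

```r
A <- rbind(c(0, -1, 1), c(1, 0, -1), c(-1, 1, 0))
find_equilibria(payoff_fitness(A), 3)
#> <equilibrium report> 4 fixed points
#>   vertex   [1, 0, 0]  residual 0.00e+00
#>   vertex   [0, 1, 0]  residual 0.00e+00
#>   vertex   [0, 0, 1]  residual 0.00e+00
#>   interior [0.3333, 0.3333, 0.3333]  residual 0.00e+00
```

Scenarios round-trip through JSON (`read_scenario()`, `write_scenario()`),
trajectories through CSV (`write_trajectory()`, `read_trajectory()`), and
a thin command-line wrapper with subcommands `simulate`, `observables`,
`action`, `equilibria`, `geometry` and `generate` is installed at
`system.file("cli", "biocontinuum.R", package = "biocontinuum")`.

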