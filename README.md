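# cadyn — adaptive dynamics of competitive-ability games

`cadyn` is an R package for a game-theoretic model of microbial
competition and its evolutionary dynamics.  A species is identified with
the distribution of *competitive ability* (CA) across its individuals: a
nonnegative vector **y** indexed by discrete levels `k/M`, or a nonnegative
density `f(x)` on `[0, 1]`.  Random pairwise contests — the stronger
individual wins, ties do nothing — give the zero-sum, symmetric payoffs

    E[y, z] = Σ_k y_k ( Σ_{j<k} z_j − Σ_{l>k} z_l )
    E[f, g] = ∫ f(x) ( ∫_0^x g − ∫_x^1 g ) dx

with every species bound by a cap on its *mean competitive ability*,
MCA ≤ 1/2.  The Nash equilibria are the flat strategies (constants, or
parity patterns `(a,b,a,…,a)` in the discrete game with `M` even), and the
canonical equation of adaptive dynamics turns the game into a constrained
gradient flow

    ∂f/∂t = (1 − H(w(f)) P) ∇E(f),      w(f) = ∫ (x − 1/2) f(x) dx,

where `∇E(f)(x) = 2∫_0^x f − ∫_0^1 f` is the selection gradient, `P`
projects onto the constraint normal `x − 1/2`, and the Heaviside switch `H`
activates the projection abruptly once the MCA reaches 1/2.  The discrete
version `dy/dt = (I − H(w·y)P) L y` is linear, with `L` the skew Toeplitz
matrix (−1 above, +1 below the diagonal), and is solved in closed form via
its real Jordan structure: a zero eigenvalue with parity-law multiplicity
and Jordan chains, plus simple purely imaginary pairs `±iβ` that make every
trajectory a sum of polynomial and rotating modes.  Equilibria of the game
are exactly the stationary states of the flow; they are neutrally stable,
perturbations never decay, and a branching-like drift of the CA
distribution follows.

The package is aimed at theoretical ecologists and applied mathematicians
who want to compute with this model: payoffs and equilibrium checks,
selection gradients and covariance transforms, exact spectral structure,
forward-Euler simulation with per-step diagnostics, and the numerical
experiments (branching, low-MCA constraint crossing, worked example,
reverse-time seeding), all scriptable from R or the bundled `cadyn` CLI.

## Worked example

The sampled parabola `f0(x) = (x − 1/2)^2` on the `M = 6` grid vanishes at
the midpoint node and equals `1/36` at `x4 = 2/3`; the constrained
gradient there is exactly `−11/810`, so one Euler step of size ε gives
`1/36 − 11ε/810`:

```r
library(cadyn)
we <- run_worked_example(eps = 2)
we$f0_at_x4       # $num 1   $den 36
we$gradient_at_x4 # $num -11 $den 810   (exact rational arithmetic)
we$update_at_x4   # $num 1   $den 1620  — still positive: 2 < 810/396
```

Conservation on the constraint surface: from a non-constant strategy with
MCA exactly 1/2, Euler integration keeps MCA, mass and L² norm fixed,

```r
s  <- random_strategy(1, 200, target_mca = 0.5, kind = "function")
tr <- integrate_dynamics(s, sim_config(step_size = 1e-3, n_steps = 1000,
                                       record_every = 250))
tr$diagnostics
#>      t mca     mass  l2_norm constraint_active
#> 1 0.00 0.5 0.614132 0.631917              TRUE
#> ...
#> 5 1.00 0.5 0.614132 0.631917              TRUE
```

and the exact spectral structure of the discrete flow is one call away:

```r
spectral_decomposition(10)
#> <ca_spectral> constrained branch, M = 10: zero eigenvalue multiplicity 3,
#>   4 rotation pairs (beta in [0.2963, 2.303])
kernel_dimension(50)  # 2   (51 x 51: odd dimension)
kernel_dimension(49)  # 1   (50 x 50: even dimension)
```

Branching: perturbing the uniform equilibrium `(1, …, 1)` (51 levels) by
±0.01 at the midpoint drives evolution in exactly opposite directions —
`run_branching(M = 50, delta = 0.01)` reports a mirror-symmetry residual at
machine precision (`4.6e-13` over 500 steps).

## Command line

```sh
cadyn spectra --M 10 --out spectra.json
cadyn experiment branching --M 50 --delta 0.01 --out runs/
cadyn equilibrium-check --input strategy.csv --kind function
cadyn simulate --config run.yaml --out runs/
```

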