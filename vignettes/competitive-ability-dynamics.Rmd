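---
title: "Adaptive dynamics of competitive-ability games: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive dynamics of competitive-ability games: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadyn)
```

## The model

A species is identified with its *strategy*: the distribution of
competitive ability (CA) across its individuals.  In the discrete game CA
takes the values $k/M$, $k = 0, \dots, M$, and a strategy is a nonnegative
vector $\mathbf{y}$ with positive total; in the continuous game it is a
nonnegative density $f$ on $[0,1]$ with positive integral.  Abundances are
deliberately *not* normalized to probabilities — the linear structure of
everything below is cleaner without it, and no result depends on the
normalization.

Individuals meet in random pairwise contests: the stronger wins, equal CA
is a draw.  Summing wins minus losses gives the bilinear payoffs
$$E[\mathbf{y},\mathbf{z}] = \sum_k y_k\Big(\sum_{j<k} z_j - \sum_{\ell>k} z_\ell\Big),
\qquad
E[f,g] = \int_0^1 f(x)\Big(\int_0^x g - \int_x^1 g\Big)\,dx,$$
which are zero-sum and symmetric ($E[a,b] = -E[b,a]$, $E[a,a]=0$).  Ties
contribute nothing because the index ranges are strict; no tie-break
parameter exists.  A species facing several opponents competes against
their component-wise sum, and the payoff is additive in the opponents.

The game is kept fair by a cap on the *mean competitive ability*
$$\mathrm{MCA}(f) = \frac{\int_0^1 x f(x)\,dx}{\int_0^1 f(x)\,dx} \le \tfrac12 .$$
The support $[0,1]$ and the bound $1/2$ are conventions, not restrictions:
any bounded CA interval and any cap can be brought to this form by an
affine change of variables.

The Nash equilibria are the flat strategies: positive constants in the
continuous game; positive multiples of $(1,\dots,1)$ for $M$ odd and the
alternating patterns $(a,b,a,\dots,a)$, $a,b \ge 0$ not both $0$, for $M$
even.  No strategy is evolutionarily stable: for any candidate $S$ there is
a $T$ with $E[S,T] = 0$ and $E[T,T] = 0$, so both ESS conditions fail.

## The constrained flow

Adaptive dynamics approximates rare-mutation evolution by the canonical
equation $\dot f = \tfrac12 \mu \bar n \int \sigma^2(x,y)\, g_f(y)\,dy$.
Mutation probability $\mu$ and equilibrium population size $\bar n$ only
set the time unit, so the prefactor is fixed to one.  The
invasion-fitness gradient of this game is
$$\nabla E(f)(x) = \int_0^x f - \int_x^1 f = 2\int_0^x f - \int_0^1 f,$$
nondecreasing whenever $f \ge 0$, with $\frac{d}{dx}\nabla E(f) = 2f$.

The MCA cap is the linear inequality $w(f) \le 0$ with
$w(f) = \int (x - \tfrac12) f$.  Following the standard treatment of
inequality constraints through a transformed variance–covariance kernel,
the flow removes the component of $\nabla E(f)$ along the constraint
normal $x - \tfrac12$ *only when the constraint is active*:
$$\dot f = A f = \big(1 - H(w(f))\,P\big)\nabla E(f), \qquad
P(g) = \frac{\langle g,\, x-\tfrac12\rangle}{\|x-\tfrac12\|^2}\,(x-\tfrac12).$$
The switch is abrupt by construction — there is no boundary layer.  We take
$H(0) = 1$: the boundary counts as active, which is the convention that
makes $w$ conserved from the moment the surface is reached.  In practice
the indicator is evaluated as $w \ge -\texttt{switch\_tolerance}\cdot
\text{mass}$ with a default relative tolerance of $10^{-12}$, because the
dynamics branches on this predicate and exact zero is not a robust
floating-point test.

Key consequences implemented and tested here: constants are the only
eigenfunctions of $A$ (eigenvalue 0), hence the only stationary states —
exactly the equilibria of the game; on the surface, MCA, mass and the
$L^2$ norm are conserved; below the surface the MCA increases at rate
$2(\tfrac12-\mathrm{MCA})^2 + \int x(1-x)f/\int f$, which stays above the
comparison curve $g(t) = \tfrac12 - 1/(c_0 + 2t)$; and for small $t$ the
evolved strategy defeats its ancestor with initial slope
$\|\nabla E(f_0)\|^2$.

In the discrete game the same construction is the linear system
$\dot{\mathbf y} = (I - H(\mathbf w\cdot\mathbf y)P)L\mathbf y$ with $L$
skew Toeplitz ($-1$ above, $+1$ below the diagonal),
$w_j = j/M - \tfrac12$ and $P = \mathbf w\mathbf w^T/\|\mathbf w\|^2$.
Note the sign conventions: $\mathbf w \cdot \mathbf y \ge 0$ is equivalent
to $\mathrm{MCA}(\mathbf y) \ge \tfrac12$ (for positive mass), which is
what the Heaviside tests.

## Exact structure of the vector flow

The structural claims about $L$ and $(I-P)L$ are exact integer/rational
statements and are computed that way:

* **Characteristic polynomial of $L$** in dimension $n$:
  $\sum_k \binom{n}{2k}\lambda^{2k}$ for $n$ even,
  $-\lambda \sum_k \binom{n}{2k+1}\lambda^{2k}$ for $n$ odd — binomial
  coefficients, returned as exact integers (`char_poly_L()`).  The test
  suite checks them against an independent oracle (exact determinant
  interpolation) for dimensions up to 8.
* **Parity laws.** $\operatorname{rank} L = M{+}1$ ($M{+}1$ even) or $M$
  ($M{+}1$ odd); $\dim\ker (I-P)L = 1$ ($M{+}1$ even) or $2$ ($M{+}1$
  odd).  No bignum library is available to this package, and fraction-free
  (Bareiss) elimination overflows double-precision integers near dimension
  20, so `exact_rank()` scales $(I-P)L$ to the integer matrix
  $S_4(I-P)L$ (with $S_4 = \sum_j (2j-M)^2$) and takes its rank by
  Gaussian elimination over three word-size prime fields.  Rank modulo a
  prime never exceeds the rational rank and equals it for all but finitely
  many primes; the maximum over the primes is additionally cross-checked
  against a tolerance-based SVD rank, and a disagreement is an error, not
  a fallback.
* **Kernels and Jordan chains.** Closed forms: for $M{+}1$ even the kernel
  is spanned by $\mathbf 1$ and the partner $v_2 = (2,0,2,0,\dots)$
  satisfies $(I-P)L\,v_2 = \mathbf 1$ exactly (verified in exact rational
  arithmetic by `ipl_apply_exact()`); for $M{+}1$ odd the kernel is the
  span of the even- and odd-position indicators.  The algebraic
  multiplicity of the zero eigenvalue is *reported empirically* by
  `spectral_decomposition()` — it is found to be 2 (even dimension, one
  chain of length 2) and 3 (odd dimension, a chain of length 2 plus a
  simple kernel vector) for every $M \le 20$ tested, consistent with the
  general lower bounds, but no closed form is assumed.
* **Propagator.** All eigenvalues are purely imaginary; the nonzero ones
  come in simple conjugate pairs $\pm i\beta_j$.  The real basis $Q$ uses
  the analytic zero-eigenvalue chains (numerically completing a defective
  eigenstructure is ill-conditioned, so the generalized eigenvector in the
  odd case is obtained by a least-squares solve against the analytic
  kernel combination that lies in the range) followed by real/imaginary
  parts of the pair eigenvectors with a fixed phase normalization, and the
  solution is $Q B(t) Q^{-1}\mathbf y_0$ with polynomial upper-triangular
  blocks $t^k/k!$ for the zero chain and rotation blocks for the pairs.
  Tests compare it to a scaling-and-squaring matrix exponential
  (`Matrix::expm`), an oracle independent of the Jordan construction.
  A defective zero eigenvalue splits numerically at roughly
  $\sqrt{\varepsilon_{\text{mach}}} \approx 10^{-8}$, so eigenvalues are
  classified as "zero group" below $10^{-6}$ of the spectral scale; the
  assembled basis is rejected if its condition number exceeds $10^8$.

## Quadrature conventions

All function-space integrals use the trapezoid rule on the closed uniform
grid $x_j = j/M$ (exact for linear integrands; the quadrature of 1 is
exactly 1 and $\int(x-\tfrac12)\,dx = 0$ exactly).  Three choices deserve
explanation because they interact:

* **Two bilinear forms.**  The payoff uses the *skew* discretization of the
  sign kernel (zero diagonal everywhere, including the two corners), which
  makes $E[f,f] = 0$ and $E[f,g] = -E[g,f]$ hold to machine precision.
  The selection gradient uses the *cumulative-trapezoid* rule
  $2C_i - T$, which is exact at every node for constant $f$.  The two
  differ only in the two boundary rows, by $O(h)$ there and $O(h^2)$ in
  any integrated quantity.  One rule cannot have both exactness
  properties: the corner entries that make the form skew are precisely the
  ones the one-sided boundary rule needs.
* **The computed 12.**  The continuum normalization
  $12 = 1/\int(x-\tfrac12)^2dx$ is *not* hard-coded: the projection uses
  $1/\sum_j q_j (x_j-\tfrac12)^2$ under the package quadrature, so that
  $P$ is exactly idempotent and $w$ is conserved exactly (not just to
  $O(h^2)$) along the projected discrete flow.  This is why the MCA of a
  surface trajectory is conserved to $10^{-12}$ and better rather than to
  quadrature accuracy.
* **Kernel form of $A$.**  `gradient_kernel_matrix()` returns the matrix
  $K$ with $Af = Kf$ *exactly*, built by summation-by-parts from the same
  quadrature; its separable part converges to the analytic kernel
  $12(x-\tfrac12)(y^2-y)$ as the grid is refined (a convergence test, not
  a node-wise identity — a literal sampling of the analytic kernel could
  only agree to $O(h^2)$).
* **The discrete delta.**  The explicit $\sigma^2$ matrix of
  `transform_covariance()` represents $\delta_x(y)$ as
  $\operatorname{diag}(1/q_j)$ (inverse quadrature weights) rather than
  $M\cdot I$: only then does the quadrature composition
  $\tilde P U \tilde P$ with $U = \delta$ reproduce
  $\delta - 12(x-\tfrac12)(y-\tfrac12)H(w)$ exactly on the grid,
  boundary nodes included.  With $M \cdot I$ the identity fails at the two
  endpoints at $O(1)$.  Inside the dynamics the delta is never
  materialized: $\sigma^2$-application is implemented as
  (identity − active · projection).

## Integration scheme

The default integrator is plain forward Euler,
$f_{n+1} = f_n + \varepsilon A(f_n)$, with the Heaviside evaluated at the
current state.  This is a deliberate choice, not a limitation: the abrupt
branch switch and its step-size artifacts are part of what the experiments
study, and all qualitative findings are reproduced with this scheme.  An
`rk4` method exists for convergence cross-checks (one test also
cross-checks against `deSolve`), and an `exact` method (vector game only)
pieces together the closed-form propagators of the two branches, locating
the first crossing of $w = 0$ by scanning before polishing with a root
finder — $w(t)$ oscillates, so a naive bracketing over the whole horizon
can return a later root.

Behavior at the constraint surface:

* once active, the constraint stays active; the projected flow conserves
  $w$ exactly in the discrete algebra, so no re-projection or clipping of
  the state is ever performed;
* a step that *crosses* the surface overshoots by
  $O(\varepsilon \cdot \dot w)$, and that overshoot is frozen by the
  projection.  In the vector game $\sum_j (L\mathbf y)_j = -2Mw$, so a
  positive frozen overshoot makes the total mass decay — visibly so at
  coarse $\varepsilon$.  This is a real property of the scheme, halving
  with $\varepsilon$; the optional `switch_refinement` splits the crossing
  step exactly at $w = 0$ (the crossing fraction is linear in the state)
  for users who want to suppress it.  It is off by default because the
  plain scheme is the object of study;
* negative components are stored and flagged (`is_admissible`, a warning),
  never clipped: strategies leaving the admissible cone is an expected
  phenomenon of this flow, starting e.g. from data that vanishes somewhere.

Conservation diagnostics at fixed grid deserve one honest caveat: in the
function game the drift of mass and $L^2$ norm along a surface trajectory
is the sum of an $O(\varepsilon)$ integrator term and an $O(h^2)$
quadrature bias, and at practical settings ($h = 1/100$,
$\varepsilon \le 10^{-2}$) the bias dominates, so the drift does *not*
halve with $\varepsilon$.  The vector game has no quadrature: mass is
conserved exactly and the $L^2$ drift is purely $O(\varepsilon)$, halving
cleanly under step halving.  The test suite asserts exactly this split.

## Fixtures

`random_strategy()` is the package's only random-input generator.  It
draws strictly positive uniform samples on $[0.2, 1]$ (bounded away from
zero so fixtures are unambiguously admissible), then either symmetrizes
about $x = \tfrac12$ — giving MCA $= \tfrac12$ exactly, by reflection — or
applies a deterministic exponential tilt $f(x)e^{\theta x}$ with $\theta$
root-found so the MCA hits the requested target within $10^{-12}$.  Same
seed, same strategy, bitwise; the global RNG state is untouched.  These
fixtures emulate rough, featureless CA distributions; they do not emulate
multimodal or heavy-tailed abundance profiles, correlated noise, or
near-zero densities, so tests passing on them demonstrate the algebraic
and dynamical identities, not robustness of the discretization on stiff
real profiles.

## Experiments and their defaults

* **Branching** (`run_branching`): $M = 50$ (51 levels), perturbation
  $\pm 0.01$ at the midpoint index 25 — the midpoint direction is exactly
  orthogonal to $\mathbf w$, so both perturbed states sit on the surface.
  Because the active-branch flow is linear, the $+$ and $-$ runs are exact
  mirrors through the equilibrium; the driver reports the mirror residual,
  which sits at accumulated machine precision.
* **Low-MCA crossing** (`run_low_mca`): the published trajectories' initial
  data are shown only graphically, so the driver uses a documented
  synthetic stand-in, the exponentially decreasing profile $e^{-4x}$
  (MCA $\approx 0.22$), and asserts structural behavior only: MCA strictly
  increasing before the crossing, pinned at $\tfrac12$ after (judged on
  the fine run, while the state remains a strategy), and the physical
  crossing time $\varepsilon \times$ step count invariant across
  $\varepsilon \in \{2\cdot 10^{-2}, 2\cdot 10^{-4}\}$ to within one
  coarse step.  The finer of the two published step-size figures quotes
  $2\cdot 10^{-4}$ in the text and $2\cdot 10^{-3}$ in its caption; only
  the former is consistent with the quoted iteration counts, so it is the
  default here.
* **Worked example** (`run_worked_example`): $f_0(x) = (x-\tfrac12)^2$
  sampled on $M = 6$; $f_0(x_4) = 1/36$ and
  $A f_0(2/3) = \tfrac23(\tfrac16)^3 - \tfrac1{10}\cdot\tfrac16 =
  -11/810$ are computed in exact rational arithmetic (a small
  rational-polynomial module: integrals and evaluations of
  rational-coefficient polynomials), alongside the fine-grid quadrature
  values and the sign scan showing the density dipping below zero just
  above $x = \tfrac12$.
* **Reverse-time seeding** (`run_reverse_time`): integrating
  $\dot{\mathbf y} = -L\mathbf y$ from $(1,\dots,1)$ for a short horizon
  ($T = 0.05$ by default — components move at rate up to $M$, so large $T$
  exits the positive cone) produces strictly positive seeds that flow back
  onto the equilibrium within integration error.

Problem sizes throughout the tests — grids up to 300 nodes, $M \le 50$
systems, horizons of a few thousand Euler steps — are the package's
desk-scale defaults: every identity they probe is resolution-independent,
and each file runs in seconds.

## Known limitations

* The function-game conservation diagnostics carry the fixed-grid $O(h^2)$
  bias discussed above; refine the grid, not just the step, when tracking
  invariants.
* `spectral_decomposition` guarantees its structure only for this matrix
  family ($L$ and $(I-P)L$); it is not a general real-Jordan-form routine,
  and it refuses matrices whose rotation frequencies collide or whose
  assembled basis is ill-conditioned.
* The deterministic flow is the whole scope: there is no individual-based
  mutation–selection simulation, no stiff/implicit solver, and no support
  for CA supports other than $[0,1]$ (a change of variables covers them).
* Strategies are not probability-normalized, by design; users wanting
  densities should divide by the mass, which is conserved exactly where
  the theory says it is.
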