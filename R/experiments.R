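# Numerical experiments: evolutionary branching around the uniform
# equilibrium, the abrupt constraint crossing from low-MCA initial data, the
# sampled-parabola worked example, and reverse-time seeding of the
# equilibrium.

#' Branching experiment: perturb the uniform equilibrium
#'
#' Perturbs the equilibrium `(1, ..., 1)` by `+delta` and `-delta` at the
#' midpoint level (CA = 1/2, index `M/2`), integrates both, and reports the
#' mirror-symmetry residual `max_t || (y_plus(t) - 1) + (y_minus(t) - 1) ||`:
#' because the flow is linear on the constraint surface (the midpoint
#' perturbation leaves `w . y = 0` exactly), the two branches are mirror
#' images through the equilibrium.
#'
#' @param M number of subintervals (even, so the midpoint is a node);
#'   default 50 (51 levels).
#' @param delta perturbation size, default 0.01.
#' @param index 0-based perturbation index; default the midpoint `M/2`.
#' @param step_size,n_steps,record_every forwarded to [sim_config()].
#' @return list with `plus`, `minus` (trajectories), `mirror_residual`
#'   (per recorded time), `max_mirror_residual`, and `initial_mca` of the
#'   perturbed states.
#' @export
run_branching <- function(M = 50L, delta = 0.01, index = M %/% 2L,
                          step_size = 0.01, n_steps = 500L,
                          record_every = 10L) {
  if (index < 0L || index > M) stop("perturbation index out of range")
  base <- rep(1, M + 1L)
  e <- replace(numeric(M + 1L), index + 1L, 1)
  cfg <- sim_config(step_size, n_steps, record_every = record_every)
  tp <- integrate_dynamics(vector_strategy(base + delta * e), cfg)
  tm <- integrate_dynamics(vector_strategy(base - delta * e), cfg)
  resid <- vapply(seq_along(tp$times), function(i)
    sqrt(sum(((tp$states[i, ] - 1) + (tm$states[i, ] - 1))^2)), 0)
  list(plus = tp, minus = tm, mirror_residual = resid,
       max_mirror_residual = max(resid),
       initial_mca = c(plus = mca(tp$initial), minus = mca(tm$initial)))
}

#' Worked example: the sampled parabola f0(x) = (x - 1/2)^2
#'
#' On the `M = 6` grid the parabola vanishes at the midpoint node and equals
#' exactly 1/36 at `x4 = 2/3`.  The constrained gradient there is exactly
#' `-11/810` (computed symbolically), so one forward-Euler step gives
#' `1/36 - 11 eps / 810`, positive for `eps < 810/396`.  The report also
#' samples `A f0` on a fine grid: it is negative just above `x = 1/2`, which
#' is how sampled strategies can hide an excursion of the underlying density
#' below zero.
#'
#' @param eps Euler step used in the one-step update report (default 2, the
#'   large illustrative value).
#' @param M coarse sampling grid (default 6).
#' @param fine_M fine grid for the sign-pattern scan (default 240).
#' @return list with exact fractions (`f0_at_x4`, `gradient_at_x4`,
#'   `update_at_x4`), `eps_positivity_threshold`, the coarse samples,
#'   the fine-grid `gradient_values`, and `sign_change_interval` (the
#'   interval just above 1/2 where `A f0 < 0`).
#' @export
run_worked_example <- function(eps = 2, M = 6L, fine_M = 240L) {
  xs <- (0:M) / M
  f0 <- function(x) (x - 0.5)^2
  # exact pieces: f0 has rational coefficients (1/4, -1, 1)
  gex <- exact_constrained_gradient(c(1, -1, 1), c(4, 1, 1), 2, 3)
  f0_x4 <- rat((2 * M / 3 - M / 2)^2, M^2)   # ((x4 - 1/2) M)^2 / M^2
  upd <- if (eps == round(eps)) {
    r <- rat_add(f0_x4, rat(eps * gex$num, gex$den))
    list(num = r$num, den = r$den, value = r$num / r$den)
  } else {
    list(num = NA_real_, den = NA_real_,
         value = f0_x4$num / f0_x4$den + eps * gex$value)
  }
  fine <- grid_spec(fine_M)
  fs <- function_strategy(f0(fine$points), fine)
  Af <- constrained_gradient(fs)
  neg <- which(Af < 0 & fine$points > 0.5)
  sci <- if (length(neg)) range(fine$points[neg]) else c(NA_real_, NA_real_)
  list(
    nodes = xs,
    f0_values = f0(xs),
    f0_at_x4 = list(num = f0_x4$num, den = f0_x4$den),
    gradient_at_x4 = gex,
    update_at_x4 = upd,
    eps_positivity_threshold = 810 / (11 * 36),
    gradient_values = Af,
    gradient_grid = fine$points,
    sign_change_interval = sci)
}

#' Low-MCA experiment: abrupt activation of the constraint
#'
#' Integrates a documented synthetic stand-in with MCA well below 1/2 (an
#' exponentially decreasing profile `exp(-4 x)`; the initial data behind the
#' published figures is not printed, so only structural behavior is
#' asserted) at two step sizes, and reports the first step at which the
#' constraint activates.  The physical crossing time `eps * step` is
#' invariant under step-size refinement; the MCA increases monotonically
#' before the crossing and is pinned at 1/2 afterwards.
#'
#' @param M number of subintervals (default 50).
#' @param eps_values the two step sizes to compare (default 0.02 and
#'   0.0002).
#' @param total_time simulated horizon for each run.
#' @param initial optional [vector_strategy()] overriding the stand-in
#'   (must have MCA < 1/2).
#' @return list with per-eps `trajectories`, `crossing_steps`,
#'   `crossing_times`, `crossing_time_spread` (difference of the crossing
#'   times; at most one coarse step), and `initial_mca`.
#' @export
run_low_mca <- function(M = 50L, eps_values = c(0.02, 2e-4),
                        total_time = 3, initial = NULL) {
  if (is.null(initial)) {
    x <- (0:M) / M
    initial <- vector_strategy(exp(-4 * x))
  }
  if (mca(initial) >= 0.5) stop("initial MCA must be below 1/2")
  runs <- lapply(eps_values, function(e) {
    cfg <- sim_config(e, n_steps = ceiling(total_time / e),
                      record_every = max(1L, ceiling(total_time / e / 600)))
    integrate_dynamics(initial, cfg)
  })
  steps <- vapply(runs, function(tr) tr$crossing_step, 0L)
  times <- steps * eps_values
  list(trajectories = runs, eps_values = eps_values,
       crossing_steps = steps, crossing_times = times,
       crossing_time_spread = max(times) - min(times),
       initial_mca = mca(initial))
}

#' Reverse-time seeding of the uniform equilibrium
#'
#' Builds a seed by integrating the reversed free flow from the equilibrium
#' `(1, ..., 1)` for time `T_rev`, then integrates it forward and reports
#' the round-trip residual.
#'
#' @param M number of subintervals.
#' @param T_rev reverse horizon (small keeps the seed positive).
#' @param step_size Euler step.
#' @return list with `seed`, `forward` trajectory, `roundtrip_residual`
#'   (max abs deviation from ones at time `T_rev`), and
#'   `seed_min_component`.
#' @export
run_reverse_time <- function(M = 10L, T_rev = 0.05, step_size = 1e-3) {
  target <- vector_strategy(rep(1, M + 1L))
  cfg <- sim_config(step_size, n_steps = as.integer(round(T_rev / step_size)))
  seed <- reverse_time_seed(target, T_rev, cfg)
  fwd <- integrate_dynamics(seed, cfg)
  final <- fwd$states[nrow(fwd$states), ]
  list(seed = seed, forward = fwd,
       roundtrip_residual = max(abs(final - 1)),
       seed_min_component = min(seed$values))
}
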