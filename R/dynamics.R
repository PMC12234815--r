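# Time integration of the adaptive dynamics, with constraint switching and
# per-step diagnostics.
#
# The default integrator is forward Euler with the Heaviside evaluated at
# the current state: state <- state + eps * A(state).  This is the scheme
# whose behavior the numerical experiments study (the switch between the
# free and projected flows is abrupt and the crossing step is a quantity of
# interest), so it is implemented directly rather than through a generic
# solver; an rk4 option exists for convergence cross-checks and an exact
# method (vector space only) pieces together the closed-form propagators of
# the two branches.

#' Simulation configuration
#'
#' @param step_size Euler step `eps > 0` (time units of the canonical
#'   equation, whose rate prefactor `(1/2) mu nbar` is set to 1).
#' @param n_steps number of steps; total simulated time is
#'   `step_size * n_steps`.
#' @param method `"euler"` (default; the scheme under study), `"rk4"`
#'   (cross-checks), or `"exact"` (vector space only).
#' @param record_every record the state every this many steps.
#' @param switch_refinement if `TRUE`, a step that crosses the constraint
#'   surface from below is split exactly at `w = 0` (the crossing fraction
#'   is linear in the state) before switching branch.  Off by default: the
#'   plain scheme is the object of study.
#' @param stop_on_negative abort at the first negative component instead of
#'   flagging it.
#' @param seed optional integer recorded with the run.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(step_size, n_steps, method = c("euler", "exact", "rk4"),
                       record_every = 1L, switch_refinement = FALSE,
                       stop_on_negative = FALSE, seed = NULL) {
  method <- match.arg(method)
  if (!is.finite(step_size) || step_size <= 0) stop("'step_size' must be > 0")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("'n_steps' must be >= 1")
  structure(list(step_size = step_size, n_steps = n_steps, method = method,
                 record_every = as.integer(record_every),
                 switch_refinement = isTRUE(switch_refinement),
                 stop_on_negative = isTRUE(stop_on_negative), seed = seed),
            class = "sim_config")
}

.wrap_like <- function(template, values) {
  if (inherits(template, "vector_strategy")) vector_strategy(values)
  else function_strategy(values, template$grid)
}

#' Integrate the adaptive dynamics
#'
#' Evolves a strategy under `d/dt f = A f` (function space) or
#' `d/dt y = (I - H(w.y) P) L y` (vector space).  Records the state and the
#' diagnostics (MCA, mass, L2 norm, constraint-active flag, defeat margin
#' against the initial state) every `record_every` steps.  Once the
#' constraint activates it stays active (the projected flow conserves `w`);
#' the discrete drift of `w` is logged, not corrected.  Negative components
#' are stored and flagged, never clipped.
#'
#' @param initial a `ca_strategy` (admissibility is checked and reported,
#'   not enforced: exploratory runs from flagged states are allowed).
#' @param config a [sim_config()].
#' @param constraint optional [constraint_spec()].
#' @return object of class `ca_trajectory`: list with `times`, `states`
#'   (matrix, one row per recorded time), `diagnostics` (data frame: `t`,
#'   `mca`, `mass`, `l2_norm`, `constraint_active`, `defeat_margin`),
#'   `initial`, `config`, `crossing_step` (first step index at which the
#'   constraint is active; 0 if active initially, NA if never).
#' @export
integrate_dynamics <- function(initial, config, constraint = NULL) {
  stopifnot(inherits(initial, "ca_strategy"), inherits(config, "sim_config"))
  if (config$method == "exact") {
    if (!inherits(initial, "vector_strategy"))
      stop("method = \"exact\" is supported for the vector space only")
    return(.integrate_exact(initial, config, constraint))
  }
  eps <- config$step_size
  rhs_fun <- function(v) {
    constrained_gradient(.wrap_like(initial, v), constraint)
  }
  v <- initial$values
  n_rec <- config$n_steps %/% config$record_every + 1L
  states <- matrix(NA_real_, n_rec, length(v))
  times <- numeric(n_rec)
  rec <- 1L
  states[1L, ] <- v
  crossing <- if (constraint_active(initial, constraint)) 0L else NA_integer_
  for (step in seq_len(config$n_steps)) {
    dv <- if (config$method == "rk4") {
      k1 <- rhs_fun(v)
      k2 <- rhs_fun(v + eps / 2 * k1)
      k3 <- rhs_fun(v + eps / 2 * k2)
      k4 <- rhs_fun(v + eps * k3)
      (k1 + 2 * k2 + 2 * k3 + k4) / 6
    } else rhs_fun(v)
    if (config$switch_refinement && is.na(crossing)) {
      s_now <- .wrap_like(initial, v)
      w_now <- constraint_value(s_now)
      v_try <- v + eps * dv
      w_try <- constraint_value(.wrap_like(initial, v_try))
      if (w_now < 0 && w_try > 0) {
        theta <- w_now / (w_now - w_try)      # w is linear in the state
        v_mid <- v + theta * eps * dv
        v <- v_mid + (1 - theta) * eps * rhs_fun(v_mid)
      } else v <- v_try
    } else {
      v <- v + eps * dv
    }
    if (!all(is.finite(v)))
      stop(sprintf("integration failure (non-finite state) at step %d", step))
    if (is.na(crossing) &&
        constraint_active(.wrap_like(initial, v), constraint))
      crossing <- step
    if (config$stop_on_negative && any(v < 0))
      stop(sprintf("negative component at step %d (strict mode)", step))
    if (step %% config$record_every == 0L) {
      rec <- rec + 1L
      states[rec, ] <- v
      times[rec] <- step * eps
    }
  }
  states <- states[seq_len(rec), , drop = FALSE]
  times <- times[seq_len(rec)]
  traj <- .finish_trajectory(initial, config, constraint, times, states,
                             crossing)
  if (!is_admissible(.wrap_like(initial, states[rec, ])))
    warning("trajectory left the strategy space (negative values); ",
            "states stored unclipped")
  traj
}

.finish_trajectory <- function(initial, config, constraint, times, states,
                               crossing) {
  diag <- do.call(rbind, lapply(seq_along(times), function(i) {
    s <- .wrap_like(initial, states[i, ])
    m <- total_mass(s)
    data.frame(
      t = times[i],
      mca = if (is.finite(m) && m > 0) mca(s) else NA_real_,
      mass = m,
      l2_norm = if (inherits(s, "function_strategy"))
        sqrt(quadrature(s$grid, s$values^2)) else sqrt(sum(s$values^2)),
      constraint_active = constraint_active(s, constraint),
      defeat_margin = payoff(s, initial))
  }))
  structure(list(times = times, states = states, diagnostics = diag,
                 initial = initial, config = config,
                 crossing_step = crossing),
            class = "ca_trajectory")
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<ca_trajectory> %d recorded states, t in [0, %.4g], ",
                     "method %s, eps = %.3g\n"),
              length(x$times), max(x$times), x$config$method,
              x$config$step_size))
  cross <- x$crossing_step
  cat(if (is.na(cross)) "  constraint never activates\n"
      else sprintf("  constraint active from step %d\n", cross))
  invisible(x)
}

# exact piecewise propagator for the vector game: L branch until w crosses
# zero, then (I - P) L
.integrate_exact <- function(initial, config, constraint) {
  M <- initial$M
  eps <- config$step_size
  total_t <- eps * config$n_steps
  rec_times <- seq(0, total_t, by = eps * config$record_every)
  w <- (0:M) / M - 0.5
  wv <- constraint_value(initial, constraint)
  tolv <- switch_tol_for(initial, constraint)
  t_cross <- 0
  if (wv < -tolv) {
    decL <- spectral_decomposition(M, "unconstrained")
    g <- function(t) sum(w * exact_solution(initial, t, decL))
    # w(t) oscillates, so locate the FIRST sign change by scanning before
    # polishing with uniroot inside the bracketing interval
    scan <- seq(0, total_t, length.out = max(1000L, config$n_steps %/% 10L))
    gv <- vapply(scan, g, 0)
    up <- which(gv[-1] >= 0 & gv[-length(gv)] < 0)
    if (!length(up)) {
      t_cross <- Inf
    } else {
      t_cross <- stats::uniroot(g, scan[c(up[1], up[1] + 1L)],
                                tol = 1e-13)$root
    }
    y_at <- function(t) exact_solution(initial, t, decL)
  } else {
    y_at <- NULL
  }
  decC <- spectral_decomposition(M, "constrained")
  y_cross <- if (t_cross > 0 && is.finite(t_cross)) y_at(t_cross) else NULL
  states <- t(vapply(rec_times, function(t) {
    if (!is.null(y_at) && t <= t_cross) y_at(t)
    else if (is.null(y_at)) exact_solution(initial, t, decC)
    else exact_solution(y_cross, t - t_cross, decC)
  }, numeric(M + 1L)))
  crossing <- if (wv >= -tolv) 0L
              else if (is.finite(t_cross)) as.integer(ceiling(t_cross / eps))
              else NA_integer_
  .finish_trajectory(initial, config, constraint, rec_times, states, crossing)
}

#' Analytic lower bound on the MCA along the free flow
#'
#' For initial MCA strictly inside (0, 1/2), the MCA of an admissible
#' trajectory grows at rate above `2 (1/2 - MCA)^2`; the comparison solution
#' is `g(t) = 1/2 - 1/(c0 + 2 t)` with `c0 = 1/(1/2 - mca0)`, so
#' `g(0) = mca0` and `g` increases to 1/2.
#'
#' @param t time (vectorized).
#' @param mca0 initial MCA in (0, 1/2).
#' @return numeric vector `g(t)`.
#' @export
mca_lower_bound <- function(t, mca0) {
  if (!is.finite(mca0) || mca0 <= 0 || mca0 >= 0.5)
    stop("'mca0' must lie strictly inside (0, 1/2)")
  c0 <- 1 / (0.5 - mca0)
  0.5 - 1 / (c0 + 2 * t)
}

#' Instantaneous rate of change of the MCA
#'
#' `d/dt MCA = 2 (1/2 - MCA)^2 + (1 - H(w)) * int x (1 - x) f dx / int f`.
#' Vanishes when the MCA is 1/2 (on the constraint surface the projected
#' flow conserves it); for nonnegative strategies below the bound it
#' strictly exceeds `2 (1/2 - MCA)^2`.
#'
#' @param strategy a `ca_strategy` with positive mass.
#' @param constraint optional [constraint_spec()].
#' @return numeric scalar.
#' @export
mca_rate <- function(strategy, constraint = NULL) {
  m <- .check_mass(total_mass(strategy))
  active <- constraint_active(strategy, constraint)
  base <- 2 * (0.5 - mca(strategy))^2
  if (active) return(base)
  x <- (0:strategy$M) / strategy$M
  extra <- if (inherits(strategy, "function_strategy"))
    quadrature(strategy$grid, x * (1 - x) * strategy$values)
  else sum(x * (1 - x) * strategy$values)
  base + extra / m
}

#' Defeat margin of a trajectory against its initial state
#'
#' `E[alpha(t), f0]` at the recorded times: zero at `t = 0`, positive for
#' small `t` when `f0` is admissible and non-constant (evolution defeats the
#' ancestor), with initial slope `||grad E(f0)||^2` on the free branch.
#'
#' @param trajectory a `ca_trajectory`.
#' @param f0 the initial strategy (must equal the trajectory's).
#' @return numeric vector, one margin per recorded time.
#' @export
defeat_margin <- function(trajectory, f0) {
  if (!isTRUE(all.equal(f0$values, trajectory$initial$values)))
    stop("'f0' does not match the trajectory's initial state")
  vapply(seq_along(trajectory$times), function(i)
    payoff(.wrap_like(f0, trajectory$states[i, ]), f0), 0)
}

#' Seed strategies that evolve into an equilibrium
#'
#' Integrates the reversed free flow `d/dt y = -L y` (vector) or
#' `d/dt f = -grad E(f)` (function) from an equilibrium for time `T`.  The
#' returned seed, integrated forward for time `T` with the same step size,
#' lands back on the target up to integration error.  Seeds with negative
#' components (large `T`) are flagged with a warning.
#'
#' @param target the equilibrium strategy (e.g. all ones).
#' @param T_rev reverse-time horizon; small values keep the seed strictly
#'   positive.
#' @param config a [sim_config()] supplying the step size (Euler is used).
#' @return a `ca_strategy` seed.
#' @export
reverse_time_seed <- function(target, T_rev, config) {
  if (T_rev < 0) stop("'T_rev' must be >= 0")
  eps <- config$step_size
  n <- max(1L, as.integer(round(T_rev / eps)))
  if (T_rev == 0) return(target)
  v <- target$values
  for (i in seq_len(n)) {
    g <- selection_gradient(.wrap_like(target, v))
    v <- v - eps * g
  }
  out <- .wrap_like(target, v)
  if (any(v < 0))
    warning("reverse-time seed has negative components; reduce T_rev")
  out
}
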