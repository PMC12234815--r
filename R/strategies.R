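# Strategy representations for the competitive-ability game.
#
# A strategy is the distribution of competitive ability (CA) across the
# individuals of a species: a nonnegative vector indexed by CA levels k/M
# (discrete game) or a nonnegative density sampled on a uniform grid over
# [0,1] (continuous game).  The mean competitive ability (MCA) is the
# mass-weighted mean CA and is bounded by 1/2 for admissible strategies.

#' Uniform grid on the unit interval
#'
#' Builds the closed uniform grid `x_j = j/M`, `j = 0..M`, together with the
#' trapezoidal quadrature weights used for every function-valued integral in
#' the package.  The trapezoid rule is exact for linear integrands, so the
#' quadrature of the constant 1 is exactly 1 and the constraint direction
#' `x - 1/2` integrates to exactly 0.
#'
#' @param M positive integer, number of subintervals (`M + 1` nodes).
#' @return An object of class `grid_spec` with fields `M`, `points`, `h`
#'   (spacing `1/M`) and `weights` (trapezoid weights summing to 1).
#' @examples
#' g <- grid_spec(10)
#' sum(g$weights)            # exactly 1
#' @export
grid_spec <- function(M) {
  M <- as.integer(M)
  if (length(M) != 1L || is.na(M) || M < 1L)
    stop("'M' must be a positive integer")
  h <- 1 / M
  w <- rep(h, M + 1L)
  w[c(1L, M + 1L)] <- h / 2
  structure(list(M = M, points = (0:M) / M, h = h, weights = w),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> M = %d (%d nodes on [0,1], h = %.6g)\n",
              x$M, x$M + 1L, x$h))
  invisible(x)
}

# trapezoid quadrature of sampled values over [0,1]
quadrature <- function(grid, values) sum(grid$weights * values)

# cumulative trapezoid integral, value at each node (0 at x = 0)
cum_quadrature <- function(grid, values) {
  as.numeric(pracma::cumtrapz(grid$points, values))
}

#' Discrete (vector) strategy
#'
#' Component `j` (0-based level `j/M`) is the abundance of individuals with
#' competitive ability `j/M`.  Components may become negative during
#' evolution; such states are stored as-is and flagged inadmissible rather
#' than clipped.
#'
#' @param values numeric vector of length `M + 1` (abundances).
#' @return Object of class `c("vector_strategy", "ca_strategy")`.
#' @seealso [function_strategy()], [mca()], [is_admissible()]
#' @export
vector_strategy <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a vector strategy needs at least 2 levels")
  structure(list(values = values, M = length(values) - 1L),
            class = c("vector_strategy", "ca_strategy"))
}

#' Function-valued strategy
#'
#' Samples of a trait density `f(x)` (individuals per unit competitive
#' ability) on a uniform grid; integrals are evaluated with the grid's
#' trapezoid rule.
#'
#' @param values numeric samples `f(x_j)`.
#' @param grid a [grid_spec()]; defaults to the uniform grid matching
#'   `length(values)`.
#' @return Object of class `c("function_strategy", "ca_strategy")`.
#' @export
function_strategy <- function(values, grid = grid_spec(length(values) - 1L)) {
  values <- as.numeric(values)
  if (!inherits(grid, "grid_spec")) stop("'grid' must be a grid_spec")
  if (length(values) != grid$M + 1L)
    stop("length(values) must equal grid$M + 1")
  structure(list(values = values, grid = grid, M = grid$M),
            class = c("function_strategy", "ca_strategy"))
}

#' @export
print.ca_strategy <- function(x, ...) {
  kind <- if (inherits(x, "vector_strategy")) "vector" else "function"
  m <- total_mass(x)
  cat(sprintf("<%s strategy> %d levels, mass %.6g", kind, x$M + 1L, m))
  if (m > 0) cat(sprintf(", MCA %.6g", mca(x)))
  cat(if (is_admissible(x)) ", admissible\n" else ", NOT admissible\n")
  invisible(x)
}

#' Constraint specification for the MCA bound
#'
#' The bound MCA `<= 1/2` is linear: it reads `w(f) <= 0` with
#' `w(f) = integral (x - 1/2) f(x) dx` in the function game, and `w . y <= 0`
#' with `w_j = j/M - 1/2` in the vector game.  `w` is orthogonal to
#' constants, so `w(f) = (MCA(f) - 1/2) * mass(f)` whenever the mass is
#' positive.
#'
#' @param M number of subintervals (vector game), or supply `grid`.
#' @param grid optional [grid_spec()] for the function game.
#' @param bound the MCA bound, 1/2.
#' @param switch_tolerance relative tolerance used by the Heaviside switch:
#'   the constraint counts as active when `w >= -switch_tolerance * mass`.
#' @return Object of class `constraint_spec` with fields `bound`, `w`
#'   (direction samples `x_j - 1/2`), `switch_tolerance`, `M`.
#' @export
constraint_spec <- function(M = NULL, grid = NULL, bound = 0.5,
                            switch_tolerance = 1e-12) {
  if (is.null(M) && is.null(grid)) stop("give 'M' or 'grid'")
  if (is.null(M)) M <- grid$M
  M <- as.integer(M)
  structure(list(bound = bound, w = (0:M) / M - 0.5, M = M,
                 switch_tolerance = switch_tolerance),
            class = "constraint_spec")
}

#' Total mass of a strategy
#'
#' Sum of components (vector game) or trapezoid integral of the density
#' (function game).
#' @param strategy a `ca_strategy`.
#' @return numeric scalar.
#' @export
total_mass <- function(strategy) UseMethod("total_mass")

#' @export
total_mass.vector_strategy <- function(strategy) sum(strategy$values)

#' @export
total_mass.function_strategy <- function(strategy)
  quadrature(strategy$grid, strategy$values)

#' Is a strategy admissible?
#'
#' Admissible means all values nonnegative and total mass strictly positive.
#' States reached by the dynamics can violate this; they are flagged, never
#' clipped.
#' @inheritParams total_mass
#' @return logical.
#' @export
is_admissible <- function(strategy) {
  all(strategy$values >= 0) && total_mass(strategy) > 0
}

#' Mean competitive ability
#'
#' The mass-weighted mean CA: `sum (k/M) y_k / sum y_k` or
#' `integral x f(x) dx / integral f(x) dx`.  Lies in `[0, 1]` for admissible
#' strategies and is invariant under positive rescaling.
#'
#' @inheritParams total_mass
#' @return numeric scalar in `[0, 1]` (for nonnegative strategies).
#' @examples
#' mca(vector_strategy(c(1, 1, 1)))   # 0.5
#' mca(vector_strategy(c(1, 0, 0)))   # 0
#' @export
mca <- function(strategy) UseMethod("mca")

.check_mass <- function(m) {
  if (!is.finite(m) || m <= 0)
    stop("MCA undefined: total mass must be strictly positive")
  m
}

#' @export
mca.vector_strategy <- function(strategy) {
  m <- .check_mass(total_mass(strategy))
  sum(((0:strategy$M) / strategy$M) * strategy$values) / m
}

#' @export
mca.function_strategy <- function(strategy) {
  m <- .check_mass(total_mass(strategy))
  quadrature(strategy$grid, strategy$grid$points * strategy$values) / m
}

#' Value of the MCA constraint functional
#'
#' Returns `w . y` (vector game) or the trapezoid value of
#' `integral (x - 1/2) f(x) dx` (function game).  Negative iff the MCA is
#' below 1/2 (for positive mass); zero on the constraint surface.
#'
#' @inheritParams total_mass
#' @param constraint optional [constraint_spec()]; checked for matching
#'   dimension when supplied.
#' @return numeric scalar.
#' @export
constraint_value <- function(strategy, constraint = NULL) {
  if (!is.null(constraint)) {
    if (!inherits(constraint, "constraint_spec"))
      stop("'constraint' must be a constraint_spec")
    if (constraint$M != strategy$M)
      stop("constraint dimension does not match the strategy")
  }
  UseMethod("constraint_value")
}

#' @export
constraint_value.vector_strategy <- function(strategy, constraint = NULL) {
  sum(((0:strategy$M) / strategy$M - 0.5) * strategy$values)
}

#' @export
constraint_value.function_strategy <- function(strategy, constraint = NULL) {
  g <- strategy$grid
  quadrature(g, (g$points - 0.5) * strategy$values)
}

# Heaviside switch H(w) with the boundary counted as active: H(u) = 1 iff
# u >= -tol.  The dynamics treats w = 0 as on the constraint surface.
h_active <- function(wval, tol = 0) wval >= -tol

# tolerance actually used by the switch for a given state
switch_tol_for <- function(strategy, constraint = NULL) {
  rel <- if (is.null(constraint)) 1e-12 else constraint$switch_tolerance
  rel * max(abs(total_mass(strategy)), 1)
}

#' Is the MCA constraint active for this strategy?
#'
#' True when `w(strategy) >= -tol` with `tol = switch_tolerance * mass`
#' (Heaviside-at-boundary convention `H(0) = 1`).
#' @inheritParams constraint_value
#' @return logical.
#' @export
constraint_active <- function(strategy, constraint = NULL) {
  h_active(constraint_value(strategy, constraint),
           switch_tol_for(strategy, constraint))
}

#' Random admissible strategy with a prescribed MCA
#'
#' Fixture generator.  Draws strictly positive uniform samples, then either
#' symmetrizes them about x = 1/2 (`target_mca = 1/2`, which gives MCA
#' exactly 1/2 by reflection symmetry) or applies a deterministic exponential
#' tilt `f(x) exp(theta x)` with `theta` found by root-finding so that the
#' MCA matches `target_mca` to within 1e-12.  Identical seeds give identical
#' output; the global RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param M number of subintervals (`M + 1` components).
#' @param target_mca target mean competitive ability, strictly inside (0,1).
#' @param kind `"vector"` or `"function"`.
#' @return a `ca_strategy` of the requested kind with
#'   `|mca - target_mca| <= 1e-12`.
#' @examples
#' s <- random_strategy(1, 20, target_mca = 0.3)
#' abs(mca(s) - 0.3) < 1e-12
#' @export
random_strategy <- function(seed, M, target_mca = 0.5,
                            kind = c("vector", "function")) {
  kind <- match.arg(kind)
  if (!is.finite(target_mca) || target_mca <= 0 || target_mca >= 1)
    stop("'target_mca' must lie strictly inside (0, 1): ",
         "a positive-mass strategy cannot have MCA 0 or 1")
  M <- as.integer(M)
  base <- withr::with_seed(as.integer(seed),
                           stats::runif(M + 1L, min = 0.2, max = 1))
  x <- (0:M) / M
  wrap <- function(v) if (kind == "vector") vector_strategy(v)
                      else function_strategy(v)
  mca_of <- function(v) mca(wrap(v))
  if (identical(target_mca, 0.5)) {
    return(wrap((base + rev(base)) / 2))
  }
  f <- function(theta) mca_of(base * exp(theta * x)) - target_mca
  root <- stats::uniroot(f, c(-50, 50), extendInt = "yes",
                         tol = .Machine$double.eps)
  out <- wrap(base * exp(root$root * x))
  if (abs(mca(out) - target_mca) > 1e-12)
    stop("root-finding on the exponential tilt did not reach the target MCA")
  out
}
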