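# Payoffs and equilibria.
#
# Random pairwise contests between individuals of two species give the
# species-level net expected wins
#   E[y, z] = sum_k y_k ( sum_{j<k} z_j - sum_{l>k} z_l )      (vector game)
#   E[f, g] = int f(x) ( int_0^x g - int_x^1 g ) dx            (function game)
# Both games are zero-sum and symmetric: E[a,b] = -E[b,a], E[a,a] = 0.
# Equal-CA ties contribute nothing (strict index ranges); no tie-break
# parameter exists or is needed.

# skew application used by the function-game payoff: S g at every node, where
# S is the trapezoid discretization of the sign kernel with zero diagonal.
# This makes diag(q) S exactly skew, so E[f,f] = 0 to machine precision.
.skew_gradient <- function(grid, values) {
  cum <- cum_quadrature(grid, values)
  tot <- cum[length(cum)]
  out <- 2 * cum - tot
  n <- length(values)
  out[1] <- out[1] + grid$h * values[1] / 2
  out[n] <- out[n] - grid$h * values[n] / 2
  out
}

#' Game payoff between two strategies
#'
#' Net expected wins of `a` against `b` under random pairwise contests.
#' Bilinear in both arguments and antisymmetric: `payoff(a, b) =
#' -payoff(b, a)` (exactly, including under the function-game quadrature,
#' which uses the antisymmetrized trapezoid bilinear form).
#'
#' @param a,b strategies of the same kind and dimension.
#' @param details if `TRUE`, also return the per-level contributions
#'   `y_k * (cumulative wins - losses)` as attribute `"components"`.
#' @return numeric scalar (with optional `"components"` attribute).
#' @examples
#' payoff(vector_strategy(c(1, 0)), vector_strategy(c(0, 1)))  # -1
#' @export
payoff <- function(a, b, details = FALSE) UseMethod("payoff")

#' @export
payoff.vector_strategy <- function(a, b, details = FALSE) {
  if (!inherits(b, "vector_strategy")) stop("'b' must be a vector strategy")
  if (a$M != b$M) stop("strategies have different lengths")
  z <- b$values
  below <- cumsum(z) - z                 # sum_{j < k} z_j
  above <- rev(cumsum(rev(z))) - z       # sum_{l > k} z_l
  comp <- a$values * (below - above)
  out <- sum(comp)
  if (details) attr(out, "components") <- comp
  out
}

#' @export
payoff.function_strategy <- function(a, b, details = FALSE) {
  if (!inherits(b, "function_strategy")) stop("'b' must be a function strategy")
  if (a$M != b$M) stop("strategies live on different grids")
  g <- a$grid
  comp <- g$weights * a$values * .skew_gradient(g, b$values)
  out <- sum(comp)
  if (details) attr(out, "components") <- comp
  out
}

#' Aggregate a panel of opponents
#'
#' A species competes against the component-wise sum of all the others;
#' the payoff against the aggregate equals the sum of the pairwise payoffs
#' (bilinearity).
#'
#' @param strategies nonempty list of strategies of one kind and dimension.
#' @return a strategy of the same kind.
#' @export
aggregate_opponents <- function(strategies) {
  if (!length(strategies)) stop("empty list of strategies")
  kinds <- vapply(strategies, function(s) class(s)[1], "")
  if (length(unique(kinds)) != 1L) stop("mixed strategy kinds")
  Ms <- vapply(strategies, function(s) s$M, 0L)
  if (length(unique(Ms)) != 1L) stop("dimension mismatch")
  vals <- Reduce(`+`, lapply(strategies, function(s) s$values))
  if (kinds[1] == "vector_strategy") vector_strategy(vals)
  else function_strategy(vals, strategies[[1]]$grid)
}

#' Nash-equilibrium / stationarity check
#'
#' In the function game the equilibria are exactly the positive constant
#' functions; in the vector game they are the positive multiples of
#' `(1, ..., 1)` when `M` is odd, and the alternating patterns
#' `(a, b, a, b, ..., a)` with `a, b >= 0`, not both zero, when `M` is even.
#' These are also exactly the stationary states of the adaptive dynamics, so
#' the check is cross-validated against the norm of the constrained
#' right-hand side.
#'
#' @param strategy a `ca_strategy`.
#' @param tol absolute tolerance on the shape; default `1e-9 *
#'   max(abs(values))`.
#' @return logical, with attribute `"diagnostics"` (list: `reason`,
#'   `shape_residual`, `rhs_norm`).
#' @examples
#' check_equilibrium(vector_strategy(rep(1, 4)))            # TRUE (M = 3 odd)
#' check_equilibrium(vector_strategy(c(3, 1, 3, 1, 3)))     # TRUE (M = 4 even)
#' check_equilibrium(vector_strategy(c(1, 2, 3)))           # FALSE
#' @export
check_equilibrium <- function(strategy, tol = NULL) {
  v <- strategy$values
  scale <- max(abs(v), .Machine$double.eps)
  if (is.null(tol)) tol <- 1e-9 * scale
  if (inherits(strategy, "function_strategy")) {
    resid <- max(v) - min(v)
    ok <- resid <= tol && mean(v) > 0
    reason <- if (ok) "positive constant function"
              else "values are not constant (or not positive)"
  } else {
    M <- strategy$M
    if (M %% 2L == 1L) {                  # M odd: multiples of ones
      resid <- max(abs(v - mean(v)))
      ok <- resid <= tol && mean(v) > 0
      reason <- if (ok) "positive multiple of (1,...,1)"
                else "not proportional to the all-ones vector"
    } else {                              # M even: (a, b, a, b, ..., a)
      a <- mean(v[seq(1, M + 1, by = 2)])
      b <- if (M >= 2) mean(v[seq(2, M + 1, by = 2)]) else 0
      fit <- rep(c(a, b), length.out = M + 1)
      resid <- max(abs(v - fit))
      ok <- resid <= tol && a >= -tol && b >= -tol && (a + b) > tol
      reason <- if (ok) "alternating pattern (a,b,a,...,a), a,b >= 0"
                else "not of the alternating equilibrium form"
    }
  }
  rhs <- constrained_gradient(strategy)
  rhs_norm <- if (inherits(strategy, "function_strategy"))
    sqrt(quadrature(strategy$grid, rhs^2)) else sqrt(sum(rhs^2))
  out <- ok
  attr(out, "diagnostics") <-
    list(reason = reason, shape_residual = resid, rhs_norm = rhs_norm)
  out
}
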