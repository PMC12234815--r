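# Selection gradients, the MCA-constraint projection, and the constrained
# operator A in both trait spaces.
#
# The invasion-fitness gradient at f is
#   grad E(f)(x) = int_0^x f - int_x^1 f = 2 int_0^x f - int_0^1 f,
# a nondecreasing function when f >= 0, with d/dx grad E(f) = 2 f.
# The constraint surface w(f) = 0 has normal direction x - 1/2; removing the
# normal component gives the constrained selection gradient
#   A f = (1 - H(w(f)) P) grad E(f),
# with the Heaviside switch active on and above the boundary (H(0) = 1).

#' System matrices of the vector game
#'
#' `L` is the `(M+1) x (M+1)` skew Toeplitz matrix with -1 above and +1
#' below the diagonal (it maps a strategy to its unconstrained selection
#' gradient); `w` has components `j/M - 1/2`; `P = w w^T / ||w||^2` projects
#' onto the constraint normal.
#'
#' @param M positive integer (number of subintervals; matrices are
#'   `(M+1) x (M+1)`).
#' @return Object of class `ca_system`: list with `L`, `w`, `P`,
#'   `I_minus_P`, `M`.
#' @examples
#' build_system_matrices(1)$L       # rbind(c(0, -1), c(1, 0))
#' @export
build_system_matrices <- function(M) {
  M <- as.integer(M)
  if (length(M) != 1L || is.na(M) || M < 1L) stop("'M' must be >= 1")
  n <- M + 1L
  L <- matrix(0, n, n)
  L[lower.tri(L)] <- 1
  L[upper.tri(L)] <- -1
  w <- (0:M) / M - 0.5
  P <- outer(w, w) / sum(w^2)
  structure(list(L = L, w = w, P = P, I_minus_P = diag(n) - P, M = M),
            class = "ca_system")
}

#' @export
print.ca_system <- function(x, ...) {
  cat(sprintf("<ca_system> M = %d: L (skew, %dx%d), w, P = ww^T/|w|^2\n",
              x$M, x$M + 1L, x$M + 1L))
  invisible(x)
}

#' Unconstrained selection gradient
#'
#' For a function strategy returns the node values of
#' `2 int_0^x f - int_0^1 f` (cumulative trapezoid rule, exact for constant
#' `f`); for a vector strategy returns `L y`.
#'
#' @param strategy a `ca_strategy`.
#' @return numeric vector of node values.
#' @export
selection_gradient <- function(strategy) UseMethod("selection_gradient")

#' @export
selection_gradient.function_strategy <- function(strategy) {
  cum <- cum_quadrature(strategy$grid, strategy$values)
  2 * cum - cum[length(cum)]
}

#' @export
selection_gradient.vector_strategy <- function(strategy) {
  z <- strategy$values
  below <- cumsum(z) - z
  above <- rev(cumsum(rev(z))) - z
  below - above                       # = L y without forming L
}

#' Projection onto the constraint normal
#'
#' `P(g)(x) = c * (x - 1/2)` with `c = <g, x - 1/2> / ||x - 1/2||^2`; the
#' output integrates to exactly 0 and `P` is exactly idempotent because the
#' normalization `1 / ||x - 1/2||^2` (the number 12 in the continuum) is
#' evaluated under the same quadrature.
#'
#' @param values numeric node values of `g`.
#' @param grid a [grid_spec()] matching `values`.
#' @return numeric node values of `P(g)`, a multiple of `x - 1/2`.
#' @export
project_normal <- function(values, grid) {
  xm <- grid$points - 0.5
  coef <- quadrature(grid, xm * values) / quadrature(grid, xm^2)
  coef * xm
}

# vector-game analog: P g with P = w w^T / |w|^2
.project_normal_vec <- function(values, w) w * (sum(w * values) / sum(w^2))

#' Constrained selection gradient A
#'
#' `A f = grad E(f) - H(w(f)) P(grad E(f))`: when the MCA is strictly below
#' 1/2 the flow is the free gradient; on and above the boundary the normal
#' component is removed, so `w` is conserved.  The switch is abrupt.
#'
#' @param strategy a `ca_strategy`.
#' @param constraint optional [constraint_spec()] (controls the switch
#'   tolerance).
#' @return numeric vector: the right-hand side of the adaptive dynamics at
#'   `strategy`.
#' @export
constrained_gradient <- function(strategy, constraint = NULL) {
  g <- selection_gradient(strategy)
  active <- h_active(constraint_value(strategy, constraint),
                     switch_tol_for(strategy, constraint))
  if (!active) return(g)
  if (inherits(strategy, "function_strategy"))
    g - project_normal(g, strategy$grid)
  else
    g - .project_normal_vec(g, (0:strategy$M) / strategy$M - 0.5)
}

#' Right-hand side of the vector dynamics
#'
#' `(I - H(w . y) P) L y` with the Heaviside evaluated at the current state.
#'
#' @param y a [vector_strategy()] (or plain numeric vector).
#' @param mats a `ca_system` from [build_system_matrices()].
#' @param constraint optional [constraint_spec()].
#' @return numeric vector.
#' @export
vector_rhs <- function(y, mats, constraint = NULL) {
  v <- if (inherits(y, "vector_strategy")) y$values else as.numeric(y)
  if (length(v) != mats$M + 1L) stop("dimension mismatch with 'mats'")
  ys <- vector_strategy(v)
  g <- selection_gradient(ys)
  if (h_active(constraint_value(ys, constraint),
               switch_tol_for(ys, constraint)))
    g - .project_normal_vec(g, mats$w)
  else g
}

#' Discrete kernel matrix of the constrained operator
#'
#' The matrix `K` with `A f = K f` exactly under the package quadrature.
#' Its first part discretizes the sign kernel `s(x, y)` (+1 below, -1 above
#' the diagonal, 0 on it); its second, separable part is the discrete
#' summation-by-parts image of `12 (x - 1/2)(y^2 - y)`, to which it
#' converges as the grid is refined.
#'
#' @param grid a [grid_spec()].
#' @param active logical: include the constraint term (Heaviside value)?
#' @return `(M+1) x (M+1)` numeric matrix.
#' @export
gradient_kernel_matrix <- function(grid, active = TRUE) {
  n <- grid$M + 1L
  q <- grid$weights
  s <- sign(outer(seq_len(n), seq_len(n), `-`))
  W <- s * rep(q, each = n)            # row i: s(x_i, y_j) q_j
  W[1, 1] <- -grid$h / 2               # one-sided rule at the two corners:
  W[n, n] <- grid$h / 2                # the diagonal there is a domain end
  if (!active) return(W)
  xm <- grid$points - 0.5
  coef <- 1 / quadrature(grid, xm^2)
  W - coef * outer(xm, as.numeric(crossprod(W, q * xm)))
}

#' Transformed variance-covariance kernel
#'
#' Dieckmann-style constraint transform of a base mutational
#' variance-covariance kernel `U`: the discretization of
#' `sigma^2(x,y) = int int Ptilde(x,r) U(r,s) Ptilde(s,y) dr ds` with
#' `Ptilde = delta - Ntilde Ntilde H(w(f)) H(int g_f Ntilde)` and
#' `Ntilde(x) = (x - 1/2) / ||x - 1/2||`.  For `U` the discrete delta the
#' result is exactly `delta - c (x-1/2)(y-1/2) H(w(f))` on the grid, the
#' kernel of the constrained adaptive-dynamics operator (`c` is the
#' discrete 12).  The second Heaviside factor equals 1 for every nonnegative
#' `f` since `int (x-1/2) grad E(f) dx = int x(1-x) f dx >= 0`.
#'
#' @param U square matrix kernel on the grid (`(M+1) x (M+1)`), or `NULL`
#'   for the discrete delta.
#' @param strategy the current [function_strategy()] (sets both Heavisides).
#' @param constraint optional [constraint_spec()].
#' @return `(M+1) x (M+1)` matrix kernel.  The discrete delta is
#'   `diag(1/q)` with `q` the trapezoid weights, so that quadrature
#'   application reproduces the identity exactly.
#' @export
transform_covariance <- function(U = NULL, strategy, constraint = NULL) {
  grid <- strategy$grid
  n <- grid$M + 1L
  q <- grid$weights
  delta <- diag(1 / q, n)
  if (is.null(U)) U <- delta
  if (!is.matrix(U) || nrow(U) != n || ncol(U) != n)
    stop("'U' must be a square matrix on the strategy's grid")
  N <- grid$points - 0.5
  Nt <- N / sqrt(quadrature(grid, N^2))
  h1 <- h_active(constraint_value(strategy, constraint),
                 switch_tol_for(strategy, constraint))
  gf <- selection_gradient(strategy)
  h2 <- h_active(quadrature(grid, gf * Nt), switch_tol_for(strategy, constraint))
  Pt <- delta - (h1 && h2) * outer(Nt, Nt)
  PtQ <- Pt * rep(q, each = n)         # quadrature composition P~ o U o P~
  PtQ %*% U %*% t(PtQ)
}

#' Apply a matrix kernel to node values by quadrature
#'
#' `(K f)(x_i) = sum_j K[i, j] q_j f(x_j)` — the discrete counterpart of
#' `int K(x, y) f(y) dy` for kernels represented on the grid (for example
#' the output of [transform_covariance()]).
#'
#' @param K matrix kernel on the grid.
#' @param values node values.
#' @param grid a [grid_spec()].
#' @return numeric node values.
#' @export
apply_kernel <- function(K, values, grid) {
  as.numeric(K %*% (grid$weights * values))
}
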