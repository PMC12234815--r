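# Exact spectral structure of the vector dynamics.
#
# L is skew, so its spectrum is purely imaginary; the same holds for
# (I - P) L (a projection times a skew matrix).  The zero eigenvalue obeys
# parity laws in the dimension n = M + 1:
#   ker L:        empty (n even) / span{(1,-1,1,...,1)} (n odd)
#   ker (I-P)L:   span{ones} (n even) / span{v_odd, v_even} (n odd)
# with the Jordan partner (2,0,2,0,...,2,0) of the all-ones vector closing a
# chain of length 2 in the even case.  Nonzero eigenvalues come in simple
# conjugate pairs +/- i beta, giving rotation blocks in the real Jordan
# form, and the solution of dy/dt = (I - P) L y is y(t) = Q B(t) Q^{-1} y0.

#' Characteristic polynomial of L
#'
#' `det(L - lambda I)` in dimension `n`: `sum_k C(n, 2k) lambda^{2k}` when
#' `n` is even and `-lambda sum_k C(n, 2k+1) lambda^{2k}` when `n` is odd.
#' Coefficients are exact integers (binomials).
#'
#' @param n_plus_1 matrix dimension (`n = M + 1` in the game).
#' @return integer coefficient vector, ascending powers
#'   (`lambda^0 ... lambda^n`).
#' @examples
#' char_poly_L(2)  # c(1, 0, 1):       lambda^2 + 1
#' char_poly_L(3)  # c(0, -3, 0, -1): -lambda^3 - 3 lambda
#' @export
char_poly_L <- function(n_plus_1) {
  n <- as.integer(n_plus_1)
  if (n < 1L) stop("dimension must be >= 1")
  coef <- numeric(n + 1L)
  if (n %% 2L == 0L) {
    for (k in 0:(n %/% 2L)) coef[2L * k + 1L] <- choose(n, 2L * k)
  } else {
    for (k in 0:((n - 1L) %/% 2L))
      coef[2L * k + 2L] <- -choose(n, 2L * k + 1L)
  }
  coef
}

#' Closed-form kernel bases of L and (I - P) L
#'
#' The analytic null-space bases, by dimension parity.  For the constrained
#' matrix with `M + 1` even the list also carries the Jordan partner
#' `v2 = (2, 0, 2, 0, ..., 2, 0)` (attribute `"jordan_partner"`), which
#' satisfies `(I - P) L v2 = (1, ..., 1)` exactly.
#'
#' @param M number of subintervals.
#' @param constrained basis for `(I - P) L` (`TRUE`) or for `L` (`FALSE`).
#' @return list of numeric vectors (possibly empty), with attribute
#'   `"jordan_partner"` in the constrained even-dimension case.
#' @export
kernel_basis <- function(M, constrained = TRUE) {
  n <- M + 1L
  if (constrained) {
    if (n %% 2L == 1L) {                      # n odd: two kernel vectors
      vo <- rep(c(0, 1), length.out = n)      # ones in odd components
      ve <- rep(c(1, 0), length.out = n)      # ones in even components
      out <- list(v_even = ve, v_odd = vo)
    } else {
      out <- list(ones = rep(1, n))
      attr(out, "jordan_partner") <- rep(c(2, 0), length.out = n)
    }
  } else {
    out <- if (n %% 2L == 1L) list(alt = rep(c(1, -1), length.out = n))
           else list()
  }
  out
}

# real 2x2 rotation generator convention: for an eigenpair A v = i b v with
# v = u + i w, A u = -b w and A w = b u, so on columns (u, w) the generator
# is C = [[0, b], [-b, 0]] and exp(tC) = [[cos bt, sin bt], [-sin bt, cos bt]].
.rot_block <- function(beta, t) {
  c1 <- cos(beta * t); s1 <- sin(beta * t)
  rbind(c(c1, s1), c(-s1, c1))
}

#' Real spectral decomposition of the vector-game flow matrix
#'
#' Builds `L` (branch `"unconstrained"`) or `(I - P) L` (branch
#' `"constrained"`) for the given `M` and assembles the real basis `Q` whose
#' columns are the zero-eigenvalue Jordan chain (taken from the analytic
#' bases of [kernel_basis()], completed by a least-squares generalized
#' eigenvector in the odd constrained case) followed by the real and
#' imaginary parts of the eigenvectors of the simple pairs `+/- i beta`.
#' The propagator is `Q B(t) Q^{-1}` with polynomial upper-triangular blocks
#' for the zero chain and rotation blocks for the pairs.
#'
#' @param M number of subintervals.
#' @param branch `"constrained"` for `(I - P) L`, `"unconstrained"` for `L`.
#' @param zero_basis optional list of exact zero-chain vectors overriding
#'   [kernel_basis()].
#' @param cond_limit error if the basis condition number exceeds this.
#' @return object of class `ca_spectral`: list with `matrix`, `Q`, `Qinv`,
#'   `blocks` (descriptors), `betas`, `m_zero` (algebraic multiplicity of 0,
#'   found empirically), `branch`, `M`.
#' @export
spectral_decomposition <- function(M, branch = c("constrained",
                                                 "unconstrained"),
                                  zero_basis = NULL, cond_limit = 1e8) {
  branch <- match.arg(branch)
  mats <- build_system_matrices(M)
  A <- if (branch == "constrained") mats$I_minus_P %*% mats$L else mats$L
  n <- M + 1L
  ev <- eigen(A)
  lam <- ev$values
  scale <- max(abs(lam), 1)
  # a defective zero eigenvalue splits numerically at ~sqrt(machine eps),
  # so the purely-imaginary check must sit above that scale
  if (max(abs(Re(lam))) > 1e-6 * scale)
    stop("eigenvalues are not purely imaginary; unexpected matrix family")
  zero_idx <- which(abs(lam) <= 1e-6 * scale)
  m_zero <- length(zero_idx)

  # --- zero-eigenvalue Jordan chain columns, with block sizes ------------
  kb <- if (is.null(zero_basis)) kernel_basis(M, branch == "constrained")
        else zero_basis
  zero_cols <- NULL
  zero_sizes <- integer(0)
  if (branch == "constrained") {
    if (n %% 2L == 0L) {                     # chain ones <- v2
      zero_cols <- cbind(kb$ones, attr(kb, "jordan_partner"))
      zero_sizes <- 2L
    } else {                                 # kernel 2-dim, one chain of 2
      B <- cbind(kb$v_even, kb$v_odd)
      sv <- svd(A)
      r <- sum(sv$d > 1e-9 * max(sv$d))
      U2 <- sv$u[, (r + 1L):n, drop = FALSE] # complement of the range
      M2 <- crossprod(U2, B)                 # 2x2: which combo is in range?
      sv2 <- svd(M2)
      cin <- sv2$v[, 2]                      # combo inside the range
      cout <- sv2$v[, 1]                     # combo not in the range
      b <- as.numeric(B %*% cin)
      pinv <- sv$v[, 1:r, drop = FALSE] %*%
        ((1 / sv$d[1:r]) * crossprod(sv$u[, 1:r, drop = FALSE], b))
      if (max(abs(A %*% pinv - b)) > 1e-8 * max(abs(b)))
        stop("failed to close the zero-eigenvalue Jordan chain")
      zero_cols <- cbind(as.numeric(B %*% cout), b, pinv)
      zero_sizes <- c(1L, 2L)
    }
  } else {
    if (n %% 2L == 1L) { zero_cols <- cbind(kb$alt); zero_sizes <- 1L }
  }
  n_zero_cols <- if (is.null(zero_cols)) 0L else ncol(zero_cols)
  if (n_zero_cols != m_zero)
    stop(sprintf(paste0("empirical zero multiplicity (%d) does not match ",
                        "the analytic chain (%d columns)"),
                 m_zero, n_zero_cols))

  # --- rotation pairs ----------------------------------------------------
  pos <- which(Im(lam) > 1e-6 * scale)
  pos <- pos[order(Im(lam[pos]))]
  betas <- Im(lam[pos])
  if (length(betas) > 1 && min(diff(sort(betas))) < 1e-9 * scale)
    stop("repeated rotation frequencies; matrix outside the expected family")
  pair_cols <- lapply(pos, function(i) {
    v <- ev$vectors[, i]
    j <- which.max(abs(v))
    v <- v / v[j]                    # fix phase for reproducibility
    cbind(Re(v), Im(v))
  })
  Q <- do.call(cbind, c(if (n_zero_cols) list(zero_cols), pair_cols))
  if (ncol(Q) != n) stop("basis assembly failed")
  kap <- kappa(Q, exact = TRUE)
  if (kap > cond_limit)
    stop(sprintf("basis condition number %.3g exceeds limit; supply an exact zero basis", kap))
  blocks <- c(lapply(zero_sizes, function(k) list(type = "jordan", size = k)),
              lapply(betas, function(b) list(type = "rotation", beta = b)))
  structure(list(matrix = A, Q = Q, Qinv = solve(Q), blocks = blocks,
                 betas = betas, m_zero = m_zero, branch = branch, M = M,
                 condition = kap),
            class = "ca_spectral")
}

#' @export
print.ca_spectral <- function(x, ...) {
  cat(sprintf(paste0("<ca_spectral> %s branch, M = %d: zero eigenvalue ",
                     "multiplicity %d, %d rotation pairs (beta in [%.4g, %.4g])\n"),
              x$branch, x$M, x$m_zero,
              length(x$betas),
              if (length(x$betas)) min(x$betas) else NA,
              if (length(x$betas)) max(x$betas) else NA))
  invisible(x)
}

#' Block propagator B(t)
#'
#' Assembles the real block-diagonal propagator: for a zero-chain block of
#' size `k`, the upper-triangular matrix with entries `t^j / j!`; for a pair
#' `+/- i beta`, the rotation block.
#'
#' @param decomposition a `ca_spectral`.
#' @param t time.
#' @return `(M+1) x (M+1)` matrix `B(t)`; `B(0)` is the identity.
#' @export
block_propagator <- function(decomposition, t) {
  sizes <- vapply(decomposition$blocks, function(b)
    if (b$type == "jordan") b$size else 2L, 0L)
  n <- sum(sizes)
  B <- matrix(0, n, n)
  at <- 1L
  for (b in decomposition$blocks) {
    if (b$type == "jordan") {
      k <- b$size
      blk <- diag(k)
      if (k > 1) for (j in 1:(k - 1))
        for (i in 1:(k - j)) blk[i, i + j] <- t^j / factorial(j)
      B[at:(at + k - 1L), at:(at + k - 1L)] <- blk
      at <- at + k
    } else {
      B[at:(at + 1L), at:(at + 1L)] <- .rot_block(b$beta, t)
      at <- at + 2L
    }
  }
  B
}

#' Exact (closed-form) solution of the linear vector dynamics
#'
#' `y(t) = Q B(t) Q^{-1} y0` for the branch the decomposition was built for.
#' The unconstrained (`L`) branch is valid only while `w . y(t) < 0`; the
#' caller (see [integrate_dynamics()] with `method = "exact"`) handles the
#' crossing and switches branch.
#'
#' @param y0 initial state ([vector_strategy()] or numeric).
#' @param t time (scalar or vector).
#' @param decomposition a `ca_spectral` for the matching branch.
#' @return numeric vector (or matrix with one row per time).
#' @export
exact_solution <- function(y0, t, decomposition) {
  v <- if (inherits(y0, "vector_strategy")) y0$values else as.numeric(y0)
  if (length(v) != decomposition$M + 1L)
    stop("dimension mismatch between 'y0' and the decomposition")
  w <- (0:decomposition$M) / decomposition$M - 0.5
  wv <- sum(w * v)
  tolv <- 1e-9 * max(sum(abs(v)), 1)
  if (decomposition$branch == "constrained" && wv < -tolv)
    stop("branch mismatch: w . y0 < 0 needs the unconstrained (L) branch")
  if (decomposition$branch == "unconstrained" && wv > tolv)
    stop("branch mismatch: w . y0 > 0 needs the constrained (I-P)L branch")
  co <- as.numeric(decomposition$Qinv %*% v)
  one <- function(ti)
    as.numeric(decomposition$Q %*% (block_propagator(decomposition, ti) %*% co))
  if (length(t) == 1L) one(t) else t(vapply(t, one, numeric(length(v))))
}
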