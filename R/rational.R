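# Exact arithmetic helpers.
#
# The structural results of the vector game (ranks, kernel dimensions,
# characteristic polynomials) and the worked example of the function game
# are exact rational statements, so they are computed without floating
# point.  Rationals are (numerator, denominator) pairs of doubles holding
# exact integers (all values here stay far below 2^53); ranks of the
# integer-scaled matrices are obtained by Gaussian elimination over several
# word-size prime fields (rank mod p never exceeds the rational rank, and
# equals it for all but finitely many primes), cross-checked against an SVD
# rank.  Direct fraction-free elimination is avoided: its intermediate
# values overflow doubles already around dimension 20.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

# reduced rational number: list(num, den), den > 0
rat <- function(num, den = 1) {
  if (den == 0) stop("zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- .gcd(num, den)
  if (g > 1) { num <- num / g; den <- den / g }
  list(num = num, den = den)
}
rat_add <- function(a, b) rat(a$num * b$den + b$num * a$den, a$den * b$den)
rat_sub <- function(a, b) rat(a$num * b$den - b$num * a$den, a$den * b$den)
rat_mul <- function(a, b) rat(a$num * b$num, a$den * b$den)
rat_scale <- function(a, k) rat(a$num * k, a$den)

# polynomials with rational coefficients, ascending powers; parallel
# num/den vectors
rp <- function(num, den = rep(1, length(num))) {
  k <- length(num)
  out <- list(num = numeric(k), den = numeric(k))
  for (i in seq_len(k)) {
    r <- rat(num[i], den[i])
    out$num[i] <- r$num; out$den[i] <- r$den
  }
  out
}
rp_get <- function(p, i) list(num = p$num[i], den = p$den[i])
rp_mul <- function(p, q) {
  k <- length(p$num) + length(q$num) - 1L
  acc <- replicate(k, rat(0), simplify = FALSE)
  for (i in seq_along(p$num)) for (j in seq_along(q$num)) {
    t <- rat_mul(rp_get(p, i), rp_get(q, j))
    acc[[i + j - 1L]] <- rat_add(acc[[i + j - 1L]], t)
  }
  rp(vapply(acc, `[[`, 0, "num"), vapply(acc, `[[`, 0, "den"))
}
rp_add <- function(p, q) {
  k <- max(length(p$num), length(q$num))
  acc <- replicate(k, rat(0), simplify = FALSE)
  for (i in seq_along(p$num)) acc[[i]] <- rat_add(acc[[i]], rp_get(p, i))
  for (i in seq_along(q$num)) acc[[i]] <- rat_add(acc[[i]], rp_get(q, i))
  rp(vapply(acc, `[[`, 0, "num"), vapply(acc, `[[`, 0, "den"))
}
rp_scale <- function(p, r) {
  acc <- lapply(seq_along(p$num), function(i) rat_mul(rp_get(p, i), r))
  rp(vapply(acc, `[[`, 0, "num"), vapply(acc, `[[`, 0, "den"))
}
# antiderivative with zero constant term
rp_int <- function(p) {
  k <- length(p$num)
  acc <- c(list(rat(0)),
           lapply(seq_len(k), function(i) rat(p$num[i], p$den[i] * i)))
  rp(vapply(acc, `[[`, 0, "num"), vapply(acc, `[[`, 0, "den"))
}
# evaluate at rational x = xn/xd by Horner
rp_eval <- function(p, xn, xd = 1) {
  x <- rat(xn, xd)
  acc <- rat(0)
  for (i in rev(seq_along(p$num)))
    acc <- rat_add(rat_mul(acc, x), rp_get(p, i))
  acc
}

#' Exact constrained selection gradient of a polynomial strategy
#'
#' For a polynomial trait density `f` (rational coefficients, ascending
#' powers) computes `A f = grad E(f) - 12 (x - 1/2) int_0^1 (y - 1/2)
#' grad E(f)(y) dy` symbolically, and evaluates it at a rational point.
#' All arithmetic is exact.
#'
#' @param coef_num,coef_den integer numerators/denominators of the
#'   polynomial coefficients of `f`, ascending powers.
#' @param x_num,x_den rational evaluation point `x = x_num / x_den`.
#' @return list with `num`, `den` (reduced fraction) and `value`
#'   (floating quotient).
#' @examples
#' # f0(x) = (x - 1/2)^2 at x = 2/3: exactly -11/810
#' exact_constrained_gradient(c(1, -1, 1), c(4, 1, 1), 2, 3)
#' @export
exact_constrained_gradient <- function(coef_num, coef_den, x_num, x_den) {
  f <- rp(coef_num, coef_den)
  FF <- rp_int(f)                            # int_0^x f
  tot <- rp_eval(FF, 1)                      # int_0^1 f
  gradE <- rp_add(rp_scale(FF, rat(2)), rp(c(-tot$num), c(tot$den)))
  # q0 = int_0^1 (y - 1/2) gradE(y) dy
  ym <- rp(c(-1, 1), c(2, 1))
  q0 <- rp_eval(rp_int(rp_mul(ym, gradE)), 1)
  corr <- rp_scale(ym, rat_mul(rat(12), q0))  # 12 (x-1/2) q0
  res <- rp_eval(rp_add(gradE, rp_scale(corr, rat(-1))), x_num, x_den)
  list(num = res$num, den = res$den, value = res$num / res$den)
}

# ---- modular linear algebra -------------------------------------------------

# primes below sqrt(2^53) so products stay exact in doubles
.rank_primes <- c(67108859, 67108837, 67108819)

.mod_inv <- function(a, p) {                 # extended Euclid
  t0 <- 0; t1 <- 1; r0 <- p; r1 <- a %% p
  while (r1 != 0) {
    q <- r0 %/% r1
    tmp <- t0 - q * t1; t0 <- t1; t1 <- tmp
    tmp <- r0 - q * r1; r0 <- r1; r1 <- tmp
  }
  if (r0 != 1) stop("not invertible mod p")
  t0 %% p
}

.rank_mod_p <- function(A, p) {
  A <- A %% p
  n <- nrow(A); m <- ncol(A)
  rank <- 0L; row <- 1L
  for (col in seq_len(m)) {
    piv <- which(A[row:n, col] != 0)
    if (!length(piv)) next
    piv <- piv[1] + row - 1L
    if (piv != row) A[c(row, piv), ] <- A[c(piv, row), ]
    inv <- .mod_inv(A[row, col], p)
    A[row, ] <- (A[row, ] * inv) %% p
    below <- seq_len(n)[-seq_len(row)]
    for (r in below) {
      if (A[r, col] != 0)
        A[r, ] <- (A[r, ] - A[r, col] * A[row, ]) %% p
    }
    rank <- rank + 1L; row <- row + 1L
    if (row > n) break
  }
  rank
}

# integer-scaled matrices: S4 * (I - P) L and L itself.  With
# w_j = (2j - M) / (2M) and S4 = sum (2j - M)^2, the matrix S4 (I-P) L has
# integer entries S4 L_ij - (2i - M) sum_k (2k - M) L_kj.
.int_L <- function(M) {
  n <- M + 1L
  L <- matrix(0, n, n); L[lower.tri(L)] <- 1; L[upper.tri(L)] <- -1
  L
}
.int_ipl <- function(M) {
  L <- .int_L(M)
  a <- 2 * (0:M) - M
  S4 <- sum(a^2)
  S4 * L - outer(a, as.numeric(a %*% L))
}

#' Exact rank of the game's system matrices
#'
#' Rank of `L` (unconstrained) or of `(I - P) L` (constrained) computed
#' exactly: the matrix is scaled to integers, its rank is taken over several
#' prime fields (the maximum is a certificate: rank mod p never exceeds the
#' rational rank) and cross-checked against a tolerance-based SVD rank.
#'
#' The parity laws are: `rank L = M + 1` for `M + 1` even, `M` for `M + 1`
#' odd; `dim ker (I-P)L = 1` for `M + 1` even, `2` for `M + 1` odd.
#'
#' @param M number of subintervals.
#' @param constrained rank of `(I - P) L` (`TRUE`) or of `L` (`FALSE`).
#' @return integer rank.
#' @export
exact_rank <- function(M, constrained = TRUE) {
  A <- if (constrained) .int_ipl(M) else .int_L(M)
  r_mod <- max(vapply(.rank_primes, function(p) .rank_mod_p(A, p), 0L))
  s <- svd(A)$d
  r_svd <- sum(s > max(dim(A)) * .Machine$double.eps * max(s))
  if (r_mod != r_svd)
    stop("modular and SVD ranks disagree; matrix outside the expected family")
  as.integer(r_mod)
}

#' Dimension of the kernel of (I - P) L (or of L)
#'
#' @inheritParams exact_rank
#' @return integer nullity (`M + 1 - rank`).
#' @examples
#' kernel_dimension(50)  # 2 (dimension 51, odd)
#' kernel_dimension(49)  # 1 (dimension 50, even)
#' @export
kernel_dimension <- function(M, constrained = TRUE) {
  as.integer(M + 1L - exact_rank(M, constrained))
}

#' Apply (I - P) L to an integer vector exactly
#'
#' Returns the exact rational vector `(I - P) L v` as reduced fractions:
#' with `a_j = 2j - M` and `S4 = sum a_j^2`, component `i` equals
#' `(L v)_i - a_i (sum_k a_k (L v)_k) / S4`.
#'
#' @param M number of subintervals.
#' @param v integer vector of length `M + 1`.
#' @return list with vectors `num` and `den` (reduced, `den > 0`).
#' @examples
#' # Jordan-partner identity: (I-P)L (2,0,2,0,...) = (1,1,...,1) for M+1 even
#' ipl_apply_exact(3, c(2, 0, 2, 0))
#' @export
ipl_apply_exact <- function(M, v) {
  if (length(v) != M + 1L) stop("length(v) must be M + 1")
  if (any(v != round(v))) stop("'v' must be an integer vector")
  Lv <- as.numeric(.int_L(M) %*% v)
  a <- 2 * (0:M) - M
  S4 <- sum(a^2)
  d <- sum(a * Lv)
  num <- den <- numeric(M + 1L)
  for (i in seq_len(M + 1L)) {
    r <- rat(S4 * Lv[i] - a[i] * d, S4)
    num[i] <- r$num; den[i] <- r$den
  }
  list(num = num, den = den)
}
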