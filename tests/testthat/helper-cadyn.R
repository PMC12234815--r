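# Shared fixtures and independent oracles.

# brute-force payoff oracle: explicit double sum over all level pairs
brute_payoff <- function(y, z) {
  s <- 0
  for (k in seq_along(y)) for (j in seq_along(z))
    s <- s + y[k] * z[j] * sign(k - j)
  s
}

# independent characteristic-polynomial oracle: integer determinant of
# L - lambda I at integer nodes, then exact interpolation (coefficients are
# integers, so rounding the Vandermonde solve recovers them exactly for the
# small dimensions used)
char_poly_oracle <- function(n) {
  L <- matrix(0, n, n); L[lower.tri(L)] <- 1; L[upper.tri(L)] <- -1
  nodes <- -(n %/% 2):(n - n %/% 2)      # n + 1 integer nodes
  dets <- vapply(nodes, function(l) round(det(L - l * diag(n))), 0)
  V <- outer(nodes, 0:n, `^`)
  round(solve(V, dets))
}

# small panel of random admissible strategies
random_panel <- function(n, M, kind, seeds = seq_len(n), mcas = NULL) {
  if (is.null(mcas)) mcas <- seq(0.25, 0.5, length.out = n)
  lapply(seq_len(n), function(i)
    random_strategy(seeds[i], M, mcas[i], kind))
}

quad_of <- function(f, v = f$values) sum(f$grid$weights * v)
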