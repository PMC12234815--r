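# Selection gradients, projections, the constrained operator, and the
# covariance transform.

test_that("system matrices satisfy the structural identities", {
  expect_equal(build_system_matrices(1)$L, rbind(c(0, -1), c(1, 0)))
  expect_equal(build_system_matrices(2)$w, c(-1 / 2, 0, 1 / 2))
  for (M in c(1, 4, 9)) {
    m <- build_system_matrices(M)
    expect_equal(m$L + t(m$L), matrix(0, M + 1, M + 1))   # skew
    expect_equal(m$P %*% m$P, m$P, tolerance = 1e-14)     # idempotent
    expect_equal(as.numeric(m$P %*% m$w), m$w)            # P w = w
    expect_equal(as.numeric(m$I_minus_P %*% m$w), rep(0, M + 1),
                 tolerance = 1e-15)
    expect_equal(m$P, t(m$P))
  }
  expect_error(build_system_matrices(0), ">= 1")
})

test_that("selection gradient is exact for constants and converges for
           the parabola", {
  g <- grid_spec(240)
  # f = 1: gradient is exactly 2x - 1 at every node under the cumulative
  # trapezoid rule
  expect_identical(selection_gradient(function_strategy(rep(1, 241), g)),
                   2 * g$points - 1)
  # f = (x - 1/2)^2: symbolic gradient (2/3)(x - 1/2)^3
  fp <- function_strategy((g$points - 0.5)^2, g)
  expect_lt(max(abs(selection_gradient(fp) - (2 / 3) * (g$points - 0.5)^3)),
            1e-5)
  # nondecreasing whenever f >= 0
  for (s in random_panel(4, 80, "function")) {
    expect_true(all(diff(selection_gradient(s)) >= -1e-14))
  }
})

test_that("d/dx of the selection gradient recovers 2 f at interior nodes", {
  # smooth densities: the central difference needs bounded curvature
  g <- grid_spec(300)
  profiles <- list(1 + 0.5 * sin(2 * pi * g$points) + g$points^2,
                   exp(-2 * g$points) * (2 + cos(3 * g$points)))
  for (v in profiles) {
    f <- function_strategy(v, g)
    gr <- selection_gradient(f)
    fd <- (gr[-(1:2)] - gr[1:(length(gr) - 2)]) / (2 * g$h)
    expect_equal(fd, 2 * f$values[-c(1, length(gr))], tolerance = 1e-3)
  }
})

test_that("normal projection maps onto the span of x - 1/2", {
  g <- grid_spec(100)
  xm <- g$points - 0.5
  # fixed point on its own span
  expect_equal(project_normal(xm, g), xm, tolerance = 1e-15)
  # constants are annihilated
  expect_equal(project_normal(rep(4, 101), g), rep(0, 101), tolerance = 1e-15)
  for (seed in 1:5) {
    v <- withr::with_seed(seed, stats::rnorm(101))
    pv <- project_normal(v, g)
    expect_lt(abs(sum(g$weights * pv)), 1e-14)        # integrates to 0
    expect_equal(project_normal(pv, g), pv, tolerance = 1e-12)  # idempotent
  }
})

test_that("constrained gradient switches branches correctly", {
  # constants are stationary (the only eigenfunctions, eigenvalue 0)
  expect_lt(max(abs(constrained_gradient(function_strategy(rep(2, 51))))),
            1e-12)
  expect_lt(max(abs(constrained_gradient(vector_strategy(rep(1, 6))))), 1e-14)
  # below the bound the flow is the free gradient, node for node
  low <- random_strategy(3, 80, 0.3, "function")
  expect_identical(constrained_gradient(low), selection_gradient(low))
  lowv <- random_strategy(3, 20, 0.3)
  mats <- build_system_matrices(20)
  expect_identical(vector_rhs(lowv, mats), selection_gradient(lowv))
  # worked example: A f0 at x = 2/3 is -11/810 up to quadrature error
  g <- grid_spec(240)
  fp <- function_strategy((g$points - 0.5)^2, g)
  expect_equal(constrained_gradient(fp)[which(g$points == 2 / 3)],
               -11 / 810, tolerance = 2e-4)
})

test_that("vector rhs vanishes at equilibria and solves the Jordan-partner
           identity", {
  mats <- build_system_matrices(9)
  expect_equal(vector_rhs(vector_strategy(rep(1, 10)), mats), rep(0, 10),
               tolerance = 1e-14)
  # (I - P) L (2,0,...,2,0) = ones in dimension 50 (a matrix identity:
  # w . v2 < 0, so the dynamics itself would take the free branch here)
  m50 <- build_system_matrices(49)
  v2 <- rep(c(2, 0), 25)
  expect_equal(as.numeric(m50$I_minus_P %*% (m50$L %*% v2)), rep(1, 50),
               tolerance = 1e-12)
})

test_that("kernel matrix application equals the direct constrained
           gradient", {
  for (M in c(30, 101)) {
    g <- grid_spec(M)
    for (seed in c(1, 4)) {
      for (tmca in c(0.3, 0.5)) {
        f <- random_strategy(seed, M, tmca, "function")
        K <- gradient_kernel_matrix(g, active = constraint_active(f))
        expect_equal(as.numeric(K %*% f$values), constrained_gradient(f),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("discrete kernel converges to s(x,y) + 12(x-1/2)(y^2-y)", {
  err <- vapply(c(40, 80, 160), function(M) {
    g <- grid_spec(M)
    K <- gradient_kernel_matrix(g, active = TRUE)
    # continuum kernel sampled and given quadrature weights
    s <- sign(outer(seq_len(M + 1), seq_len(M + 1), `-`))
    kc <- s + 12 * outer(g$points - 0.5, g$points^2 - g$points)
    Kc <- kc * rep(g$weights, each = M + 1)
    max(abs(K - Kc)[2:M, 2:M])       # interior; corners carry the
  }, 0)                              # one-sided boundary rule
  expect_lt(err[3], 2e-4)
  expect_gt(err[1] / err[3], 3)      # shrinks with the grid
})

test_that("covariance transform recovers the adaptive-dynamics kernel", {
  g <- grid_spec(60)
  xm <- g$points - 0.5
  delta <- diag(1 / g$weights)
  c12 <- 1 / sum(g$weights * xm^2)
  on_surface <- random_strategy(8, 60, 0.5, "function")
  below <- random_strategy(8, 60, 0.3, "function")
  # active constraint: delta - 12 (x-1/2)(y-1/2)
  expect_equal(transform_covariance(NULL, on_surface),
               delta - c12 * outer(xm, xm), tolerance = 1e-10)
  # inactive: the delta alone
  expect_equal(transform_covariance(NULL, below), delta, tolerance = 1e-12)
  # sandwiching preserves symmetry
  U <- withr::with_seed(2, matrix(stats::rnorm(61^2), 61))
  U <- U + t(U)
  S2 <- transform_covariance(U, on_surface)
  expect_equal(S2, t(S2), tolerance = 1e-10)
  expect_error(transform_covariance(U[1:10, 1:10], on_surface), "square")
  # applying the delta kernel by quadrature is the identity
  expect_equal(apply_kernel(delta, below$values, g), below$values)
})

test_that("second Heaviside factor is always active for admissible
           strategies", {
  # integral of (x - 1/2) grad E(f) equals integral of x(1-x) f >= 0
  for (s in random_panel(6, 120, "function")) {
    g <- s$grid
    val <- sum(g$weights * (g$points - 0.5) * selection_gradient(s))
    expect_gte(val, -1e-14)
    expect_lt(abs(val -
                  sum(g$weights * g$points * (1 - g$points) * s$values)),
              1e-4 * total_mass(s))
  }
})

test_that("gradient mass identity holds on random strategies", {
  # integral of grad E(f) = 2 (1/2 - MCA) mass
  for (s in random_panel(8, 150, "function")) {
    g <- s$grid
    expect_lt(abs(sum(g$weights * selection_gradient(s)) -
                  2 * (0.5 - mca(s)) * total_mass(s)),
              1e-4 * total_mass(s))
  }
})

test_that("only constants solve the eigenproblem A f = lambda f", {
  g <- grid_spec(120)
  cst <- function_strategy(rep(1.4, 121), g)
  expect_lt(max(abs(constrained_gradient(cst) - 0 * cst$values)), 1e-12)
  # non-constant f: residual stays away from zero over a line search on
  # lambda (best least-squares lambda = <Af, f>/<f, f>)
  for (seed in c(6, 9)) {
    f <- random_strategy(seed, 120, 0.5, "function")
    af <- constrained_gradient(f)
    lam <- sum(g$weights * af * f$values) / sum(g$weights * f$values^2)
    resid <- sqrt(sum(g$weights * (af - lam * f$values)^2)) /
      sqrt(sum(g$weights * f$values^2))
    expect_gt(resid, 1e-3)
  }
})
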