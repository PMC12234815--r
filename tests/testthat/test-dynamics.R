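# Time integration: conservation laws, monotonicity, defeat margins,
# crossing behavior, reverse-time seeding.

test_that("constant initial data stays constant", {
  f0 <- function_strategy(rep(1.2, 101))
  tr <- integrate_dynamics(f0, sim_config(1e-2, 200, record_every = 50))
  expect_lt(max(abs(tr$states - 1.2)), 1e-12)
  expect_lt(max(abs(constrained_gradient(f0))), 1e-12)
})

test_that("MCA is conserved exactly on the constraint surface", {
  f0 <- random_strategy(11, 200, 0.5, "function")
  tr <- integrate_dynamics(f0, sim_config(1e-3, 1000, record_every = 100))
  expect_lt(max(abs(tr$diagnostics$mca - 0.5)), 1e-12)
  expect_true(all(tr$diagnostics$constraint_active))
})

test_that("mass and L2 norm are conserved with O(eps) drift in the vector
           game", {
  y0 <- random_strategy(31, 30, 0.5)
  drifts <- sapply(c(2e-3, 1e-3, 5e-4), function(e) {
    tr <- integrate_dynamics(y0, sim_config(e, round(1 / e),
                                            record_every = round(1 / e)))
    d <- tr$diagnostics
    c(mass = abs(d$mass[2] - d$mass[1]) / d$mass[1],
      l2 = abs(d$l2_norm[2] - d$l2_norm[1]) / d$l2_norm[1])
  })
  expect_lt(max(drifts["mass", ]), 1e-12)   # exact: no quadrature involved
  expect_lt(abs(drifts["l2", 1] / drifts["l2", 2] - 2), 0.3)
  expect_lt(abs(drifts["l2", 2] / drifts["l2", 3] - 2), 0.3)
})

test_that("function-game conservation carries a fixed quadrature bias", {
  # at fixed grid the relative drift is bounded by O(h^2) + O(eps)
  f0 <- random_strategy(11, 100, 0.5, "function")
  tr <- integrate_dynamics(f0, sim_config(1e-3, 1000, record_every = 1000))
  d <- tr$diagnostics
  expect_lt(abs(d$mass[2] - d$mass[1]) / d$mass[1], 1e-5)
  expect_lt(abs(d$l2_norm[2] - d$l2_norm[1]) / d$l2_norm[1], 1e-5)
})

test_that("below the bound the MCA rises monotonically above the analytic
           bound", {
  f0 <- random_strategy(19, 60, 0.25, "function")
  tr <- suppressWarnings(
    integrate_dynamics(f0, sim_config(1e-3, 3000, record_every = 30)))
  m <- tr$diagnostics$mca
  pre <- m[m < 0.5 - 1e-9]
  expect_true(all(diff(pre) > 0))
  expect_true(all(m >= mca_lower_bound(tr$times, mca(f0)) - 1e-3))
  # once active, the constraint stays active
  act <- tr$diagnostics$constraint_active
  expect_true(all(diff(act) >= 0))
  # and w barely moves after activation
  post <- which(act)
  w_post <- vapply(post, function(i)
    constraint_value(function_strategy(tr$states[i, ], f0$grid)), 0)
  expect_lt(max(abs(w_post)), 5e-3)
})

test_that("mca_rate matches the analytic formula and the simulation", {
  expect_equal(mca_rate(random_strategy(1, 80, 0.5, "function")), 0)
  # below the bound the rate strictly exceeds 2 (1/2 - MCA)^2
  s <- random_strategy(23, 100, 0.3, "function")
  expect_gt(mca_rate(s), 2 * (0.5 - mca(s))^2)
  # finite difference of the simulated MCA reproduces the rate
  tr <- integrate_dynamics(s, sim_config(1e-5, 2, record_every = 1))
  fd <- (tr$diagnostics$mca[2] - tr$diagnostics$mca[1]) / 1e-5
  expect_equal(fd, mca_rate(s), tolerance = 1e-3)
  expect_error(mca_lower_bound(1, 0.7), "strictly inside")
})

test_that("evolution defeats the initial data with slope |grad E|^2", {
  g0 <- random_strategy(13, 100, 0.35, "function")
  e <- 1e-4
  tr <- integrate_dynamics(g0, sim_config(e, 50, record_every = 1))
  margins <- defeat_margin(tr, g0)
  expect_equal(margins[1], 0)
  expect_true(all(margins[-1] > 0))
  gr <- selection_gradient(g0)
  expect_equal(margins[2] / e, sum(g0$grid$weights * gr^2),
               tolerance = 1e-2)
  # boundary case: slope is the constrained inner product <A f0, grad E f0>
  s0 <- random_strategy(17, 100, 0.5, "function")
  tr2 <- integrate_dynamics(s0, sim_config(e, 1, record_every = 1))
  pred <- sum(s0$grid$weights * constrained_gradient(s0) *
                selection_gradient(s0))
  expect_equal(defeat_margin(tr2, s0)[2] / e, pred, tolerance = 2e-2)
  expect_gt(pred, 0)
  expect_error(defeat_margin(tr, s0), "does not match")
})

test_that("never constant: distance to the best constant is preserved", {
  f0 <- random_strategy(29, 100, 0.5, "function")
  tr <- integrate_dynamics(f0, sim_config(1e-3, 2000, record_every = 100))
  g <- f0$grid
  dist <- vapply(seq_along(tr$times), function(i) {
    v <- tr$states[i, ]
    cbest <- sum(g$weights * v)          # L2-best constant
    sqrt(sum(g$weights * (v - cbest)^2))
  }, 0)
  expect_gt(min(dist), 0.5 * dist[1])
})

test_that("exact method pieces the two branches together", {
  y <- random_strategy(2, 10, 0.35)
  e <- 5e-3; n2 <- 100
  ex <- integrate_dynamics(y, sim_config(e, n2, method = "exact",
                                         record_every = n2))
  eu <- integrate_dynamics(y, sim_config(e, n2, record_every = n2))
  expect_equal(ex$crossing_step, eu$crossing_step, tolerance = 1)
  expect_lt(max(abs(ex$states[2, ] - eu$states[2, ])), 50 * e)
  expect_error(
    integrate_dynamics(random_strategy(1, 10, 0.4, "function"),
                       sim_config(1e-2, 10, method = "exact")),
    "vector space only")
})

test_that("rk4 agrees with an independent solver on the smooth branch", {
  skip_if_not_installed("deSolve")
  y <- random_strategy(5, 8, 0.5)
  cfg <- sim_config(1e-2, 100, method = "rk4", record_every = 100)
  tr <- integrate_dynamics(y, cfg)
  mats <- build_system_matrices(8)
  sol <- deSolve::ode(y$values, c(0, 1),
                      function(t, s, p) list(vector_rhs(s, mats)),
                      parms = NULL, method = "ode45")
  expect_equal(tr$states[2, ], as.numeric(sol[2, -1]), tolerance = 1e-6)
})

test_that("switch refinement lands the crossing on the surface", {
  y <- random_strategy(2, 10, 0.35)
  tr <- integrate_dynamics(y, sim_config(5e-3, 100, record_every = 1,
                                         switch_refinement = TRUE))
  i <- tr$crossing_step + 1L           # first recorded active state
  w_at <- constraint_value(vector_strategy(tr$states[i, ]))
  expect_lt(abs(w_at), 1e-9)
})

test_that("reverse-time seeds return to the equilibrium", {
  target <- vector_strategy(rep(1, 11))
  cfg <- sim_config(1e-3, 50)
  expect_identical(reverse_time_seed(target, 0, cfg)$values, target$values)
  seed <- reverse_time_seed(target, 0.05, cfg)
  expect_true(all(seed$values > 0))
  fwd <- integrate_dynamics(seed, sim_config(1e-3, 50, record_every = 50))
  expect_lt(max(abs(fwd$states[2, ] - 1)), 5e-3)
  expect_warning(reverse_time_seed(target, 1, sim_config(1e-3, 1000)),
                 "negative components")
})

test_that("stationarity coincides with game equilibrium on a mixed panel", {
  panel <- c(random_panel(8, 12, "vector", seeds = 1:8),
             list(vector_strategy(rep(2, 13)),
                  vector_strategy(rep(c(1, 4), length.out = 13))))
  for (s in panel) {
    d <- attr(check_equilibrium(s), "diagnostics")
    rhs_small <- d$rhs_norm < 1e-10
    expect_identical(rhs_small, as.logical(check_equilibrium(s)))
  }
})

test_that("trajectories round-trip through the CSV writers", {
  tr <- integrate_dynamics(random_strategy(3, 10, 0.5),
                           sim_config(1e-2, 20, record_every = 5))
  sp <- withr::local_tempfile(fileext = ".csv")
  dp <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, sp, dp)
  back <- read_trajectory_csv(sp)
  expect_equal(back$times, tr$times)
  expect_equal(back$states, tr$states, ignore_attr = TRUE)
  d <- utils::read.csv(dp)
  expect_equal(d$mca, tr$diagnostics$mca)
})
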