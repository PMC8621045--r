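# Process generators: exact O-U propagation vs an independent moment-ODE
# oracle, the conservative FP solver, the Langevin ensemble, the coupled
# dichotomous system, and the probability current.

test_that("ou_propagate reproduces the initial state, stationary limit and ramp lag", {
  spec <- default_spec()
  init <- default_init()
  path <- ou_propagate(spec, init, c(0, 0.5, 20))
  expect_identical(path$y[1], 5)
  expect_identical(path$beta[1], 0.3)
  expect_equal(path$beta[3], stationary_beta(spec), tolerance = 1e-8)
  # ramp v = u t drags the mean with lag u/gamma
  spr <- process_spec(1, 0.5, ramp_u = 1)
  pr <- ou_propagate(spr, gaussian_state(0, 1), c(0, 20))
  expect_equal(pr$y[2] - 20, -1, tolerance = 1e-8)
  expect_error(ou_propagate(spec, list(mean = 0, beta = -1), c(0, 1)))
})

test_that("quadrature propagation of time-dependent coefficients matches the moment ODE", {
  spec <- process_spec(gamma = function(t) 1 + 0.5 * sin(t),
                       D = function(t) 0.3 + 0.2 * exp(-t),
                       v = function(t) sin(2 * t))
  init <- gaussian_state(2, 0.4)
  times <- c(0, 0.3, 0.7, 1.5, 3)
  path <- ou_propagate(spec, init, times)
  oracle <- ode_moment_oracle(spec, init, times)
  expect_rel_equal(path$y[-1], oracle$y[-1], 1e-7)
  expect_rel_equal(path$sigma2, oracle$sigma2, 1e-7)
})

test_that("the FP solver is exact for frozen dynamics and matches analytic O-U moments", {
  g <- grid1d(-8, 8, 512)
  p0 <- gaussian_to_grid(gaussian_state(0, 1), g)
  # f = 0, D = 0: nothing moves
  frozen <- fp_solve(NULL, p0, c(0, 0.5, 1), dt = 0.01,
                     drift = function(x, t) rep(0, length(x)), D = 0)
  expect_equal(max(abs(frozen$trajectory$P[, 3] - p0$p)), 0, tolerance = 1e-13)
  # O-U relaxation: moments within 1e-4 relative of the closed forms
  spec <- default_spec()
  g2 <- grid1d(-10, 15, 4096)
  fp <- fp_solve(spec, gaussian_to_grid(default_init(), g2),
                 c(0, 0.5, 1, 2), dt = 1e-3)
  ref <- ou_propagate(spec, default_init(), c(0, 0.5, 1, 2))
  for (k in 2:4) {
    m <- moments(traj_snapshot(fp$trajectory, k))
    expect_rel_equal(m$mean, ref$y[k], 1e-4)
    expect_rel_equal(m$variance, ref$sigma2[k], 1e-4)
  }
  expect_lt(max(abs(fp$mass - 1)), 1e-8)
})

test_that("the stationary density is a fixed point with vanishing current", {
  spec <- default_spec()
  g <- grid1d(-10, 10, 2048)
  ps <- gaussian_to_grid(gaussian_state(0, stationary_beta(spec)), g)
  fp <- fp_solve(spec, ps, c(0, 0.5, 1), dt = 1e-3)
  expect_lt(max(abs(fp$trajectory$P[, 3] - ps$p)), 1e-6)
  expect_lt(max(abs(fp$J)), 1e-6)
})

test_that("probability current matches the Gaussian transient identity and parity", {
  spec <- default_spec()
  g <- grid1d(-10, 15, 2048)
  # equilibrium: detailed balance, J = 0
  ps <- gaussian_to_grid(gaussian_state(0, stationary_beta(spec)),
                         grid1d(-10, 10, 2048))
  expect_lt(max(abs(probability_current(ps, function(x) -x, 0.5))), 1e-8)
  # transient: J = [-(betadot/2 beta)(x - y) + ydot] p
  path <- ou_propagate(spec, default_init(), c(0, 0.5))
  pk <- gaussian_to_grid(gaussian_state(path$y[2], path$beta[2]), g)
  J <- probability_current(pk, function(x) -x, 0.5)
  Jref <- (-(path$betadot[2] / (2 * path$beta[2])) * (g$x - path$y[2]) +
             path$ydot[2]) * pk$p
  expect_lt(max(abs(J - Jref)), 1e-4)
  # symmetric p, odd f, D = 0: J is odd
  g0 <- grid1d(-8, 8, 513)
  psym <- gaussian_to_grid(gaussian_state(0, 1), g0)
  Jodd <- probability_current(psym, function(x) -x^3, 0)
  expect_lt(max(abs(Jodd + rev(Jodd))), 1e-12)
})

test_that("the Langevin ensemble agrees with the analytic moments within sampling error", {
  spec <- default_spec()
  # noiseless limit: deterministic exponential decay
  mc0 <- langevin_simulate(process_spec(1, 0), 200, 5, c(0, 1), seed = 4)
  expect_equal(mc0$moments$var[2], 0)
  expect_equal(mc0$moments$mean[2], 5 * exp(-1), tolerance = 1e-2)
  # stochastic: mean within 4 SE at t = 1, stationary variance at late times
  mc <- langevin_simulate(spec, 2e4, 5, c(0, 1, 8), seed = 4,
                          grid = grid1d(-6, 10, 256))
  expect_lt(abs(mc$moments$mean[2] - 5 * exp(-1)), 4 * mc$moments$se_mean[2])
  se_var <- mc$moments$var[3] * sqrt(2 / (2e4 - 1))
  expect_lt(abs(mc$moments$var[3] - 0.5), 4 * se_var)
  # reproducibility for a fixed seed
  mc2 <- langevin_simulate(spec, 2e4, 5, c(0, 1, 8), seed = 4)
  expect_identical(mc$paths, mc2$paths)
  # empirical trajectory is a valid normalized pdf_trajectory
  expect_s3_class(mc$trajectory, "pdf_trajectory")
})

test_that("the dichotomous system conserves component masses and sums to the O-U mixture", {
  spec <- default_spec()
  bs <- stationary_beta(spec)
  g <- grid1d(-6, 11, 768)
  eq_half <- gaussian_to_grid(gaussian_state(0, bs), g)$p / 2
  d_half <- gaussian_to_grid(gaussian_state(5, bs), g)$p / 2
  tms <- seq(0, 3, by = 0.02)
  sol <- dichotomous_solve(spec, 1, eq_half, d_half, g, tms, dt = 0.005)
  expect_lt(max(abs(sol$mass1 - 0.5)), 1e-8)
  expect_lt(max(abs(sol$mass2 - 0.5)), 1e-8)
  # identical drifts: total density follows the analytic two-Gaussian mixture
  pa <- ou_propagate(spec, gaussian_state(0, bs), tms)
  pb <- ou_propagate(spec, gaussian_state(5, bs), tms)
  l1 <- vapply(seq_along(tms), function(k) {
    mix <- 0.5 * gaussian_to_grid(gaussian_state(pa$y[k], pa$beta[k]), g)$p +
           0.5 * gaussian_to_grid(gaussian_state(pb$y[k], pb$beta[k]), g)$p
    sum(trapz_weights_for_test(g) * abs(sol$total$P[, k] - mix))
  }, numeric(1))
  expect_lt(max(l1), 1e-3)
  # r = 0 decouples: component 2 evolves as an independent O-U density
  sol0 <- dichotomous_solve(spec, 0, eq_half, d_half, g, seq(0, 1, by = 0.02),
                            dt = 0.005)
  fp0 <- fp_solve(spec, grid_pdf(g, 2 * d_half, renormalize = TRUE),
                  seq(0, 1, by = 0.02), dt = 0.005)
  expect_lt(max(abs(sol0$comp2$P[, 51] - fp0$trajectory$P[, 51])), 1e-6)
  expect_error(dichotomous_solve(spec, 1, eq_half, 2 * d_half, g, tms),
               "mass 1/2")
})
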