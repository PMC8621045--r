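# Shared builders for the test suite. The default relaxation scenario
# (gamma = 1, D = 0.5, x0 = 5, beta0 = 0.3) is the workhorse configuration
# used across modules.

default_spec <- function() process_spec(gamma = 1, D = 0.5, v = 0)

default_init <- function() gaussian_state(5, 0.3)

default_grid <- function(n = 2048) grid1d(-10, 15, n)

# analytic O-U trajectory sampled on a grid
analytic_trajectory <- function(spec = default_spec(), init = default_init(),
                                times = seq(0.1, 2, by = 1e-3),
                                grid = default_grid()) {
  path <- ou_propagate(spec, init, times)
  list(path = path, traj = ou_path_to_trajectory(path, grid))
}

# independent moment-ODE oracle for the O-U mean/variance (deSolve), used to
# cross-check the quadrature formulas of ou_propagate
ode_moment_oracle <- function(spec, init, times) {
  rhs <- function(t, state, parms) {
    list(c(-spec$gamma(t) * (state[1] - spec$v(t)),
           -2 * spec$gamma(t) * state[2] + 2 * spec$D(t)))
  }
  out <- deSolve::lsoda(c(y = init$mean, s2 = init$sigma2), times, rhs,
                        rtol = 1e-11, atol = 1e-12)
  data.frame(t = out[, 1], y = out[, 2], sigma2 = out[, 3])
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}

trapz_weights_for_test <- function(g) {
  w <- rep(g$dx, g$n); w[c(1, g$n)] <- g$dx / 2
  w
}
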