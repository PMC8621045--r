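# Thermodynamic functionals: closed forms on analytic Gaussian paths,
# grid-quadrature closure on sampled trajectories, the stationary-reference
# relative entropy, the Gamma identities and the Schwartz-inequality suite.

driven_path <- function(times = seq(0, 20, by = 0.005)) {
  # u-driven equilibrium start: gamma = 1, D = 0.5, u = 1, beta0 = beta_s
  spec <- process_spec(1, 0.5, ramp_u = 1)
  list(spec = spec,
       path = ou_propagate(spec, gaussian_state(0, stationary_beta(spec)),
                           times))
}

test_that("the driven-from-equilibrium closed forms hit their exact values at t = ln 2", {
  d <- driven_path(times = sort(unique(c(log(2), seq(0, 20, by = 0.01)))))
  ts <- thermo_gaussian(d$path, d$spec)
  k <- which(ts$t == log(2))
  D <- 0.5
  expect_equal(D * ts$ST_dot[k], 0.25, tolerance = 1e-12)
  expect_equal(ts$Wdot[k], 0.5, tolerance = 1e-12)
  expect_equal(D * ts$K_s[k], 0.125, tolerance = 1e-12)
  expect_equal(D * ts$dK_dt[k], 0.25, tolerance = 1e-12)
  expect_equal(ts$c_fluct[k], 0.5, tolerance = 1e-12)
  expect_equal(ts$Qdot[k], D * ts$Sm_dot[k], tolerance = 1e-14)
  # t -> infinity: D ST_dot = Qdot = Wdot -> u^2, Sdot and dK/dt -> 0
  n <- nrow(ts)
  expect_equal(D * ts$ST_dot[n], 1, tolerance = 1e-6)
  expect_equal(ts$Qdot[n], 1, tolerance = 1e-6)
  expect_equal(ts$Wdot[n], 1, tolerance = 1e-6)
  expect_lt(abs(ts$Sdot[n]), 1e-6)
  expect_lt(abs(ts$dK_dt[n]), 1e-6)
  # all drive quantities rise monotonically to their asymptotes
  expect_true(all(diff(ts$ST_dot) >= -1e-14))
  expect_true(all(diff(ts$Qdot) >= -1e-14))
  expect_true(all(diff(ts$Wdot) >= -1e-14))
  expect_true(all(diff(ts$K_s) >= -1e-14))
})

test_that("entropy rates close (Sdot = ST_dot - Sm_dot) and match dS/dt of the closed form", {
  # pure variance relaxation: Sdot = sigmadot/sigma equals d/dt of S(beta)
  spec <- default_spec()
  path <- ou_propagate(spec, gaussian_state(0, 0.3), seq(0.1, 2, by = 1e-3))
  ts <- thermo_gaussian(path, spec)
  dS_num <- (ts$S[3:nrow(ts)] - ts$S[1:(nrow(ts) - 2)]) / (2 * 1e-3)
  expect_rel_equal(ts$Sdot[2:(nrow(ts) - 1)], dS_num, 1e-5)
  # equilibrium: everything vanishes
  eq <- ou_propagate(spec, gaussian_state(0, stationary_beta(spec)),
                     seq(0, 1, by = 0.01))
  tse <- thermo_gaussian(eq, spec)
  expect_lt(max(abs(tse$ST_dot)), 1e-8)
  expect_lt(max(abs(tse$Sdot)), 1e-8)
  # driven case at t = ln 2: ST_dot = 0.5 through entropy_rates
  d <- driven_path(times = sort(unique(c(log(2), seq(0, 2, by = 0.01)))))
  er <- entropy_rates(d$path, d$spec)
  expect_equal(er$ST_dot[er$t == log(2)], 0.5, tolerance = 1e-12)
})

test_that("numeric closure holds on an analytically sampled trajectory", {
  spec <- default_spec()
  tt <- seq(0.5, 1.5, by = 2.5e-4)
  path <- ou_propagate(spec, default_init(), tt)
  traj <- ou_path_to_trajectory(path, default_grid())
  ts <- thermo_numeric(traj, spec)
  res <- attr(ts, "residuals")
  expect_lt(res$entropy_split, 1e-6)
  expect_lt(res$first_law, 1e-6)
  expect_lt(res$free_energy, 1e-6)
  # and against the closed forms
  tg <- thermo_gaussian(path, spec)
  expect_rel_equal(ts$ST_dot, tg$ST_dot, 1e-3)
  expect_rel_equal(ts$S, tg$S, 1e-5)
  expect_rel_equal(ts$U, tg$U, 1e-5)
})

test_that("work, heat and dissipated power behave as the first and second laws demand", {
  d <- driven_path(times = seq(0, 4, by = 0.01))
  hw <- heat_work_energy(d$path, d$spec)
  expect_true(all(hw$Wdot >= 0))
  fe <- free_energy(d$path, d$spec)
  expect_true(all(fe$WD_dot >= -1e-12))          # D ST_dot >= 0
  expect_true(all(fe$W_minus_dF >= -1e-10))      # integrated dissipation
  # static potential, stationary state: all rates vanish
  spec <- default_spec()
  eq <- ou_propagate(spec, gaussian_state(0, stationary_beta(spec)),
                     seq(0, 1, by = 0.01))
  hw0 <- heat_work_energy(eq, spec)
  expect_lt(max(abs(hw0$Wdot)), 1e-12)
  expect_lt(max(abs(hw0$Qdot)), 1e-10)
  expect_error(thermo_gaussian(eq, process_spec(1, function(t) 0.5 + 0 * t)),
               "time-varying D")
})

test_that("the stationary reference satisfies F - F_s = D K_s with K_s >= 0", {
  d <- driven_path(times = seq(0, 5, by = 0.01))
  sr <- stationary_reference(d$path, d$spec)
  expect_lt(attr(sr, "residual_free_energy"), 1e-8)
  expect_true(all(sr$K_s >= 0))
  # p = p_s: zero relative entropy
  spec <- default_spec()
  eq <- ou_propagate(spec, gaussian_state(0, stationary_beta(spec)),
                     seq(0, 1, by = 0.01))
  sre <- stationary_reference(eq, spec)
  expect_lt(max(abs(sre$K_s)), 1e-13)
  expect_lt(max(abs(sre$F - sre$F_s)), 1e-13)
  # numeric route: dK/dt identity within the pipeline tolerance
  tt <- seq(0.5, 1.5, by = 5e-4)
  path <- ou_propagate(spec, default_init(), tt)
  traj <- ou_path_to_trajectory(path, default_grid())
  srn <- stationary_reference(traj, spec)
  expect_lt(attr(srn, "residual_dK"), 1e-3)
  expect_error(stationary_reference(d$path, process_spec(function(t) 1 + t, 0.5)),
               "constant gamma")
})

test_that("Gamma^2 = (D/sigma^2) ST_dot + Sdot^2 to rounding on random analytic draws", {
  set.seed(23)
  for (i in 1:100) {
    spec <- process_spec(runif(1, 0.2, 5), runif(1, 0.05, 2),
                         ramp_u = runif(1, -2, 2))
    path <- ou_propagate(spec, gaussian_state(runif(1, -10, 10),
                                              runif(1, 0.05, 10)),
                         seq(0.01, 5, length.out = 80))
    gi <- gamma_identities(path, spec)
    expect_lt(max(gi$eq_gamma_st), 1e-10)
    expect_lt(max(gi$eq_speed), 1e-10)
  }
  # frozen variance: the proportional form and L = |d<x>|/sigma hold exactly
  spec <- process_spec(1, 0.5, ramp_u = 1)
  path <- ou_propagate(spec, gaussian_state(0, stationary_beta(spec)),
                       seq(0, 5, by = 0.01))
  gi <- gamma_identities(path, spec)
  expect_true(gi$sigma_frozen)
  expect_lt(max(gi$eq_linear), 1e-10)
  expect_lt(max(gi$eq_L_mean), 1e-6)
  # general relaxation (beta0 != beta_s): proportionality must fail
  spec2 <- default_spec()
  path2 <- ou_propagate(spec2, default_init(), seq(0.1, 2, by = 0.01))
  gi2 <- gamma_identities(path2, spec2)
  expect_false(gi2$sigma_frozen)
  ts2 <- thermo_gaussian(path2, spec2)
  expect_gt(max(abs(ts2$Gamma^2 - (0.5 / ts2$sigma^2) * ts2$ST_dot) /
                  ts2$Gamma^2), 0.01)
})

test_that("microscopic free-energy identities hold through the numeric pipeline", {
  spec <- default_spec()
  tt <- seq(0.3, 1.3, by = 5e-4)
  path <- ou_propagate(spec, default_init(), tt)
  traj <- ou_path_to_trajectory(path, default_grid())
  mf <- micro_free_energy_checks(traj, spec)
  expect_lt(max(mf$res_power), 1e-6)    # <dmu/dt> = Wdot
  expect_lt(max(mf$res_gamma), 0.01)    # <(dmu/dt - dV/dt)^2> = D^2 Gamma^2
  expect_lt(max(mf$res_entropy), 0.01)  # -int mu pdot = D ST_dot
  # driven scenario exercises a non-zero power
  spec_u <- process_spec(1, 0.5, ramp_u = 1)
  ttu <- seq(0.2, 1.2, by = 5e-4)
  path_u <- ou_propagate(spec_u, gaussian_state(0, 1), ttu)
  traj_u <- ou_path_to_trajectory(path_u, grid1d(-8, 10, 2048))
  mfu <- micro_free_energy_checks(traj_u, spec_u)
  expect_lt(max(mfu$res_power), 1e-4)
  expect_lt(max(mfu$res_entropy), 0.01)
})

test_that("the Schwartz bounds hold with saturation in the two extreme cases", {
  set.seed(31)
  for (i in 1:100) {
    spec <- process_spec(runif(1, 0.2, 5), runif(1, 0.05, 2),
                         ramp_u = runif(1, -2, 2))
    path <- ou_propagate(spec, gaussian_state(runif(1, -10, 10),
                                              runif(1, 0.05, 10)),
                         seq(0.01, 5, length.out = 60))
    iq <- inequality_suite(path, spec)
    expect_gt(min(iq$margin_S), -1e-12)
    expect_gt(min(iq$margin_Q), -1e-12)
    expect_gt(min(iq$margin_ST), -1e-12)
  }
  # frozen sigma (driven from equilibrium): ST_dot bound saturates
  spec <- process_spec(1, 0.5, ramp_u = 1)
  path <- ou_propagate(spec, gaussian_state(0, stationary_beta(spec)),
                       seq(0.1, 3, by = 0.05))
  sat <- attr(inequality_suite(path, spec), "saturation")
  expect_lt(sat$sigma_frozen, 1e-10)
  # frozen mean (pure variance relaxation): saturates as well
  spec2 <- default_spec()
  path2 <- ou_propagate(spec2, gaussian_state(0, 0.3), seq(0.1, 3, by = 0.05))
  sat2 <- attr(inequality_suite(path2, spec2), "saturation")
  expect_lt(sat2$mean_frozen, 1e-10)
})
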