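# Non-equilibrium thermodynamics of a trajectory (k_B = 1, D plays the role
# of the bath temperature). Two routes are provided for every functional:
# closed forms on analytic Gaussian paths ("ou_path") and grid quadrature on
# sampled trajectories ("pdf_trajectory").

# time derivative of v(t) (exact for constants and ramps, numeric otherwise)
spec_vdot <- function(spec, t) {
  if (!is.na(spec$ramp_u)) return(rep(spec$ramp_u, length(t)))
  if (!is.na(spec$v_const)) return(rep(0, length(t)))
  h <- 1e-6
  (spec$v(t + h) - spec$v(t - h)) / (2 * h)
}

spec_gammadot <- function(spec, t) {
  if (!is.na(spec$gamma_const)) return(rep(0, length(t)))
  h <- 1e-6
  (spec$gamma(t + h) - spec$gamma(t - h)) / (2 * h)
}

#' Closed-form thermodynamic series of a Gaussian O-U path
#'
#' Evaluates, at every time of the path, the Gaussian closed forms of the
#' thermodynamic functionals of an O-U process: entropy
#' `S = (1 + ln(pi/beta))/2`, system entropy rate `Sdot = sigmadot/sigma`,
#' total entropy production `D ST_dot = sigmadot^2 + ydot^2`, entropy flow
#' `Sm_dot = ST_dot - Sdot`, heat `Qdot = D Sm_dot`, internal energy
#' `U = <V>`, power `Wdot = <dV/dt>`, free energy `F = U - D S`, dissipated
#' power `WD_dot = D ST_dot`, relative entropy to the frozen stationary
#' state `K_s`, its rate, the fluctuation speed `c = sigma Gamma`, and the
#' information rate `Gamma` itself.
#'
#' @param path An `ou_path` data frame (from [ou_propagate()] or
#'   [geodesic_path()]).
#' @param spec The [process_spec()] that generated it. `D` must be a
#'   constant (`F = U - D S` treats `D` as the effective temperature);
#'   `K_s` columns additionally require constant `gamma`.
#' @return A data frame of class `thermo_series`.
#' @export
thermo_gaussian <- function(path, spec) {
  stopifnot(inherits(path, "ou_path"), inherits(spec, "process_spec"))
  if (is.na(spec$D_const))
    stop("thermo_gaussian: time-varying D is not supported (F = U - D*S needs a fixed effective temperature)")
  D <- spec$D_const
  t <- path$t
  gam <- spec$gamma(t)
  vt <- spec$v(t)
  vdot <- spec_vdot(spec, t)
  gamdot <- spec_gammadot(spec, t)
  S <- 0.5 * (1 + log(pi / path$beta))
  Sdot <- path$sigmadot / path$sigma
  DST <- path$sigmadot^2 + path$ydot^2
  ST_dot <- DST / D
  Sm_dot <- ST_dot - Sdot
  Qdot <- D * Sm_dot
  dev <- path$y - vt
  U <- gam / 2 * (path$sigma2 + dev^2)
  Wdot <- gamdot / 2 * (path$sigma2 + dev^2) - gam * vdot * dev
  F <- U - D * S
  Gamma <- sqrt((2 * path$sigmadot^2 + path$ydot^2) / path$sigma2)
  out <- data.frame(t = t, S = S, Sdot = Sdot, ST_dot = ST_dot,
                    Sm_dot = Sm_dot, Qdot = Qdot, U = U, Wdot = Wdot,
                    F = F, WD_dot = D * ST_dot, Gamma = Gamma,
                    c_fluct = path$sigma * Gamma,
                    sigma = path$sigma, sigmadot = path$sigmadot,
                    ydot = path$ydot)
  if (!is.na(spec$gamma_const) && D > 0) {
    beta_s <- stationary_beta(spec)
    out$K_s <- 0.5 * (log(path$beta / beta_s) - 1) +
      beta_s * (dev^2 + 1 / (2 * path$beta))
    out$dK_dt <- -ST_dot + Wdot / D  # frozen-parameter F_s is constant
    out$Wirr_dot <- D * ST_dot + D * out$dK_dt
    out$F_s <- gam / 2 * (1 / (2 * beta_s)) - D * 0.5 * (1 + log(pi / beta_s))
  }
  class(out) <- c("thermo_series", "data.frame")
  out
}

#' Numeric thermodynamic series of a sampled trajectory
#'
#' Grid-quadrature version of [thermo_gaussian()] for arbitrary sampled
#' densities. The probability current is `J = f p - D dp/dx`; then
#' `ST_dot = integral J^2/(D p) dx` (evaluated where `p > 1e-14`),
#' `Sm_dot = integral J f / D dx`, `Qdot = integral J f dx`, `U = <V>`,
#' `Wdot = <dV/dt>`, `F = U - D S`. Scalar series are differentiated by
#' central differences in time. Decomposition residuals
#' `|Sdot - (ST_dot - Sm_dot)|` and `|Udot - (Wdot - Qdot)|` are returned so
#' callers can verify closure.
#'
#' @param traj A [pdf_trajectory()].
#' @param spec The [process_spec()] that generated it (constant `D > 0`).
#' @return A data frame of class `thermo_series` with an attribute
#'   `residuals` (list with `entropy_split`, `first_law`, `free_energy`).
#' @export
thermo_numeric <- function(traj, spec) {
  stopifnot(inherits(traj, "pdf_trajectory"), inherits(spec, "process_spec"))
  if (is.na(spec$D_const))
    stop("thermo_numeric: time-varying D is not supported")
  D <- spec$D_const
  t <- traj$times
  nt <- length(t)
  dt <- check_uniform_dt(t)
  grid <- traj$grid
  x <- grid$x
  w <- trapz_weights(grid)
  h <- 1e-6
  S <- numeric(nt); ST_dot <- numeric(nt); Sm_dot <- numeric(nt)
  Qdot <- numeric(nt); U <- numeric(nt); Wdot <- numeric(nt)
  K_s <- rep(NA_real_, nt)
  have_ks <- !is.na(spec$gamma_const) && D > 0
  if (have_ks) beta_s <- stationary_beta(spec)
  for (k in seq_len(nt)) {
    pk <- traj_snapshot(traj, k)
    fv <- spec$f(x, t[k])
    J <- probability_current(pk, fv, D)
    live <- pk$p > 1e-14
    if (D > 0) {
      integ <- numeric(grid$n)
      integ[live] <- J[live]^2 / (D * pk$p[live])
      ST_dot[k] <- sum(w * integ)
      Sm_dot[k] <- sum(w * J * fv) / D
    } else if (max(abs(J)) > 1e-12) {
      stop("thermo_numeric: D = 0 with non-zero current; ST_dot undefined")
    }
    S[k] <- differential_entropy(pk)
    Vv <- spec$V(x, t[k])
    dV <- (spec$V(x, t[k] + h) - spec$V(x, t[k] - h)) / (2 * h)
    U[k] <- sum(w * Vv * pk$p)
    Wdot[k] <- sum(w * dV * pk$p)
    Qdot[k] <- sum(w * J * fv)
    if (have_ks) {
      ps <- gaussian_to_grid(gaussian_state(spec$v(t[k]), beta_s), grid)
      K_s[k] <- kl_divergence(pk, ps)
    }
  }
  Sdot <- time_derivative_series(S, dt)
  Udot <- time_derivative_series(U, dt)
  F <- U - D * S
  Fdot <- time_derivative_series(F, dt)
  out <- data.frame(t = t, S = S, Sdot = Sdot, ST_dot = ST_dot,
                    Sm_dot = Sm_dot, Qdot = Qdot, U = U, Udot = Udot,
                    Wdot = Wdot, F = F, Fdot = Fdot, WD_dot = D * ST_dot,
                    K_s = K_s)
  # interior times only: the one-sided end stencils are less accurate
  interior <- 2:(nt - 1)
  attr(out, "residuals") <- list(
    entropy_split = max(abs(Sdot - (ST_dot - Sm_dot))[interior]),
    first_law = max(abs(Udot - (Wdot - Qdot))[interior]),
    free_energy = max(abs(Fdot - (Wdot - D * ST_dot))[interior]))
  class(out) <- c("thermo_series", "data.frame")
  out
}

#' Entropy rates of a trajectory
#'
#' System entropy rate `Sdot`, total entropy production rate `ST_dot` and
#' entropy flow to the environment `Sm_dot`, with the decomposition
#' `Sdot = ST_dot - Sm_dot`.
#'
#' @param traj An `ou_path` (closed forms) or [pdf_trajectory()] (numeric).
#' @param spec The generating [process_spec()].
#' @return A data frame `t, S, Sdot, ST_dot, Sm_dot` with attribute
#'   `residual` (maximal decomposition residual; exactly 0 on the analytic
#'   route where `Sm_dot` is defined by the split).
#' @export
entropy_rates <- function(traj, spec) {
  ts <- if (inherits(traj, "ou_path")) thermo_gaussian(traj, spec)
        else thermo_numeric(traj, spec)
  out <- ts[, c("t", "S", "Sdot", "ST_dot", "Sm_dot")]
  attr(out, "residual") <- if (inherits(traj, "ou_path")) 0
    else attr(ts, "residuals")$entropy_split
  out
}

#' Heat, work and internal energy of a trajectory
#'
#' `U = <V>`, power `Wdot = <dV/dt>`, heat rate `Qdot = integral J f dx`,
#' and the first-law closure `Udot = Wdot - Qdot`. The cumulative work
#' `W = integral Wdot` is attached.
#'
#' @inheritParams entropy_rates
#' @return A data frame `t, U, Wdot, Qdot, W` with attribute `residual`
#'   (maximal first-law residual; 0 on the analytic route).
#' @export
heat_work_energy <- function(traj, spec) {
  ts <- if (inherits(traj, "ou_path")) thermo_gaussian(traj, spec)
        else thermo_numeric(traj, spec)
  out <- ts[, c("t", "U", "Wdot", "Qdot")]
  out$W <- cumtrapz(ts$t, ts$Wdot)
  attr(out, "residual") <- if (inherits(traj, "ou_path")) 0
    else attr(ts, "residuals")$first_law
  out
}

#' Non-equilibrium free energy and dissipated power
#'
#' `F = U - D S` (constant `D` as effective temperature), its rate
#' `Fdot = Wdot - D ST_dot`, and the non-negative dissipated power
#' `WD_dot = Wdot - Fdot = D ST_dot`.
#'
#' @inheritParams entropy_rates
#' @return A data frame `t, F, WD_dot` plus `W_minus_dF` (the cumulative
#'   dissipated work `W - dF >= 0`), with attribute `residual`.
#' @export
free_energy <- function(traj, spec) {
  ts <- if (inherits(traj, "ou_path")) thermo_gaussian(traj, spec)
        else thermo_numeric(traj, spec)
  out <- ts[, c("t", "F", "WD_dot")]
  W <- cumtrapz(ts$t, ts$Wdot)
  out$W_minus_dF <- W - (ts$F - ts$F[1])
  attr(out, "residual") <- if (inherits(traj, "ou_path")) 0
    else attr(ts, "residuals")$free_energy
  out
}

#' Frozen-parameter stationary reference and relative entropy
#'
#' For an O-U spec with constant `gamma` and `D`, the instantaneous
#' stationary state is the Gaussian centered at `v(t)` with
#' `beta_s = gamma/(2D)`. Returns the relative entropy `K_s = K[p | p_s]`,
#' the identity `F - F_s = D K_s`, the irreversible-work rate
#' `Wirr_dot = D ST_dot + D dK_s/dt`, and the residual of
#' `dK_s/dt = -ST_dot + Wdot/D` (valid while `F_s` is constant).
#'
#' @inheritParams entropy_rates
#' @return A data frame `t, K_s, F, F_s, dK_dt, Wirr_dot` with attributes
#'   `residual_free_energy` (max `|F - F_s - D K_s|`) and `residual_dK`
#'   (max residual of the rate identity, numeric route only).
#' @export
stationary_reference <- function(traj, spec) {
  if (is.na(spec$gamma_const) || is.na(spec$D_const) || spec$D_const <= 0)
    stop("stationary_reference: requires an O-U spec with constant gamma and D > 0")
  D <- spec$D_const
  beta_s <- stationary_beta(spec)
  F_s <- spec$gamma_const / 2 * (1 / (2 * beta_s)) -
    D * 0.5 * (1 + log(pi / beta_s))
  if (inherits(traj, "ou_path")) {
    ts <- thermo_gaussian(traj, spec)
    out <- data.frame(t = ts$t, K_s = ts$K_s, F = ts$F, F_s = F_s,
                      dK_dt = ts$dK_dt, Wirr_dot = ts$Wirr_dot)
    attr(out, "residual_free_energy") <- max(abs(ts$F - F_s - D * ts$K_s))
    attr(out, "residual_dK") <- 0
  } else {
    ts <- thermo_numeric(traj, spec)
    dt <- check_uniform_dt(ts$t)
    dK <- time_derivative_series(ts$K_s, dt)
    out <- data.frame(t = ts$t, K_s = ts$K_s, F = ts$F, F_s = F_s,
                      dK_dt = dK, Wirr_dot = D * ts$ST_dot + D * dK)
    interior <- 2:(nrow(ts) - 1)
    attr(out, "residual_free_energy") <- max(abs(ts$F - F_s - D * ts$K_s))
    attr(out, "residual_dK") <-
      max(abs(dK - (-ts$ST_dot + ts$Wdot / D))[interior])
  }
  if (min(out$K_s) < -1e-12)
    stop("stationary_reference: negative relative entropy")
  out
}

#' Identities linking the information rate to entropy production
#'
#' Residual report for the exact O-U identities:
#' `Gamma^2 = (D/sigma^2) ST_dot + Sdot^2` (always),
#' `Gamma^2 = (D/sigma^2) ST_dot` and `L = |<x>(t) - <x>(0)|/sigma` (when
#' `sigmadot = 0`), and the fluctuation speed
#' `c = sigma Gamma = sqrt(D ST_dot + sigma^2 Sdot^2)`.
#'
#' @param path An `ou_path`.
#' @param spec The generating [process_spec()] (constant `D`).
#' @return A list with per-time relative residuals `eq_gamma_st` (the full
#'   identity), `eq_speed` (the `c` form), and, when the variance is frozen,
#'   `eq_linear` (the proportional form) and `eq_L_mean` (the mean-sweep
#'   length); plus `sigma_frozen` (logical).
#' @export
gamma_identities <- function(path, spec) {
  ts <- thermo_gaussian(path, spec)
  D <- spec$D_const
  E <- ts$Gamma^2
  rhs <- (D / ts$sigma^2) * ts$ST_dot + ts$Sdot^2
  scale <- pmax(E, 1e-30)
  res <- list(
    eq_gamma_st = abs(E - rhs) / scale,
    eq_speed = abs(ts$c_fluct - sqrt(pmax(D * ts$ST_dot + ts$sigma^2 * ts$Sdot^2, 0))) /
      pmax(ts$c_fluct, 1e-30),
    sigma_frozen = all(abs(ts$sigmadot) < 1e-12 * max(1, max(abs(ts$ydot)))))
  if (res$sigma_frozen) {
    res$eq_linear <- abs(E - (D / ts$sigma^2) * ts$ST_dot) / scale
    L <- cumtrapz(ts$t, ts$Gamma)
    Lref <- abs(cumtrapz(ts$t, ts$ydot)) / ts$sigma
    res$eq_L_mean <- abs(L - Lref) / pmax(Lref, 1e-12)
  }
  res
}

#' Microscopic free-energy identities (numeric)
#'
#' With `mu = V + D ln p`, checks on a sampled trajectory that
#' `<dmu/dt> = Wdot`, `<(dmu/dt - dV/dt)^2> = D^2 Gamma^2`, and
#' `D ST_dot = -integral mu dp/dt dx`. Time derivatives by central
#' differences; integrands are restricted to nodes with `p > 1e-14`.
#'
#' @param traj A [pdf_trajectory()].
#' @param spec The generating [process_spec()] with constant `D > 0`.
#' @return A data frame (interior times) with the three left/right pairs and
#'   their relative residuals `res_power`, `res_gamma`, `res_entropy`.
#' @export
micro_free_energy_checks <- function(traj, spec) {
  stopifnot(inherits(traj, "pdf_trajectory"))
  if (is.na(spec$D_const) || spec$D_const <= 0)
    stop("micro_free_energy_checks: requires constant D > 0")
  D <- spec$D_const
  grid <- traj$grid
  w <- trapz_weights(grid)
  t <- traj$times
  dt <- check_uniform_dt(t)
  pdot <- time_derivative_matrix(traj$P, dt)
  gser <- information_rate_numeric(traj)
  ts <- thermo_numeric(traj, spec)
  h <- 1e-6
  interior <- 2:(length(t) - 1)
  rows <- lapply(interior, function(k) {
    p <- traj$P[, k]
    live <- p > 1e-14
    pd <- pdot[, k]
    Vv <- spec$V(grid$x, t[k])
    dV <- (spec$V(grid$x, t[k] + h) - spec$V(grid$x, t[k] - h)) / (2 * h)
    mu <- ifelse(live, Vv + D * log(pmax(p, 1e-300)), 0)
    # <dmu/dt> = <dV/dt> + D * integral pdot  (integral pdot = 0 exactly)
    lhs_power <- sum(w * p * dV) + D * sum(w * pd)
    lhs_gamma <- D^2 * sum(w[live] * pd[live]^2 / p[live])
    lhs_entropy <- -sum(w[live] * mu[live] * pd[live])
    data.frame(t = t[k],
               power_lhs = lhs_power, power_rhs = ts$Wdot[k],
               gamma_lhs = lhs_gamma, gamma_rhs = D^2 * gser$E[k],
               entropy_lhs = lhs_entropy, entropy_rhs = D * ts$ST_dot[k])
  })
  out <- do.call(rbind, rows)
  # relative to the global scale of each identity, so identically-zero
  # right-hand sides (e.g. Wdot = 0 in pure relaxation) stay well-posed
  scale_power <- max(abs(out$power_rhs), max(out$entropy_rhs), 1e-12)
  out$res_power <- abs(out$power_lhs - out$power_rhs) / scale_power
  out$res_gamma <- abs(out$gamma_lhs - out$gamma_rhs) /
    max(out$gamma_rhs, 1e-30)
  out$res_entropy <- abs(out$entropy_lhs - out$entropy_rhs) /
    max(out$entropy_rhs, 1e-30)
  out
}

#' Schwartz-inequality suite for the O-U process
#'
#' Checks the three bounds that the information rate puts on thermodynamic
#' rates of a Gaussian O-U trajectory:
#' `|Sdot| <= Gamma/sqrt(2)`,
#' `|Qdot| <= Gamma sigma sqrt(ydot^2 + gamma^2 sigma^2 / 2)`, and
#' `D ST_dot <= Gamma sigma sqrt(ydot^2 + sigmadot^2 / 2)`.
#' The last bound saturates when either `sigmadot = 0` or `ydot = 0`.
#'
#' @param path An `ou_path` of an O-U process with constant `gamma`, `D`.
#' @param spec The generating [process_spec()].
#' @return A data frame with per-time margins (`bound - |rate|`, all
#'   non-negative up to rounding) and attribute `saturation` giving the
#'   maximal relative slack of the `ST_dot` bound where a saturating
#'   condition holds.
#' @export
inequality_suite <- function(path, spec) {
  if (is.na(spec$gamma_const))
    stop("inequality_suite: requires constant gamma")
  ts <- thermo_gaussian(path, spec)
  gam <- spec$gamma_const
  D <- spec$D_const
  b_S <- ts$Gamma / sqrt(2)
  b_Q <- ts$Gamma * ts$sigma * sqrt(ts$ydot^2 + gam^2 * ts$sigma^2 / 2)
  b_ST <- ts$Gamma * ts$sigma * sqrt(ts$ydot^2 + ts$sigmadot^2 / 2)
  out <- data.frame(t = ts$t,
                    margin_S = b_S - abs(ts$Sdot),
                    margin_Q = b_Q - abs(ts$Qdot),
                    margin_ST = b_ST - D * ts$ST_dot)
  sat <- abs(out$margin_ST) / pmax(b_ST, 1e-30)
  frozen_sigma <- abs(ts$sigmadot) < 1e-12 * pmax(1, abs(ts$ydot))
  frozen_mean <- abs(ts$ydot) < 1e-12 * pmax(1, abs(ts$sigmadot))
  attr(out, "saturation") <- list(
    sigma_frozen = if (any(frozen_sigma)) max(sat[frozen_sigma]) else NA_real_,
    mean_frozen = if (any(frozen_mean)) max(sat[frozen_mean]) else NA_real_)
  out
}
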