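#' Ornstein-Uhlenbeck process specification
#'
#' Defines the overdamped Langevin model
#' `dx/dt = -gamma(t) (x - v(t)) + xi`, with delta-correlated Gaussian noise
#' `<xi(t) xi(t')> = 2 D(t) delta(t - t')`. The drift is
#' `f(x, t) = -gamma(t) (x - v(t))` and the confining potential
#' `V(x, t) = gamma(t) (x - v(t))^2 / 2`.
#'
#' Each coefficient may be a constant or a function of time; constants are
#' detected and unlock the closed-form propagation formulas. A linear ramp
#' `v(t) = u t` can be requested directly with `ramp_u`.
#'
#' @param gamma Damping, positive (constant or function of t).
#' @param D Noise amplitude, non-negative (constant or function of t).
#' @param v Force center (constant or function of t); ignored when `ramp_u`
#'   is given.
#' @param ramp_u Optional ramp rate making `v(t) = ramp_u * t`.
#' @return An object of class `process_spec`.
#' @export
#' @examples
#' sp <- process_spec(gamma = 1, D = 0.5)
#' sp$f(0.5, 0)  # drift -gamma * x at x = 0.5
process_spec <- function(gamma = 1, D = 1, v = 0, ramp_u = NULL) {
  as_fn <- function(a) if (is.function(a)) a else function(t) rep(a, length(t))
  gamma_const <- if (is.numeric(gamma)) gamma else NA_real_
  D_const <- if (is.numeric(D)) D else NA_real_
  if (!is.null(ramp_u)) {
    v_const <- NA_real_
    v_fn <- function(t) ramp_u * t
  } else {
    v_const <- if (is.numeric(v)) v else NA_real_
    v_fn <- as_fn(v)
  }
  gamma_fn <- as_fn(gamma)
  D_fn <- as_fn(D)
  if (is.numeric(gamma) && gamma <= 0) stop("process_spec: gamma must be > 0")
  if (is.numeric(D) && D < 0) stop("process_spec: D must be >= 0")
  sp <- list(gamma = gamma_fn, D = D_fn, v = v_fn,
             gamma_const = gamma_const, D_const = D_const,
             v_const = v_const, ramp_u = if (is.null(ramp_u)) NA_real_ else ramp_u)
  sp$f <- function(x, t) -sp$gamma(t) * (x - sp$v(t))
  sp$V <- function(x, t) sp$gamma(t) * (x - sp$v(t))^2 / 2
  structure(sp, class = "process_spec")
}

#' @export
print.process_spec <- function(x, ...) {
  fmt <- function(const, label) {
    if (!is.na(const)) sprintf("%s = %g", label, const)
    else sprintf("%s = <function>", label)
  }
  vlab <- if (!is.na(x$ramp_u)) sprintf("v = %g * t", x$ramp_u)
          else fmt(x$v_const, "v")
  cat("process_spec:", fmt(x$gamma_const, "gamma"), "|",
      fmt(x$D_const, "D"), "|", vlab, "\n")
  invisible(x)
}

spec_is_const <- function(spec) !is.na(spec$gamma_const) && !is.na(spec$D_const)

#' Stationary inverse temperature of an O-U spec
#'
#' For constant `gamma` and `D`, the stationary Gaussian has
#' `beta_s = gamma / (2 D)` (variance `D / gamma`).
#'
#' @param spec A [process_spec()] with constant `gamma` and `D > 0`.
#' @return `beta_s`.
#' @export
stationary_beta <- function(spec) {
  if (!spec_is_const(spec) || spec$D_const <= 0)
    stop("stationary_beta: requires constant gamma and D > 0")
  spec$gamma_const / (2 * spec$D_const)
}

#' Exact O-U propagation of a Gaussian state
#'
#' Propagates a Gaussian initial condition through the (possibly
#' non-autonomous) O-U process. The density remains Gaussian for all time;
#' its mean and variance are given by the exact quadrature formulas
#' `y(t) = x0 exp(-G(t)) + integral_0^t exp(-(G(t) - G(s))) gamma(s) v(s) ds`
#' and
#' `sigma^2(t) = exp(-2 G(t)) sigma0^2
#'             + integral_0^t exp(-2 (G(t) - G(s))) 2 D(s) ds`,
#' with `G(t) = integral_0^t gamma`. Constant coefficients use the closed
#' forms (including the ramp case `v = u t`, where
#' `y = x0 e^{-gamma t} + u t - (u/gamma)(1 - e^{-gamma t})`); otherwise the
#' integrals are evaluated by adaptive quadrature to `1e-10`.
#'
#' The exact derivatives `ydot = -gamma (y - v)` and
#' `betadot = 2 gamma beta - 4 D beta^2` are returned alongside, so no
#' numeric differentiation is ever needed on analytic trajectories.
#'
#' @param spec A [process_spec()].
#' @param init A [gaussian_state()] at `t = 0`.
#' @param times Output times (>= 0).
#' @return A data frame of class `ou_path` with columns
#'   `t, y, beta, sigma, sigma2, ydot, betadot, sigmadot`.
#' @export
#' @examples
#' path <- ou_propagate(process_spec(1, 0.5), gaussian_state(5, 0.3),
#'                      seq(0, 2, by = 0.1))
#' path$y[1]  # 5 at t = 0
ou_propagate <- function(spec, init, times) {
  stopifnot(inherits(spec, "process_spec"), inherits(init, "gaussian_state"))
  if (init$beta <= 0) stop("ou_propagate: beta0 must be > 0")
  if (any(times < 0)) stop("ou_propagate: times must be >= 0")
  x0 <- init$mean
  s20 <- init$sigma2
  if (spec_is_const(spec)) {
    g <- spec$gamma_const
    D <- spec$D_const
    decay <- exp(-g * times)
    s2 <- decay^2 * s20 + D * (1 - decay^2) / g
    if (!is.na(spec$ramp_u)) {
      u <- spec$ramp_u
      y <- x0 * decay + u * times - (u / g) * (1 - decay)
    } else if (!is.na(spec$v_const)) {
      y <- spec$v_const + (x0 - spec$v_const) * decay
    } else {
      y <- vapply(seq_along(times), function(k) {
        t <- times[k]
        if (t == 0) return(x0)
        conv <- stats::integrate(function(s) exp(-g * (t - s)) * g * spec$v(s),
                                 0, t, rel.tol = 1e-10, abs.tol = 1e-12)$value
        x0 * decay[k] + conv
      }, numeric(1))
    }
  } else {
    G <- function(t) {
      if (t == 0) return(0)
      stats::integrate(spec$gamma, 0, t, rel.tol = 1e-10, abs.tol = 1e-12)$value
    }
    y <- numeric(length(times))
    s2 <- numeric(length(times))
    for (k in seq_along(times)) {
      t <- times[k]
      if (t == 0) {
        y[k] <- x0
        s2[k] <- s20
        next
      }
      Gt <- G(t)
      Gs <- Vectorize(G)
      y[k] <- x0 * exp(-Gt) +
        stats::integrate(function(s) exp(-(Gt - Gs(s))) * spec$gamma(s) * spec$v(s),
                         0, t, rel.tol = 1e-10, abs.tol = 1e-12)$value
      s2[k] <- exp(-2 * Gt) * s20 +
        stats::integrate(function(s) exp(-2 * (Gt - Gs(s))) * 2 * spec$D(s),
                         0, t, rel.tol = 1e-10, abs.tol = 1e-12)$value
    }
  }
  beta <- 1 / (2 * s2)
  gamma_t <- spec$gamma(times)
  D_t <- spec$D(times)
  ydot <- -gamma_t * (y - spec$v(times))
  betadot <- 2 * gamma_t * beta - 4 * D_t * beta^2
  sigma <- sqrt(s2)
  out <- data.frame(t = times, y = y, beta = beta, sigma = sigma,
                    sigma2 = s2, ydot = ydot, betadot = betadot,
                    sigmadot = -betadot * (2 * beta)^(-1.5))
  class(out) <- c("ou_path", "data.frame")
  out
}

#' Gaussian states of an O-U path
#'
#' @param path An `ou_path` data frame from [ou_propagate()] or
#'   [geodesic_path()].
#' @param k Row indices (default all).
#' @return A list of [gaussian_state()] objects.
#' @export
ou_path_states <- function(path, k = seq_len(nrow(path))) {
  lapply(k, function(i) gaussian_state(path$y[i], path$beta[i], t = path$t[i]))
}

#' Sample an O-U path as a PDF trajectory on a grid
#'
#' @param path An `ou_path` data frame.
#' @param grid A [grid1d()] covering every state to six standard deviations.
#' @return A [pdf_trajectory()].
#' @export
ou_path_to_trajectory <- function(path, grid) {
  P <- vapply(seq_len(nrow(path)), function(k) {
    gaussian_to_grid(gaussian_state(path$y[k], path$beta[k]), grid)$p
  }, numeric(grid$n))
  pdf_trajectory(grid, path$t, P)
}

#' Probability current on a grid
#'
#' The Fokker-Planck current `J = f p - D dp/dx`. The space derivative uses
#' fourth-order central differences in the interior (so detailed-balance
#' residuals are limited by the grid only at `O(dx^4)`), falling back to
#' second-order stencils at the outermost nodes where the density is
#' negligible anyway.
#'
#' @param pdf A [grid_pdf()].
#' @param f Drift values at the grid nodes (vector) or a function of x.
#' @param D Noise amplitude (scalar).
#' @return The current at the grid nodes.
#' @export
probability_current <- function(pdf, f, D) {
  stopifnot(inherits(pdf, "grid_pdf"))
  fv <- if (is.function(f)) f(pdf$grid$x) else f
  n <- pdf$grid$n
  dx <- pdf$grid$dx
  p <- pdf$p
  dp <- numeric(n)
  i <- 3:(n - 2)
  dp[i] <- (-p[i + 2] + 8 * p[i + 1] - 8 * p[i - 1] + p[i - 2]) / (12 * dx)
  dp[2] <- (p[3] - p[1]) / (2 * dx)
  dp[n - 1] <- (p[n] - p[n - 2]) / (2 * dx)
  dp[1] <- (-3 * p[1] + 4 * p[2] - p[3]) / (2 * dx)
  dp[n] <- (3 * p[n] - 4 * p[n - 1] + p[n - 2]) / (2 * dx)
  fv * p - D * dp
}

# Chang-Cooper face weights: delta in [0,1] multiplying the left node in the
# advective face value, exponentially fitted so the discrete stationary state
# is exact and the scheme is positivity-preserving.
cc_delta <- function(w) {
  d <- numeric(length(w))
  big <- abs(w) > 1e-8
  d[big] <- 1 / (1 - exp(-w[big])) - 1 / w[big]
  d[!big] <- 0.5 + w[!big] / 12  # series expansion near w = 0
  d[w > 500] <- 1
  d[w < -500] <- 0
  d
}

# generator matrix (n x n, tridiagonal, columns sum to zero) of the
# conservative finite-volume discretization of dp/dt = -d/dx (f p) + D d2p/dx2
# with zero-flux boundaries
fp_generator <- function(grid, fface, D) {
  n <- grid$n
  dx <- grid$dx
  if (D > 0) {
    w <- fface * dx / D
    delta <- cc_delta(w)
    a <- fface * delta + D / dx       # coefficient of p_i in face flux J_i
    b <- fface * (1 - delta) - D / dx # coefficient of p_{i+1}
  } else {
    delta <- ifelse(fface > 0, 1, 0)
    a <- fface * delta
    b <- fface * (1 - delta)
  }
  # row i: dp_i/dt = (J_{i-1} - J_i)/dx, J_0 = J_n = 0
  diag_main <- c(-a[1], b[seq_len(n - 2)] - a[2:(n - 1)], b[n - 1]) / dx
  Matrix::bandSparse(n, n, k = -1:1,
                     diagonals = list(a / dx, diag_main, -b / dx))
}

#' Conservative Fokker-Planck solver
#'
#' Solves `dp/dt = -d/dx (f p) + D d^2p/dx^2` by a conservative finite-volume
#' discretization with exponentially fitted (Chang-Cooper) face weights and
#' Crank-Nicolson time stepping. Zero-flux (reflecting) boundaries conserve
#' the discrete mass exactly; the domain should be wide enough that the
#' boundary density stays below `1e-12`, which makes the boundary choice
#' immaterial.
#'
#' @param spec A [process_spec()], or `NULL` when `drift` is given.
#' @param p0 Initial [grid_pdf()].
#' @param times Output times (increasing, starting at the initial time).
#' @param dt Internal time step (default `1e-3`); output times must fall on
#'   the internal step grid.
#' @param drift Optional general drift `function(x, t)` overriding the spec.
#' @param D Noise amplitude (scalar or function of t); taken from the spec
#'   when omitted.
#' @return An object of class `fp_solution`: a list with the
#'   [pdf_trajectory()] `trajectory`, the per-snapshot current matrix `J`,
#'   and a `mass` conservation log (one entry per internal step).
#' @export
fp_solve <- function(spec, p0, times, dt = 1e-3, drift = NULL, D = NULL) {
  stopifnot(inherits(p0, "grid_pdf"))
  grid <- p0$grid
  f_fn <- if (!is.null(drift)) drift
          else if (inherits(spec, "process_spec")) spec$f
          else stop("fp_solve: need a process_spec or a drift function")
  D_fn <- if (is.null(D)) {
    if (!inherits(spec, "process_spec")) stop("fp_solve: need D")
    spec$D
  } else if (is.function(D)) D else function(t) rep(D, length(t))
  if (max(p0$p[c(1L, grid$n)]) > 1e-12)
    warning("fp_solve: boundary density exceeds 1e-12; widen the grid")
  t0 <- times[1]
  tF <- times[length(times)]
  n_steps <- round((tF - t0) / dt)
  if (n_steps < 1) stop("fp_solve: no steps between first and last time")
  step_times <- t0 + dt * (0:n_steps)
  snap_idx <- vapply(times, function(t) {
    k <- which.min(abs(step_times - t))
    if (abs(step_times[k] - t) > 1e-9 * max(1, abs(t)))
      stop(sprintf("fp_solve: output time %g does not fall on the dt = %g step grid", t, dt))
    k
  }, integer(1))
  xf <- grid$x[-grid$n] + grid$dx / 2  # face midpoints
  autonomous <- is.function(drift) == FALSE &&
    inherits(spec, "process_spec") &&
    !is.na(spec$gamma_const) && !is.na(spec$D_const) && !is.na(spec$v_const)
  Agen <- function(t) fp_generator(grid, f_fn(xf, t), D_fn(t)[1])
  I <- Matrix::Diagonal(grid$n)
  p <- p0$p
  w <- trapz_weights(grid)
  mass0 <- sum(w * p)
  P <- matrix(0, grid$n, length(times))
  mass_log <- numeric(n_steps)
  clip_log <- 0
  if (autonomous) {
    A <- Agen(t0)
    lhs_fac <- Matrix::lu(I - (dt / 2) * A)
    rhs_M <- I + (dt / 2) * A
  }
  out_k <- 1L
  if (snap_idx[out_k] == 1L) {
    P[, out_k] <- p
    out_k <- out_k + 1L
  }
  for (s in seq_len(n_steps)) {
    if (autonomous) {
      rhs <- rhs_M %*% p
      p <- as.numeric(Matrix::solve(lhs_fac, rhs))
    } else {
      A0 <- Agen(step_times[s])
      A1 <- Agen(step_times[s + 1])
      rhs <- (I + (dt / 2) * A0) %*% p
      p <- as.numeric(Matrix::solve(I - (dt / 2) * A1, rhs))
    }
    if (anyNA(p) || !all(is.finite(p)))
      stop(sprintf("fp_solve: step dt = %g failed (non-finite density at t = %g); reduce dt",
                   dt, step_times[s + 1]))
    neg <- min(p)
    if (neg < 0) {
      if (neg < -1e-12)
        clip_log <- max(clip_log, -neg)
      p <- pmax(p, 0)
    }
    mass_log[s] <- sum(w * p)
    if (abs(mass_log[s] - mass0) > 1e-8)
      stop(sprintf("fp_solve: mass drifted by %g at t = %g",
                   mass_log[s] - mass0, step_times[s + 1]))
    while (out_k <= length(times) && snap_idx[out_k] == s + 1L) {
      P[, out_k] <- p
      out_k <- out_k + 1L
    }
  }
  traj <- pdf_trajectory(grid, times, P, renormalize = TRUE)
  J <- vapply(seq_along(times), function(k) {
    probability_current(traj_snapshot(traj, k), f_fn(grid$x, times[k]),
                        D_fn(times[k])[1])
  }, numeric(grid$n))
  structure(list(trajectory = traj, J = J, mass = mass_log,
                 max_negative_clipped = clip_log, dt = dt),
            class = "fp_solution")
}

#' @export
print.fp_solution <- function(x, ...) {
  cat(sprintf("fp_solution: %d snapshots, dt = %g, max |mass - 1| = %.3g, max clipped negativity = %.3g\n",
              length(x$trajectory$times), x$dt,
              max(abs(x$mass - 1)), x$max_negative_clipped))
  invisible(x)
}

#' Euler-Maruyama Langevin simulator
#'
#' Simulates an ensemble of paths of `dx = f(x, t) dt + sqrt(2 D dt) N(0,1)`
#' and bins them into empirical densities on an analysis grid (histogram with
#' bins centered on the grid nodes). Reproducible for a fixed seed.
#'
#' @param spec A [process_spec()].
#' @param n_paths Number of paths (at least 100).
#' @param x0_sampler Function `n -> n` initial positions, or a single numeric
#'   (all paths start there), or a [gaussian_state()] to sample from.
#' @param t_grid Output times (increasing, starting at 0).
#' @param seed RNG seed.
#' @param grid Optional [grid1d()] for the empirical densities.
#' @param dt Step size; default `min(1e-3, 0.01 / max gamma)`.
#' @return A list with the path matrix `paths` (`n_paths` x `length(t_grid)`),
#'   a `moments` data frame (`t`, `mean`, `var`, `se_mean`), and, when a grid
#'   is supplied, the empirical [pdf_trajectory()] `trajectory`.
#' @export
langevin_simulate <- function(spec, n_paths, x0_sampler, t_grid, seed = 1,
                              grid = NULL, dt = NULL) {
  stopifnot(inherits(spec, "process_spec"))
  if (n_paths < 100) stop("langevin_simulate: n_paths must be >= 100")
  if (is.null(dt)) {
    gmax <- max(spec$gamma(seq(min(t_grid), max(t_grid), length.out = 101)))
    dt <- min(1e-3, 0.01 / gmax)
  }
  sampler <- if (is.function(x0_sampler)) x0_sampler
    else if (inherits(x0_sampler, "gaussian_state"))
      function(n) stats::rnorm(n, x0_sampler$mean, x0_sampler$sigma)
    else function(n) rep(as.numeric(x0_sampler), n)
  set.seed(seed)
  x <- sampler(n_paths)
  out <- matrix(0, n_paths, length(t_grid))
  t_now <- t_grid[1]
  out[, 1] <- x
  for (k in 2:length(t_grid)) {
    n_sub <- max(1L, round((t_grid[k] - t_now) / dt))
    h <- (t_grid[k] - t_now) / n_sub
    for (s in seq_len(n_sub)) {
      Dval <- spec$D(t_now)[1]
      noise <- if (Dval > 0) stats::rnorm(n_paths, 0, sqrt(2 * Dval * h)) else 0
      x <- x + spec$f(x, t_now) * h + noise
      t_now <- t_now + h
    }
    out[, k] <- x
  }
  mom <- data.frame(t = t_grid,
                    mean = colMeans(out),
                    var = apply(out, 2L, stats::var))
  mom$se_mean <- sqrt(mom$var / n_paths)
  res <- list(paths = out, moments = mom, dt = dt, seed = seed)
  if (!is.null(grid)) {
    breaks <- c(grid$x - grid$dx / 2, grid$x[grid$n] + grid$dx / 2)
    P <- vapply(seq_along(t_grid), function(k) {
      xk <- pmin(pmax(out[, k], breaks[1]), breaks[length(breaks)])
      h <- graphics::hist(xk, breaks = breaks, plot = FALSE)
      h$counts / (n_paths * grid$dx)
    }, numeric(grid$n))
    res$trajectory <- pdf_trajectory(grid, t_grid, P, renormalize = TRUE)
  }
  res
}

#' Two components coupled by dichotomous (telegraph) noise
#'
#' Evolves two half-mass densities `P1`, `P2` under
#' `dP1/dt = -d/dx (f1 P1) + D d^2 P1/dx^2 + r (P2 - P1)` and symmetrically
#' for `P2`. With identical drifts `f1 = f2 = -gamma x` the total
#' `P = P1 + P2` solves the plain O-U Fokker-Planck equation, while each
#' component is dragged by the exchange with the other. Symmetric switching
#' conserves each component's mass at 1/2.
#'
#' @param spec A [process_spec()] providing the default drift and `D`.
#' @param r Switching rate, `r >= 0`.
#' @param init1,init2 Initial component densities on one grid, each of mass
#'   1/2 (within `1e-8`). Supply as node-value vectors.
#' @param grid The shared [grid1d()].
#' @param times Output times.
#' @param dt Internal step (default `1e-2`).
#' @param f1,f2 Optional per-component drifts `function(x, t)`; both default
#'   to the spec's drift.
#' @return A list with matrices `P1`, `P2` (columns are snapshots of the
#'   half-mass components), the total [pdf_trajectory()] `total`, normalized
#'   per-component trajectories `comp1`, `comp2` (densities `2 P_i`), and
#'   mass logs.
#' @export
dichotomous_solve <- function(spec, r, init1, init2, grid, times, dt = 1e-2,
                              f1 = NULL, f2 = NULL) {
  stopifnot(inherits(grid, "grid1d"), r >= 0,
            length(init1) == grid$n, length(init2) == grid$n)
  w <- trapz_weights(grid)
  m1 <- sum(w * init1)
  m2 <- sum(w * init2)
  if (abs(m1 - 0.5) > 1e-8 || abs(m2 - 0.5) > 1e-8)
    stop("dichotomous_solve: each component must carry mass 1/2")
  f1 <- if (is.null(f1)) spec$f else f1
  f2 <- if (is.null(f2)) spec$f else f2
  Dv <- spec$D(0)[1]
  t0 <- times[1]
  tF <- times[length(times)]
  n_steps <- round((tF - t0) / dt)
  step_times <- t0 + dt * (0:n_steps)
  snap_idx <- vapply(times, function(t) {
    k <- which.min(abs(step_times - t))
    if (abs(step_times[k] - t) > 1e-9 * max(1, abs(t)))
      stop("dichotomous_solve: output times must fall on the step grid")
    k
  }, integer(1))
  xf <- grid$x[-grid$n] + grid$dx / 2
  n <- grid$n
  block <- function(t) {
    A1 <- fp_generator(grid, f1(xf, t), Dv)
    A2 <- fp_generator(grid, f2(xf, t), Dv)
    rI <- r * Matrix::Diagonal(n)
    rbind(cbind(A1 - rI, rI), cbind(rI, A2 - rI))
  }
  I2 <- Matrix::Diagonal(2L * n)
  # autonomous when the drifts do not depend on t
  A <- block(t0)
  lhs_fac <- Matrix::lu(I2 - (dt / 2) * A)
  rhs_M <- I2 + (dt / 2) * A
  p <- c(init1, init2)
  P1 <- matrix(0, n, length(times))
  P2 <- matrix(0, n, length(times))
  mass1 <- numeric(n_steps)
  mass2 <- numeric(n_steps)
  out_k <- 1L
  if (snap_idx[out_k] == 1L) {
    P1[, 1] <- p[1:n]; P2[, 1] <- p[(n + 1):(2 * n)]
    out_k <- out_k + 1L
  }
  for (s in seq_len(n_steps)) {
    p <- as.numeric(Matrix::solve(lhs_fac, rhs_M %*% p))
    p <- pmax(p, 0)
    mass1[s] <- sum(w * p[1:n])
    mass2[s] <- sum(w * p[(n + 1):(2 * n)])
    while (out_k <= length(times) && snap_idx[out_k] == s + 1L) {
      P1[, out_k] <- p[1:n]; P2[, out_k] <- p[(n + 1):(2 * n)]
      out_k <- out_k + 1L
    }
  }
  total <- pdf_trajectory(grid, times, P1 + P2, renormalize = TRUE)
  comp1 <- pdf_trajectory(grid, times, 2 * P1, renormalize = TRUE)
  comp2 <- pdf_trajectory(grid, times, 2 * P2, renormalize = TRUE)
  list(P1 = P1, P2 = P2, total = total, comp1 = comp1, comp2 = comp2,
       mass1 = mass1, mass2 = mass2, times = times)
}
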