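#' PDF trajectory on a shared grid
#'
#' A time-ordered sequence of density snapshots on one grid, the input of
#' the numeric information-rate estimator and of the thermodynamic
#' functionals. Times must be strictly increasing and (for time
#' differentiation) uniform within 1%.
#'
#' @param grid A [grid1d()].
#' @param times Strictly increasing time stamps (at least 3).
#' @param P Matrix of densities, one column per time, `grid$n` rows.
#' @param renormalize Renormalize every column by its trapezoid integral.
#'
#' @return An object of class `pdf_trajectory` with fields `grid`, `times`,
#'   `P`.
#' @export
pdf_trajectory <- function(grid, times, P, renormalize = FALSE) {
  stopifnot(inherits(grid, "grid1d"), is.matrix(P),
            nrow(P) == grid$n, ncol(P) == length(times))
  if (length(times) < 3L) stop("pdf_trajectory: need at least 3 snapshots")
  if (any(diff(times) <= 0)) stop("pdf_trajectory: times must be increasing")
  if (min(P) < -1e-12) stop("pdf_trajectory: negative densities")
  P[P < 0] <- 0
  w <- trapz_weights(grid)
  mass <- as.numeric(crossprod(w, P))
  if (renormalize) {
    P <- sweep(P, 2L, mass, "/")
  } else if (max(abs(mass - 1)) > 1e-6) {
    stop("pdf_trajectory: snapshots not normalized (worst |mass-1| = ",
         format(max(abs(mass - 1))), ")")
  }
  structure(list(grid = grid, times = times, P = P),
            class = "pdf_trajectory")
}

#' @export
print.pdf_trajectory <- function(x, ...) {
  cat(sprintf("pdf_trajectory: %d snapshots on [%g, %g] (%d nodes), t in [%g, %g]\n",
              length(x$times), x$grid$x_min, x$grid$x_max, x$grid$n,
              min(x$times), max(x$times)))
  invisible(x)
}

#' Extract one snapshot of a trajectory
#'
#' @param traj A [pdf_trajectory()].
#' @param k Snapshot index.
#' @return The k-th snapshot as a (renormalized) [grid_pdf()].
#' @export
traj_snapshot <- function(traj, k) {
  grid_pdf(traj$grid, traj$P[, k], t = traj$times[k], renormalize = TRUE)
}

check_uniform_dt <- function(times, tol = 0.01) {
  dt <- diff(times)
  if ((max(dt) - min(dt)) > tol * mean(dt))
    stop("time step is non-uniform beyond 1%; the differentiation stencils assume a uniform step")
  mean(dt)
}

# second-order time derivative of the columns of a matrix (central interior,
# one-sided second-order at the ends); dt uniform
time_derivative_matrix <- function(M, dt) {
  n <- ncol(M)
  dM <- matrix(0, nrow(M), n)
  dM[, 2:(n - 1)] <- (M[, 3:n] - M[, 1:(n - 2)]) / (2 * dt)
  dM[, 1] <- (-3 * M[, 1] + 4 * M[, 2] - M[, 3]) / (2 * dt)
  dM[, n] <- (3 * M[, n] - 4 * M[, n - 1] + M[, n - 2]) / (2 * dt)
  dM
}

# same stencils for a vector-valued time series
time_derivative_series <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * dt)
  d[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * dt)
  d
}

#' Information-rate series
#'
#' Container for the information rate `Gamma(t)` (units 1/time), the squared
#' rate `E = Gamma^2`, the cumulative information length
#' `L(t) = integral_0^t Gamma` (dimensionless, non-decreasing, `L(t0) = 0`)
#' and the characteristic time `tau = 1/Gamma`.
#'
#' @param times Time stamps.
#' @param Gamma Non-negative rate values.
#' @return A data frame of class `info_series` with columns `t`, `Gamma`,
#'   `E`, `L`, `tau`.
#' @export
info_series <- function(times, Gamma) {
  stopifnot(length(times) == length(Gamma))
  if (any(Gamma < 0)) stop("info_series: Gamma must be non-negative")
  L <- cumtrapz(times, Gamma)
  out <- data.frame(t = times, Gamma = Gamma, E = Gamma^2, L = L,
                    tau = ifelse(Gamma > 0, 1 / Gamma, Inf))
  class(out) <- c("info_series", "data.frame")
  out
}

#' Numeric information rate of a PDF trajectory
#'
#' Estimates `Gamma(t)^2 = 4 integral (dq/dt)^2 dx` with `q = sqrt(p)` from
#' sampled snapshots. The amplitude form is used (rather than
#' `(dp/dt)^2 / p`) because it stays finite where the density vanishes.
#' Time derivatives use central differences at interior times and
#' second-order one-sided stencils at the ends, so the estimator is
#' second-order accurate in the snapshot spacing.
#'
#' @param traj A [pdf_trajectory()] with a uniform time step (within 1%).
#' @return An [info_series()].
#' @export
information_rate_numeric <- function(traj) {
  stopifnot(inherits(traj, "pdf_trajectory"))
  dt <- check_uniform_dt(traj$times)
  dq <- time_derivative_matrix(sqrt(traj$P), dt)
  w <- trapz_weights(traj$grid)
  E <- 4 * as.numeric(crossprod(w, dq^2))
  info_series(traj$times, sqrt(pmax(E, 0)))
}

#' Information rate of a Gaussian trajectory (closed form)
#'
#' For a Gaussian density with mean `y(t)` and inverse temperature `beta(t)`
#' the information rate has the closed form
#' `Gamma^2 = 2 beta ydot^2 + betadot^2 / (2 beta^2)
#'          = (2 sigmadot^2 + ydot^2) / sigma^2`.
#' Both algebraic forms are evaluated and cross-checked (they must agree to
#' `1e-10` relative); the first is returned.
#'
#' @param times Time stamps.
#' @param y,beta Mean and inverse-temperature paths: numeric vectors on
#'   `times`, or functions of time.
#' @param ydot,betadot Optional exact derivatives (vectors or functions).
#'   When omitted they are obtained by central differences (step `1e-6` for
#'   functions, the time grid for vectors).
#' @return An [info_series()].
#' @export
#' @examples
#' tt <- seq(0, 3, by = 0.01)
#' s <- information_rate_gaussian(tt, y = function(t) t,
#'                                beta = function(t) rep(2, length(t)),
#'                                ydot = function(t) rep(1, length(t)),
#'                                betadot = function(t) rep(0, length(t)))
#' head(s$Gamma)  # |ydot|/sigma = 2
information_rate_gaussian <- function(times, y, beta, ydot = NULL,
                                      betadot = NULL) {
  eval_path <- function(f) if (is.function(f)) f(times) else f
  num_deriv <- function(f, v) {
    if (!is.null(f)) return(eval_path(f))
    if (is.function(v)) {
      h <- 1e-6
      (v(times + h) - v(times - h)) / (2 * h)
    } else {
      time_derivative_series(v, check_uniform_dt(times))
    }
  }
  yv <- eval_path(y)
  bv <- eval_path(beta)
  if (any(bv <= 0)) stop("information_rate_gaussian: beta must be positive")
  yd <- num_deriv(ydot, y)
  bd <- num_deriv(betadot, beta)
  E1 <- 2 * bv * yd^2 + bd^2 / (2 * bv^2)
  sigma <- 1 / sqrt(2 * bv)
  sigmadot <- -bd * (2 * bv)^(-1.5)
  E2 <- (2 * sigmadot^2 + yd^2) / sigma^2
  rel <- abs(E1 - E2) / pmax(E1, E2, 1e-30)
  if (max(rel) > 1e-10)
    stop("information_rate_gaussian: the two closed forms disagree")
  info_series(times, sqrt(E1))
}

#' Information length from a rate series
#'
#' Cumulative trapezoid integral `L(t) = integral_{t0}^{t} Gamma`, starting
#' at 0 and non-decreasing.
#'
#' @param series An [info_series()].
#' @return The same series with the `L` column (re)computed.
#' @export
information_length <- function(series) {
  stopifnot(inherits(series, "info_series"))
  series$L <- cumtrapz(series$t, series$Gamma)
  series
}

#' Small-dt equivalence of relative entropy and information rate
#'
#' Checks the defining limit `2 K[p(t+dt) | p(t)] / dt^2 -> Gamma(t)^2` as
#' `dt -> 0`, together with the leading-order symmetry of the divergence
#' (`K` forward and backward agree to `O(dt^2)`). The trajectory must be
#' re-evaluable at arbitrary times, so it is supplied as a function.
#'
#' @param pdf_at Function mapping a time to a [grid_pdf()] (all on one grid).
#' @param t Base time.
#' @param dt_list Decreasing vector of time offsets.
#' @param gamma_sq Reference `Gamma(t)^2` (e.g. a closed form). If `NULL` it
#'   is estimated from the smallest offset by a central difference of the
#'   amplitude.
#' @return A list with a per-`dt` data frame (`dt`, `ratio`, `asymmetry`),
#'   the fitted convergence order of `|ratio - 1|` in `dt`, and `gamma_sq`.
#' @export
small_dt_equivalence <- function(pdf_at, t, dt_list, gamma_sq = NULL) {
  dt_list <- sort(dt_list, decreasing = TRUE)
  p0 <- pdf_at(t)
  if (is.null(gamma_sq)) {
    h <- min(dt_list) / 10
    dq <- (pdf_at(t + h)$q - pdf_at(t - h)$q) / (2 * h)
    gamma_sq <- 4 * grid_trapz(p0$grid, dq^2)
  }
  rows <- lapply(dt_list, function(dt) {
    p1 <- pdf_at(t + dt)
    kf <- kl_divergence(p1, p0)
    kb <- kl_divergence(p0, p1)
    data.frame(dt = dt, K_forward = kf, K_backward = kb,
               ratio = if (gamma_sq > 0) 2 * kf / (dt^2 * gamma_sq) else NA_real_,
               asymmetry = if (kf > 0) abs(kf - kb) / kf else 0)
  })
  tab <- do.call(rbind, rows)
  order_fit <- NA_real_
  if (gamma_sq > 0 && all(abs(tab$ratio - 1) > 0)) {
    order_fit <- unname(stats::coef(
      stats::lm(log(abs(tab$ratio - 1)) ~ log(tab$dt)))[2])
  }
  list(table = tab, order = order_fit, gamma_sq = gamma_sq)
}

#' Parametric (Fisher-metric) information rate and its bounds
#'
#' For a parametrized family `p(x; lambda(t))` the information rate can be
#' written as `Gamma^2 = lambdadot' g lambdadot` with `g` the Fisher metric.
#' The Cramer-Rao relation bounds the fluctuation-normalized speed of each
#' parameter by `Gamma`: `sum_a lambdadot_a^2 / <dlambda_a^2> <= Gamma^2`
#' and, per parameter, `|lambdadot_a| / sqrt(<dlambda_a^2>) <= Gamma`.
#'
#' For the Gaussian family (`lambda = (y, beta)`) the metric is built in:
#' `g_yy = 2 beta`, `g_bb = 1/(2 beta^2)`, `g_yb = 0`, and the parameter
#' fluctuations are the Cramer-Rao-saturating `C = diag(1/g)`.
#'
#' @param times Time stamps.
#' @param lambda Matrix of parameter paths (one column per parameter).
#' @param metric `"gaussian"` (default; `lambda` columns are `y`, `beta`) or
#'   a function `lambda_row -> metric matrix`.
#' @param covariance Optional function `lambda_row -> covariance matrix` of
#'   the parameter fluctuations; defaults to `diag(1/diag(g))`.
#' @param lambdadot Optional matrix of exact parameter velocities.
#' @return A list with the `info_series` of `Gamma_param`, a per-time data
#'   frame of bound margins, and the flags `bound_sum_ok`, `bound_single_ok`.
#' @export
parametric_rate_and_bounds <- function(times, lambda, metric = "gaussian",
                                       covariance = NULL, lambdadot = NULL) {
  stopifnot(is.matrix(lambda), nrow(lambda) == length(times))
  if (is.null(lambdadot)) {
    dt <- check_uniform_dt(times)
    lambdadot <- apply(lambda, 2L, time_derivative_series, dt = dt)
  }
  gfun <- if (identical(metric, "gaussian")) {
    function(lam) diag(c(2 * lam[2], 1 / (2 * lam[2]^2)), 2L)
  } else metric
  cfun <- if (is.null(covariance)) {
    function(lam) {
      g <- gfun(lam)
      diag(1 / diag(g), nrow(g))
    }
  } else covariance
  n <- length(times)
  E <- numeric(n)
  lhs_sum <- numeric(n)
  lhs_single <- matrix(0, n, ncol(lambda))
  for (k in seq_len(n)) {
    g <- gfun(lambda[k, ])
    ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-12 * max(abs(ev)))
      stop("parametric_rate_and_bounds: Fisher metric not positive semi-definite")
    v <- lambdadot[k, ]
    E[k] <- as.numeric(v %*% g %*% v)
    C <- cfun(lambda[k, ])
    lhs_sum[k] <- sum(v^2 / diag(C))
    lhs_single[k, ] <- abs(v) / sqrt(diag(C))
  }
  Gamma <- sqrt(pmax(E, 0))
  tol <- 1e-10 * pmax(E, 1)
  list(series = info_series(times, Gamma),
       bounds = data.frame(t = times, lhs_sum = lhs_sum, E = E,
                           margin_sum = E - lhs_sum),
       lhs_single = lhs_single,
       bound_sum_ok = all(lhs_sum <= E + tol),
       bound_single_ok = all(lhs_single <= Gamma + sqrt(tol)))
}

#' Coordinate invariance of the information rate
#'
#' `Gamma` and `L` are invariant under strictly monotone, time-independent
#' transformations `y = h(x)`: the transformed density
#' `p_y(y, t) = p_x(x, t) / |h'(x)|` carries the same information content.
#' This routine computes `Gamma` in the transformed coordinate (by trapezoid
#' quadrature on the non-uniform image nodes `h(x_i)`) and compares it with
#' the untransformed value.
#'
#' @param traj A [pdf_trajectory()].
#' @param h Strictly monotone transformation (function of x).
#' @param hprime Optional derivative of `h`; numeric central difference
#'   (step `1e-6`) if omitted.
#' @param tol Relative agreement tolerance for the report flag (default 1%).
#' @return A list with the two rate series, the maximal relative differences
#'   of `Gamma` and of the final `L`, and the flag `ok`.
#' @export
invariance_check <- function(traj, h, hprime = NULL, tol = 0.01) {
  stopifnot(inherits(traj, "pdf_trajectory"))
  x <- traj$grid$x
  yx <- h(x)
  dy <- diff(yx)
  if (all(dy < 0)) {
    # orientation flip: work with -h, same densities
    yx <- -yx
    dy <- -dy
    hp <- if (is.null(hprime)) NULL else function(z) -hprime(z)
  } else hp <- hprime
  if (any(dy <= 0))
    stop("invariance_check: h must be strictly monotone on the grid")
  jac <- if (is.null(hp)) {
    hh <- 1e-6 * pmax(1, abs(x))
    abs((h(x + hh) - h(x - hh)) / (2 * hh))
  } else abs(hp(x))
  dt <- check_uniform_dt(traj$times)
  # amplitude of the transformed density at the image nodes
  Qy <- sqrt(sweep(traj$P, 1L, jac, "/"))
  dQy <- time_derivative_matrix(Qy, dt)
  E_y <- 4 * apply(dQy^2, 2L, function(col) trapz_nonuniform(yx, col))
  series_y <- info_series(traj$times, sqrt(pmax(E_y, 0)))
  series_x <- information_rate_numeric(traj)
  live <- series_x$Gamma > 1e-8 * max(series_x$Gamma)
  rel_gamma <- max(abs(series_y$Gamma[live] - series_x$Gamma[live]) /
                     series_x$Gamma[live])
  Lx <- series_x$L[length(series_x$L)]
  Ly <- series_y$L[length(series_y$L)]
  rel_L <- abs(Ly - Lx) / max(Lx, 1e-300)
  list(series_x = series_x, series_y = series_y,
       rel_gamma = rel_gamma, rel_L = rel_L,
       ok = rel_gamma <= tol && rel_L <= tol)
}
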