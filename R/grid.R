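#' Uniform one-dimensional grid
#'
#' Constructs the uniform grid on which all densities are sampled. Integrals
#' over the grid use the composite trapezoid rule, which is second-order
#' accurate for the smooth integrands arising here and makes normalization
#' and invariance checks exactly reproducible.
#'
#' @param x_min,x_max Endpoints of the support window (`x_max > x_min`).
#' @param n_points Number of nodes (at least 16).
#'
#' @return An object of class `grid1d` with fields `x_min`, `x_max`, `n`,
#'   the node vector `x` and the spacing `dx`.
#' @export
#' @examples
#' g <- grid1d(-6, 6, 256)
#' g$dx
grid1d <- function(x_min, x_max, n_points) {
  if (!(is.numeric(x_min) && is.numeric(x_max) && x_max > x_min))
    stop("grid1d: need x_max > x_min")
  n_points <- as.integer(n_points)
  if (n_points < 16L) stop("grid1d: n_points must be >= 16")
  x <- seq(x_min, x_max, length.out = n_points)
  structure(list(x_min = x_min, x_max = x_max, n = n_points,
                 x = x, dx = x[2L] - x[1L]),
            class = "grid1d")
}

#' @export
print.grid1d <- function(x, ...) {
  cat(sprintf("grid1d: [%g, %g], %d nodes, dx = %g\n",
              x$x_min, x$x_max, x$n, x$dx))
  invisible(x)
}

# trapezoid weights on a uniform grid
trapz_weights <- function(grid) {
  w <- rep(grid$dx, grid$n)
  w[c(1L, grid$n)] <- grid$dx / 2
  w
}

# trapezoid integral of node values y over the grid
grid_trapz <- function(grid, y) sum(trapz_weights(grid) * y)

# trapezoid integral on an arbitrary (possibly non-uniform) abscissa
trapz_nonuniform <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# cumulative trapezoid integral, first element 0
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1L] - x[-n]) * (y[-1L] + y[-n]) / 2))
}

same_grid <- function(g1, g2) {
  g1$n == g2$n && isTRUE(all.equal(g1$x_min, g2$x_min, tolerance = 1e-12)) &&
    isTRUE(all.equal(g1$x_max, g2$x_max, tolerance = 1e-12))
}

#' Grid-sampled probability density
#'
#' Wraps a non-negative density sampled on a [grid1d()]. The trapezoid
#' integral of the density must equal 1 within `1e-8` unless
#' `renormalize = TRUE`, in which case the sampled values are rescaled.
#'
#' @param grid A [grid1d()].
#' @param p Non-negative density values at the grid nodes.
#' @param t Optional time tag.
#' @param renormalize Rescale `p` so the trapezoid integral is exactly 1.
#' @param lp Optional log-density at the nodes (used by the divergences so
#'   that far-tail values below the double-precision underflow threshold
#'   keep a meaningful logarithm; defaults to `log(p)`).
#'
#' @return An object of class `grid_pdf` with fields `grid`, `p`, the
#'   amplitude `q = sqrt(p)`, the log-density `lp` and `t`.
#' @export
grid_pdf <- function(grid, p, t = NA_real_, renormalize = FALSE, lp = NULL) {
  stopifnot(inherits(grid, "grid1d"), length(p) == grid$n)
  if (any(p < 0)) {
    if (min(p) < -1e-12) stop("grid_pdf: negative density values")
    p <- pmax(p, 0)
  }
  mass <- grid_trapz(grid, p)
  if (renormalize) {
    if (mass <= 0) stop("grid_pdf: cannot normalize zero density")
    p <- p / mass
    if (!is.null(lp)) lp <- lp - log(mass)
  } else if (abs(mass - 1) > 1e-8) {
    stop(sprintf("grid_pdf: density integrates to %.10g, not 1", mass))
  }
  if (is.null(lp)) lp <- log(p)
  structure(list(grid = grid, p = p, q = sqrt(p), lp = lp, t = t),
            class = "grid_pdf")
}

#' @export
print.grid_pdf <- function(x, ...) {
  m <- moments(x)
  cat(sprintf("grid_pdf on [%g, %g] (%d nodes)%s: mean %.6g, variance %.6g\n",
              x$grid$x_min, x$grid$x_max, x$grid$n,
              if (is.na(x$t)) "" else sprintf(" at t = %g", x$t),
              m$mean, m$variance))
  invisible(x)
}

#' Gaussian state (mean, inverse temperature)
#'
#' Carrier of the closed-form Gaussian results: a normal density
#' `p(x) = sqrt(beta/pi) exp(-beta (x - y)^2)` with mean `y` and inverse
#' temperature `beta`, so the variance is `sigma^2 = 1/(2 beta)` (k_B = 1).
#'
#' @param mean Mean `y`.
#' @param beta Inverse temperature, `beta > 0`.
#' @param t Optional time tag.
#'
#' @return An object of class `gaussian_state` with derived `sigma` and
#'   `sigma2`.
#' @export
#' @examples
#' gaussian_state(0, 0.5)$sigma2  # variance 1
gaussian_state <- function(mean, beta, t = NA_real_) {
  if (!is.numeric(beta) || beta <= 0) stop("gaussian_state: beta must be > 0")
  structure(list(mean = mean, beta = beta, t = t,
                 sigma2 = 1 / (2 * beta), sigma = 1 / sqrt(2 * beta)),
            class = "gaussian_state")
}

#' @export
print.gaussian_state <- function(x, ...) {
  cat(sprintf("gaussian_state: mean %.6g, beta %.6g (sigma %.6g)%s\n",
              x$mean, x$beta, x$sigma,
              if (is.na(x$t)) "" else sprintf(" at t = %g", x$t)))
  invisible(x)
}

#' Sample a Gaussian state on a grid
#'
#' Evaluates the Gaussian density of `state` at the grid nodes and
#' renormalizes by its trapezoid integral. The grid must span at least
#' six standard deviations on each side of the mean so that truncation
#' does not bias downstream integrals; the renormalization factor is then
#' within `1e-6` of 1.
#'
#' @param state A [gaussian_state()].
#' @param grid A [grid1d()].
#'
#' @return A [grid_pdf()] tagged with the state's time.
#' @export
#' @examples
#' g <- grid1d(-6, 6, 2048)
#' p <- gaussian_to_grid(gaussian_state(0, pi), g)
#' max(p$p)  # peak (beta/pi)^(1/2) = 1
gaussian_to_grid <- function(state, grid) {
  stopifnot(inherits(state, "gaussian_state"), inherits(grid, "grid1d"))
  lo <- state$mean - 6 * state$sigma
  hi <- state$mean + 6 * state$sigma
  if (grid$x_min > lo || grid$x_max < hi)
    stop(sprintf(paste0("gaussian_to_grid: grid [%g, %g] does not cover ",
                        "[mean - 6 sigma, mean + 6 sigma] = [%g, %g]; ",
                        "truncation would bias integrals"),
                 grid$x_min, grid$x_max, lo, hi))
  lp <- 0.5 * log(state$beta / pi) - state$beta * (grid$x - state$mean)^2
  grid_pdf(grid, exp(lp), t = state$t, renormalize = TRUE, lp = lp)
}

#' Moments of a grid density
#'
#' Trapezoid-quadrature mean, variance and fourth central moment. For a
#' Gaussian input the fourth central moment equals `3 * variance^2`.
#'
#' @param pdf A [grid_pdf()].
#' @return List with `mean`, `variance`, `m4` (fourth central moment).
#' @export
moments <- function(pdf) {
  stopifnot(inherits(pdf, "grid_pdf"))
  w <- trapz_weights(pdf$grid) * pdf$p
  m <- sum(w * pdf$grid$x)
  d <- pdf$grid$x - m
  list(mean = m, variance = sum(w * d^2), m4 = sum(w * d^4))
}

#' Differential entropy of a grid density
#'
#' Computes `S = -integral p ln p dx` by trapezoid quadrature with the
#' convention `0 * ln 0 = 0` at zero-density nodes (k_B = 1). For a Gaussian
#' with inverse temperature `beta` this equals `(1 + ln(pi/beta))/2`.
#'
#' @param pdf A [grid_pdf()].
#' @return The differential entropy (a real number; can be negative).
#' @export
#' @examples
#' g <- grid1d(-8, 8, 2048)
#' differential_entropy(gaussian_to_grid(gaussian_state(0, pi), g))  # 0.5
differential_entropy <- function(pdf) {
  stopifnot(inherits(pdf, "grid_pdf"))
  integrand <- ifelse(pdf$p > 0, pdf$p * log(pmax(pdf$p, 1e-300)), 0)
  -grid_trapz(pdf$grid, integrand)
}

#' Gaussian closed forms
#'
#' Closed-form reference values for Gaussian densities, used as analytic
#' counterparts of the grid-quadrature routines: the Kullback-Leibler
#' divergence between two normals, the Bhattacharyya coefficient (whose
#' arccos is the Wootters angle), and the differential entropy.
#'
#' @param mean1,var1,mean2,var2 Means and variances of the two normals.
#' @param beta Inverse temperature (`var = 1/(2 beta)`).
#' @name gaussian_closed_forms
NULL

#' @rdname gaussian_closed_forms
#' @export
gaussian_kl <- function(mean1, var1, mean2, var2) {
  log(sqrt(var2 / var1)) + (var1 + (mean1 - mean2)^2) / (2 * var2) - 0.5
}

#' @rdname gaussian_closed_forms
#' @export
gaussian_bhattacharyya <- function(mean1, var1, mean2, var2) {
  sqrt(2 * sqrt(var1 * var2) / (var1 + var2)) *
    exp(-(mean1 - mean2)^2 / (4 * (var1 + var2)))
}

#' @rdname gaussian_closed_forms
#' @export
gaussian_entropy <- function(beta) 0.5 * (1 + log(pi / beta))
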