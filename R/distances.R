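#' Distances between two grid densities
#'
#' The four two-PDF distances used throughout the package. All are computed
#' by trapezoid quadrature on the shared grid of the two inputs.
#'
#' * `wootters_distance()`: the statistical angle
#'   `arccos(integral sqrt(p1 p2) dx)`, in `[0, pi/2]`. The inner product is
#'   clipped to `[0, 1]` before `arccos` to absorb quadrature rounding.
#' * `kl_divergence()`: the relative entropy
#'   `integral p1 ln(p1/p2) dx >= 0`. Nodes where `p1` vanishes contribute 0;
#'   if `p1` is positive where `p2` is a true zero (below `1e-300`) the
#'   divergence is `+Inf`.
#' * `jensen_divergence()`: the symmetrized divergence
#'   `(KL(p1|p2) + KL(p2|p1))/2`.
#' * `l2_distance()`: the squared Euclidean norm
#'   `integral (p1 - p2)^2 dx`. Note the squared convention; take
#'   `sqrt()` for the rooted norm.
#'
#' @param p1,p2 [grid_pdf()] objects on the same grid.
#' @return A non-negative real number (possibly `Inf` for the divergences).
#' @seealso [distance_report()] for all four at once.
#' @name pdf_distances
NULL

check_shared_grid <- function(p1, p2) {
  stopifnot(inherits(p1, "grid_pdf"), inherits(p2, "grid_pdf"))
  if (!same_grid(p1$grid, p2$grid))
    stop("distance: the two densities are not on the same grid")
}

# tolerance below which a density value counts as a true zero
.zero_tol <- 1e-300

#' @rdname pdf_distances
#' @export
wootters_distance <- function(p1, p2) {
  check_shared_grid(p1, p2)
  ip <- grid_trapz(p1$grid, p1$q * p2$q)
  acos(min(max(ip, 0), 1))
}

#' @rdname pdf_distances
#' @export
kl_divergence <- function(p1, p2) {
  check_shared_grid(p1, p2)
  a <- p1$p
  live <- a > .zero_tol
  # log-densities keep far-tail ratios meaningful below the underflow
  # threshold; a true zero of p2 under the support of p1 is a divergence
  if (any(live & p1$lp > -Inf & p2$lp == -Inf)) return(Inf)
  integrand <- numeric(length(a))
  integrand[live] <- a[live] * (p1$lp[live] - p2$lp[live])
  grid_trapz(p1$grid, integrand)
}

#' @rdname pdf_distances
#' @export
jensen_divergence <- function(p1, p2) {
  (kl_divergence(p1, p2) + kl_divergence(p2, p1)) / 2
}

#' @rdname pdf_distances
#' @export
l2_distance <- function(p1, p2) {
  check_shared_grid(p1, p2)
  grid_trapz(p1$grid, (p1$p - p2$p)^2)
}

#' All four PDF distances at once
#'
#' @param p1,p2 [grid_pdf()] objects on the same grid.
#' @return An object of class `distance_report`: a list with `wootters`,
#'   `kl_forward`, `kl_backward`, `jensen` and `l2`.
#' @export
#' @examples
#' g <- grid1d(-10, 10, 2048)
#' a <- gaussian_to_grid(gaussian_state(0, 0.5), g)
#' b <- gaussian_to_grid(gaussian_state(1, 0.5), g)
#' distance_report(a, b)
distance_report <- function(p1, p2) {
  kf <- kl_divergence(p1, p2)
  kb <- kl_divergence(p2, p1)
  structure(list(wootters = wootters_distance(p1, p2),
                 kl_forward = kf, kl_backward = kb,
                 jensen = (kf + kb) / 2,
                 l2 = l2_distance(p1, p2)),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf(paste0("distances: Wootters %.6g | KL(p1|p2) %.6g | ",
                     "KL(p2|p1) %.6g | Jensen %.6g | L2^2 %.6g\n"),
              x$wootters, x$kl_forward, x$kl_backward, x$jensen, x$l2))
  invisible(x)
}
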