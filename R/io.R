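#' Read and write PDF snapshot / trajectory CSV files
#'
#' The on-disk interchange formats are plain CSV with headers:
#' a single snapshot has columns `x, p`; a trajectory is long-format with
#' columns `t, x, p`, ordered by `t` then `x`, every snapshot on the same
#' uniform grid.
#'
#' @param path File path.
#' @param pdf A [grid_pdf()].
#' @param traj A [pdf_trajectory()].
#' @param renormalize Renormalize on read (default TRUE, to absorb the
#'   rounding of decimal output).
#' @name trajectory_io
NULL

#' @rdname trajectory_io
#' @export
read_snapshot_csv <- function(path, renormalize = TRUE) {
  d <- utils::read.csv(path)
  if (!all(c("x", "p") %in% names(d)))
    stop("read_snapshot_csv: need columns x, p")
  d <- d[order(d$x), ]
  g <- grid1d(min(d$x), max(d$x), nrow(d))
  if (max(abs(g$x - d$x)) > 1e-8 * max(1, g$dx))
    stop("read_snapshot_csv: x values are not a uniform grid")
  grid_pdf(g, d$p, renormalize = renormalize)
}

#' @rdname trajectory_io
#' @export
write_snapshot_csv <- function(pdf, path) {
  stopifnot(inherits(pdf, "grid_pdf"))
  utils::write.csv(data.frame(x = pdf$grid$x, p = pdf$p), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname trajectory_io
#' @export
read_trajectory_csv <- function(path, renormalize = TRUE) {
  d <- utils::read.csv(path)
  if (!all(c("t", "x", "p") %in% names(d)))
    stop("read_trajectory_csv: need columns t, x, p")
  d <- d[order(d$t, d$x), ]
  times <- sort(unique(d$t))
  xs <- d$x[d$t == times[1]]
  g <- grid1d(min(xs), max(xs), length(xs))
  P <- matrix(d$p, nrow = length(xs), ncol = length(times))
  pdf_trajectory(g, times, P, renormalize = renormalize)
}

#' @rdname trajectory_io
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "pdf_trajectory"))
  d <- data.frame(t = rep(traj$times, each = traj$grid$n),
                  x = rep(traj$grid$x, length(traj$times)),
                  p = as.numeric(traj$P))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write an information-rate series as CSV
#'
#' Columns `t, Gamma, E, L`.
#'
#' @param series An [info_series()].
#' @param path File path.
#' @export
write_info_csv <- function(series, path) {
  stopifnot(inherits(series, "info_series"))
  utils::write.csv(series[, c("t", "Gamma", "E", "L")], path,
                   row.names = FALSE)
  invisible(path)
}
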