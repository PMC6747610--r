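## NMR-comparable observables from MD-derived time series: windowed N-H
## order parameters, hydrogen-bond occupancy and burial from exposed
## area. Vectors are assumed pre-aligned to the molecular frame
## (tumbling removed); alignment is the caller's responsibility.

## ensemble second-moment S2 over a block of unit vectors (rows)
.s2Block <- function(v) {
  x <- v[, 1]; y <- v[, 2]; z <- v[, 3]
  1.5 * (mean(x^2)^2 + mean(y^2)^2 + mean(z^2)^2 +
         2 * mean(x * y)^2 + 2 * mean(x * z)^2 + 2 * mean(y * z)^2) - 0.5
}

#' Windowed N-H order parameter from a vector trajectory
#'
#' Per analysis window, the squared generalized order parameter is the
#' ensemble second moment
#' \deqn{S^2 = \tfrac{3}{2}\left[\langle x^2\rangle^2 + \langle y^2\rangle^2
#'   + \langle z^2\rangle^2 + 2\langle xy\rangle^2 + 2\langle xz\rangle^2
#'   + 2\langle yz\rangle^2\right] - \tfrac{1}{2}}
#' over the frames in the window. A window whose first- and second-half
#' estimates differ by more than \code{convergenceTol} is flagged
#' non-converged (drifting mean orientation).
#'
#' @param traj a \linkS4class{VectorTrajectory}; the trajectory must hold
#'   at least one full window.
#' @param convergenceTol half-vs-half S2 difference above which a window
#'   is flagged (default 0.05).
#' @return list with \code{perWindow} data.frame (window, s2, converged),
#'   \code{s2Mean}, \code{s2SD} (across windows; NA with one window).
#' @export
orderParameter <- function(traj, convergenceTol = 0.05) {
  framesPerWin <- floor(traj@window / traj@dt)
  nWin <- nrow(traj@frames) %/% framesPerWin
  if (nWin < 1L)
    stop("window (", traj@window, " s) is longer than the trajectory")
  rows <- lapply(seq_len(nWin), function(w) {
    idx <- ((w - 1L) * framesPerWin + 1L):(w * framesPerWin)
    v <- traj@frames[idx, , drop = FALSE]
    half <- length(idx) %/% 2L
    s2a <- .s2Block(v[seq_len(half), , drop = FALSE])
    s2b <- .s2Block(v[(half + 1L):length(idx), , drop = FALSE])
    data.frame(window = w, s2 = .s2Block(v),
               converged = abs(s2a - s2b) <= convergenceTol)
  })
  perWindow <- do.call(rbind, rows)
  list(perWindow = perWindow, s2Mean = mean(perWindow$s2),
       s2SD = if (nWin > 1L) stats::sd(perWindow$s2) else NA_real_)
}

#' Hydrogen-bond occupancy from an H...acceptor distance series
#'
#' Percentage of frames in which the hydrogen-to-heavy-atom distance is
#' at or below the cutoff (2.4 Angstrom by default, no angle
#' restriction; the boundary is inclusive).
#'
#' @param distances per-frame H...acceptor distances (Angstrom).
#' @param cutoff distance cutoff (Angstrom).
#' @return occupancy percentage in [0, 100].
#' @export
hbondOccupancy <- function(distances, cutoff = 2.4) {
  stopifnot(length(distances) >= 1L, all(distances > 0))
  100 * mean(distances <= cutoff)
}

#' Buried fraction from exposed area
#'
#' Time-averaged linear ramp mapping the per-frame exposed value onto
#' percent buried: \code{fullBurial} exposed (default 0) is 100% buried,
#' \code{zeroBurial} exposed (default 10) is 0% buried, clamped outside
#' the range.
#'
#' @param exposed per-frame exposed values.
#' @param fullBurial exposure at (and below) which a frame counts fully
#'   buried.
#' @param zeroBurial exposure at (and above) which a frame counts fully
#'   exposed.
#' @return percentage buried in [0, 100].
#' @export
buriedFraction <- function(exposed, fullBurial = 0, zeroBurial = 10) {
  stopifnot(zeroBurial > fullBurial, all(exposed >= 0))
  frac <- (zeroBurial - exposed) / (zeroBurial - fullBurial)
  100 * mean(pmin(pmax(frac, 0), 1))
}
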