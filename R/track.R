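#' Particle track of a probe centre
#'
#' Uniformly sampled 2-D positions of the chain centre, together with the
#' chain-axis unit vector recorded at the start of the track (used to resolve
#' displacements parallel and perpendicular to the chain).
#'
#' @param times sample times in seconds, strictly increasing and uniform.
#' @param x,y coordinates in meters.
#' @param axis length-2 unit vector of the chain direction; default c(1, 0).
#' @return object of class `endo_track` with elements `times`, `x`, `y`,
#'   `axis`, `dt`.
#' @export
endo_track <- function(times, x, y, axis = c(1, 0)) {
  n <- length(times)
  if (n < 2) stop_invalid("a track needs at least 2 samples")
  if (length(x) != n || length(y) != n)
    stop_invalid("times, x, y must have equal length")
  if (anyNA(times) || anyNA(x) || anyNA(y) ||
      any(!is.finite(x)) || any(!is.finite(y)))
    stop_invalid("track contains NA or non-finite values")
  dts <- diff(times)
  if (any(dts <= 0))
    stop_invalid("times must be strictly increasing (first violation at row %d)",
                 which(dts <= 0)[1] + 1L)
  if (max(dts) - min(dts) > 1e-9)
    stop_invalid("track sampling is non-uniform (dt spread %.3g s)",
                 max(dts) - min(dts))
  nrm <- sqrt(sum(axis^2))
  if (length(axis) != 2 || nrm == 0) stop_invalid("axis must be a 2-vector")
  structure(list(times = as.numeric(times), x = as.numeric(x),
                 y = as.numeric(y), axis = axis / nrm,
                 dt = mean(dts)),
            class = "endo_track")
}

#' @export
print.endo_track <- function(x, ...) {
  cat(sprintf(
    "Track: %d samples, dt = %.4g s, duration = %.4g s, axis = (%.2f, %.2f)\n",
    length(x$times), x$dt, x$times[length(x$times)] - x$times[1],
    x$axis[1], x$axis[2]))
  invisible(x)
}

#' @export
as.data.frame.endo_track <- function(x, ...) {
  data.frame(time_s = x$times, x_m = x$x, y_m = x$y,
             axis_x = x$axis[1], axis_y = x$axis[2])
}

#' @export
plot.endo_track <- function(x, ...) {
  graphics::plot(x$x * 1e6, x$y * 1e6, type = "l", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  invisible(x)
}

#' Project a track on an axis
#'
#' @param track an [endo_track()].
#' @param axis "parallel" (along the chain axis), "perpendicular", "x" or "y".
#' @return numeric vector of 1-D positions (m).
#' @noRd
track_coordinate <- function(track, axis = c("parallel", "perpendicular",
                                             "x", "y")) {
  axis <- match.arg(axis)
  u <- track$axis
  switch(axis,
         parallel = track$x * u[1] + track$y * u[2],
         perpendicular = -track$x * u[2] + track$y * u[1],
         x = track$x,
         y = track$y)
}
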