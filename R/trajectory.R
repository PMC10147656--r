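#' Time-stamped probe trajectory
#'
#' The central data container: uniformly sampled probe positions (metres)
#' on 1--3 axes with acquisition metadata. Positions are stored as a matrix
#' with named columns drawn from `x`, `y`, `z`.
#'
#' @param t Time stamps in seconds, strictly increasing and uniformly
#'   spaced.
#' @param positions Numeric matrix (`length(t)` rows, 1--3 columns) of
#'   positions in metres, or a numeric vector for a single axis.
#' @param frame_rate Acquisition rate in Hz; must equal `1/dt` to within
#'   `1e-9` relative.
#' @param context A [probe_context()].
#' @param provenance Free-text description of the source (simulation
#'   parameters or video file).
#' @param dropped_frames Optional integer vector of frame indices that
#'   failed localization (gaps are recorded, never interpolated).
#' @return An object of class `trajectory` with elements `t`, `positions`,
#'   `frame_rate`, `dt`, `context`, `provenance`, `dropped_frames`.
#' @export
trajectory <- function(t, positions, frame_rate, context,
                       provenance = "unknown", dropped_frames = integer()) {
  stopifnot(inherits(context, "probe_context"))
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 1L,
                                                   dimnames = list(NULL, "x"))
  positions <- as.matrix(positions)
  if (is.null(colnames(positions)))
    colnames(positions) <- c("x", "y", "z")[seq_len(ncol(positions))]
  if (!all(colnames(positions) %in% c("x", "y", "z")))
    stop("position columns must be named from 'x', 'y', 'z'")
  if (ncol(positions) < 1L || ncol(positions) > 3L)
    stop("1 to 3 position axes are supported")
  n <- length(t)
  if (n < 2L) stop("a trajectory needs at least 2 samples")
  if (nrow(positions) != n)
    stop(sprintf("length(t) == %d but positions has %d rows", n,
                 nrow(positions)))
  if (!all(is.finite(t)) || !all(is.finite(positions)))
    stop("all times and positions must be finite")
  dts <- diff(t)
  if (any(dts <= 0)) stop("time stamps must be strictly increasing")
  dt <- dts[1L]
  if (max(abs(dts - dt)) > 1e-9 * dt)
    stop("time stamps must be uniformly spaced")
  if (abs(dt - 1 / frame_rate) > 1e-9 * dt)
    stop("dt and 1/frame_rate disagree beyond 1e-9 relative tolerance")
  structure(
    list(t = as.numeric(t), positions = positions,
         frame_rate = frame_rate, dt = dt, context = context,
         provenance = provenance,
         dropped_frames = as.integer(dropped_frames)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames at %.4g Hz (%.4g s), axes: %s\n",
              length(x$t), x$frame_rate, x$t[length(x$t)] - x$t[1L],
              paste(colnames(x$positions), collapse = ", ")))
  sds <- apply(x$positions, 2L, stats::sd)
  cat(sprintf("  position sd: %s m\n",
              paste(sprintf("%s = %.3g", names(sds), sds), collapse = ", ")))
  if (length(x$dropped_frames))
    cat(sprintf("  dropped frames: %d\n", length(x$dropped_frames)))
  cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, axis = colnames(x$positions)[1L], ...) {
  graphics::plot(x$t, x$positions[, axis] * 1e6, type = "l",
                 xlab = "time (s)", ylab = sprintf("%s (um)", axis), ...)
  invisible(x)
}

#' Number of axes in a trajectory
#' @param traj A [trajectory()].
#' @export
n_axes <- function(traj) ncol(traj$positions)

# Pull one named axis as a plain numeric vector.
axis_series <- function(traj, axis) {
  if (!axis %in% colnames(traj$positions))
    stop(sprintf("axis '%s' not present (have: %s)", axis,
                 paste(colnames(traj$positions), collapse = ", ")))
  traj$positions[, axis]
}
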