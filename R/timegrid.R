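#' Uniform acquisition time grid
#'
#' Represents the temporal sampling of a dynamic contrast-enhanced series:
#' `n_frames` frames acquired every `dt` seconds, the first at `t0` seconds.
#' The default constructor arguments match a typical small-animal DCE
#' acquisition of 65 repetitions at 6.6 s temporal resolution.
#'
#' @param n_frames integer number of frames (>= 2).
#' @param dt frame spacing in seconds (> 0).
#' @param t0 acquisition time of the first frame in seconds.
#' @return An object of class `time_grid`.
#' @examples
#' g <- time_grid(65, 6.6)
#' head(frame_times(g))
#' @export
time_grid <- function(n_frames = 65L, dt = 6.6, t0 = 0) {
  n_frames <- as.integer(n_frames)
  if (length(n_frames) != 1L || is.na(n_frames) || n_frames < 2L)
    stop("n_frames must be a single integer >= 2")
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (seconds)")
  structure(list(n_frames = n_frames, dt = dt, t0 = t0),
            class = "time_grid")
}

#' Frame acquisition times
#'
#' @param grid a [time_grid()].
#' @param unit `"s"` (default) or `"min"`.
#' @return Numeric vector of length `n_frames`.
#' @export
frame_times <- function(grid, unit = c("s", "min")) {
  unit <- match.arg(unit)
  t <- grid$t0 + (seq_len(grid$n_frames) - 1) * grid$dt
  if (unit == "min") t / 60 else t
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d frames, dt = %g s (%.2f min total)\n",
              x$n_frames, x$dt, (x$n_frames - 1) * x$dt / 60))
  invisible(x)
}

stopifnot_grid <- function(grid) {
  if (!inherits(grid, "time_grid")) stop("expected a 'time_grid' object")
  invisible(grid)
}

#' Arterial input function
#'
#' Plasma enhancement sampled on a uniform time grid, typically the per-frame
#' median enhancement over an aortic ROI. Values before the bolus-arrival
#' frame are expected to be zero.
#'
#' @param grid a [time_grid()].
#' @param cp numeric vector of plasma enhancement, one value per frame.
#' @param arrival_frame optional index (1-based) of the bolus-arrival frame,
#'   stored as an attribute when known.
#' @return An object of class `aif`.
#' @export
aif <- function(grid, cp, arrival_frame = NULL) {
  stopifnot_grid(grid)
  cp <- as.numeric(cp)
  if (length(cp) != grid$n_frames)
    stop("length(cp) must equal grid$n_frames")
  if (!all(is.finite(cp))) stop("cp must be finite")
  structure(list(grid = grid, cp = cp, arrival_frame = arrival_frame),
            class = "aif")
}

#' @export
print.aif <- function(x, ...) {
  cat(sprintf("<aif> %d frames, peak %.3g at frame %d\n",
              x$grid$n_frames, max(x$cp), which.max(x$cp)))
  invisible(x)
}

#' Tissue enhancement curve
#'
#' @param grid a [time_grid()].
#' @param ct numeric tissue enhancement per frame (signal units, S(t) - S0).
#' @return An object of class `tissue_curve`.
#' @export
tissue_curve <- function(grid, ct) {
  stopifnot_grid(grid)
  ct <- as.numeric(ct)
  if (length(ct) != grid$n_frames)
    stop("length(ct) must equal grid$n_frames")
  if (!all(is.finite(ct))) stop("ct must be finite")
  structure(list(grid = grid, ct = ct), class = "tissue_curve")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$n_frames, b$n_frames)) &&
    isTRUE(all.equal(a$dt, b$dt)) &&
    isTRUE(all.equal(a$t0, b$t0))
}
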