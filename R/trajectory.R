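#' Marker trajectory container
#'
#' A `marker_trajectory` holds the sampled 3-D positions of a set of optical
#' motion-capture markers: a common time axis `times` (seconds, strictly
#' increasing), a nominal `rate` (Hz), and one K x 3 coordinate matrix per
#' marker with columns X, Y, Z in the input length units.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing, length K >= 2.
#' @param coords Named list of K x 3 numeric matrices, one per marker.
#' @param rate Sampling rate in Hz. Defaults to `1 / median(diff(times))`.
#'   Must agree with the time axis to within `1e-9` relative.
#' @param units Length-unit label carried through unchanged (e.g. `"mm"`).
#'
#' @return An object of class `marker_trajectory` with elements `times`,
#'   `rate`, `markers` (character vector of names), `coords`, `units`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 120)
#' xyz <- cbind(sin(2 * pi * t), cos(2 * pi * t), 0 * t)
#' traj <- marker_trajectory(t, list(heel = xyz))
#' traj
marker_trajectory <- function(times, coords, rate = NULL, units = "mm") {
  times <- as.numeric(times)
  K <- length(times)
  if (K < 2L)
    mn_stop("a marker trajectory needs at least 2 frames", "mn_data_error")
  dt <- diff(times)
  if (any(!is.finite(times)) || any(dt <= 0))
    mn_stop("times must be finite and strictly increasing", "mn_data_error")
  if (!is.list(coords) || length(coords) == 0L || is.null(names(coords)) ||
      any(!nzchar(names(coords))))
    mn_stop("coords must be a non-empty named list of K x 3 matrices",
            "mn_data_error")
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  for (nm in names(coords)) {
    m <- coords[[nm]]
    if (nrow(m) != K || ncol(m) != 3L)
      mn_stop(sprintf("marker '%s': coordinates must be %d x 3", nm, K),
              "mn_data_error")
    if (any(!is.finite(m)))
      mn_stop(sprintf("marker '%s': non-finite coordinate values", nm),
              "mn_data_error")
    colnames(m) <- c("x", "y", "z")
    coords[[nm]] <- m
  }
  if (is.null(rate)) rate <- 1 / median(dt)
  if (!is_number(rate) || rate <= 0)
    mn_stop("rate must be a positive number", "mn_data_error")
  # uniform sampling consistent with the declared rate
  rel <- abs(dt - 1 / rate) * rate
  if (any(rel > 1e-6))
    mn_stop("times are not uniform at the declared sampling rate", "mn_data_error")
  structure(
    list(times = times, rate = rate, markers = names(coords),
         coords = coords, units = units),
    class = "marker_trajectory"
  )
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf(
    "<marker_trajectory> %d markers, %d frames @ %.6g Hz (%.3g s), units: %s\n",
    length(x$markers), length(x$times), x$rate,
    x$times[length(x$times)] - x$times[1], x$units))
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

#' Stack marker coordinates into a channel matrix
#'
#' Flattens the per-marker K x 3 coordinate blocks into a single K x 3M
#' matrix whose columns are named `<marker>.x`, `<marker>.y`, `<marker>.z`
#' (marker order as requested). This is the target matrix used by the
#' least-squares weight fit.
#'
#' @param trajectory A [marker_trajectory()].
#' @param markers Markers to include (default all, in stored order).
#' @return K x 3M numeric matrix with named columns.
#' @export
channel_matrix <- function(trajectory, markers = trajectory$markers) {
  stopifnot(inherits(trajectory, "marker_trajectory"))
  missing <- setdiff(markers, trajectory$markers)
  if (length(missing))
    mn_stop(paste0("unknown marker(s): ", paste(missing, collapse = ", ")),
            "mn_data_error")
  blocks <- lapply(markers, function(nm) trajectory$coords[[nm]])
  out <- do.call(cbind, blocks)
  colnames(out) <- as.vector(t(outer(markers, c("x", "y", "z"), paste, sep = ".")))
  out
}

#' Extract a frame range as a new trajectory
#'
#' @param trajectory A [marker_trajectory()].
#' @param from,to 1-based first and last frame (inclusive).
#' @return A [marker_trajectory()] covering frames `from:to`.
#' @export
trajectory_window <- function(trajectory, from, to) {
  K <- length(trajectory$times)
  if (from < 1L || to > K || from >= to)
    mn_stop("invalid frame window", "mn_data_error")
  idx <- from:to
  marker_trajectory(trajectory$times[idx],
                    lapply(trajectory$coords, function(m) m[idx, , drop = FALSE]),
                    rate = trajectory$rate, units = trajectory$units)
}
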