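## run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  expr
}

#' Specification of a synthetic ground-truth motion
#'
#' Describes the generator used for all recovery experiments: n harmonic
#' centers mapped through a Gaussian-rbf satellite layer to `markers`
#' marker channels, sampled at `rate` Hz for `duration` seconds, with
#' optional i.i.d. Gaussian observation noise scaled to each channel's
#' amplitude. Defaults emulate typical whole-body capture: 120 Hz, 10 s
#' (K = 1200 frames), sub-Hz center frequencies.
#'
#' @param n Number of centers.
#' @param freqs_hz Center frequencies in Hz (length n), or `NULL` to draw
#'   them uniformly from `freq_range` under the seed.
#' @param freq_range Range for random frequencies (Hz).
#' @param n_m Satellite count.
#' @param markers Number of markers (each contributes x, y, z channels).
#' @param duration Seconds of motion.
#' @param rate Sampling rate in Hz.
#' @param noise_sd Observation-noise SD as a fraction of each channel's
#'   amplitude (`(max - min)/2` of the noiseless channel).
#' @param segments Optional segment plan: list of `list(duration,
#'   freqs_hz)` entries for [generate_segmented()].
#' @param seed Mandatory integer seed; every random draw derives from it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n = 2L, freqs_hz = c(0.5, 1.3), freq_range = c(0.1, 2),
                       n_m = 25L, markers = 1L, duration = 10, rate = 120,
                       noise_sd = 0, segments = NULL, seed) {
  if (missing(seed) || !is_number(seed))
    mn_stop("synth_spec requires an explicit integer seed", "mn_config_error")
  n <- as.integer(n)
  if (n < 1L || n_m < 1L || markers < 1L || rate <= 0 || duration <= 0 ||
      noise_sd < 0)
    mn_stop("invalid synthetic spec", "mn_config_error")
  if (!is.null(freqs_hz) && length(freqs_hz) != n)
    mn_stop("freqs_hz must have length n", "mn_config_error")
  structure(list(n = n, freqs_hz = freqs_hz, freq_range = freq_range,
                 n_m = as.integer(n_m), markers = as.integer(markers),
                 duration = duration, rate = rate, noise_sd = noise_sd,
                 segments = segments, seed = as.integer(seed)),
            class = "synth_spec")
}

synth_times <- function(duration, rate) seq(0, by = 1 / rate,
                                            length.out = round(duration * rate))

#' Generate a ground-truth motion model
#'
#' Builds the generating network for a [synth_spec()]: harmonic centers
#' at the spec frequencies (drawn from `freq_range` when unspecified),
#' radial centers placed on the actual center trajectory, and satellite
#' weights drawn i.i.d. standard normal then rescaled so each channel has
#' unit amplitude `(max - min)/2 = 1`. Deterministic given `(spec, seed)`.
#'
#' @param spec A [synth_spec()].
#' @return A `motion_model` (with an empty accuracy report).
#' @export
generate_model <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    freqs <- spec$freqs_hz
    if (is.null(freqs))
      freqs <- sort(runif(spec$n, spec$freq_range[1], spec$freq_range[2]))
    bank <- oscillator_bank(omega = rad_s(sort(freqs)))
    times <- synth_times(spec$duration, spec$rate)
    states <- harmonic_states(bank, times)
    Phi <- eval_basis(states, basis_config("rbf", n_m = spec$n_m))
    basis <- attr(Phi, "config")
    C <- 3L * spec$markers
    W <- matrix(rnorm(C * ncol(Phi)), C, ncol(Phi))
    X <- Phi %*% t(W)
    amp <- (apply(X, 2, max) - apply(X, 2, min)) / 2
    amp[amp == 0] <- 1
    W <- W / amp
    marker_names <- sprintf("marker%d", seq_len(spec$markers))
    rownames(W) <- as.vector(t(outer(marker_names, c("x", "y", "z"),
                                     paste, sep = ".")))
    colnames(W) <- colnames(Phi)
    structure(
      list(bank = bank, basis = basis, W = W,
           channels = data.frame(marker = rep(marker_names, each = 3L),
                                 axis = rep(c("x", "y", "z"), spec$markers),
                                 stringsAsFactors = FALSE),
           t0 = 0, units = "unit"),
      class = "motion_model")
  })
}

#' Generate a marker trajectory from a ground-truth model
#'
#' Evaluates the model on the uniform time grid of the spec and adds
#' i.i.d. Gaussian observation noise with SD `noise_sd` times each
#' channel's amplitude. The noise draw derives from `spec$seed` (offset
#' so it is independent of the weight draw).
#'
#' @param model A `motion_model`, typically from [generate_model()].
#' @param spec The [synth_spec()].
#' @return A list: `trajectory` ([marker_trajectory()]), `truth` (list
#'   with `freqs_hz`, `omega`, `model`, `noise_sd`, `noiseless` matrix).
#' @export
generate_trajectory <- function(model, spec) {
  stopifnot(inherits(model, "motion_model"), inherits(spec, "synth_spec"))
  times <- synth_times(spec$duration, spec$rate)
  X <- predict(model, times)
  amp <- (apply(X, 2, max) - apply(X, 2, min)) / 2
  noisy <- X
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed + 104729L,
                       matrix(rnorm(length(X)), nrow(X), ncol(X)))
    noisy <- X + sweep(noise, 2, spec$noise_sd * amp, `*`)
  }
  markers <- unique(model$channels$marker)
  coords <- lapply(markers, function(nm)
    noisy[, paste0(nm, ".", c("x", "y", "z")), drop = FALSE])
  names(coords) <- markers
  traj <- marker_trajectory(times, coords, rate = spec$rate, units = "unit")
  list(trajectory = traj,
       truth = list(freqs_hz = hz(model$bank$omega),
                    omega = model$bank$omega, model = model,
                    noise_sd = spec$noise_sd, noiseless = X))
}

#' Convenience: model plus trajectory in one call
#'
#' @param spec A [synth_spec()].
#' @return As [generate_trajectory()].
#' @export
synth_motion <- function(spec) {
  generate_trajectory(generate_model(spec), spec)
}

#' Generate a segmented synthetic motion
#'
#' Concatenates independent per-segment generations (each segment has its
#' own frequency vector and weights, drawn under a seed derived from the
#' spec seed and the segment index) on a continuous time axis, and
#' returns the true frame boundaries in the `T_1 < ... < T_{Nseg+1}`
#' convention used by [fit_segmented()].
#'
#' @param spec A [synth_spec()] whose `segments` field is a list of at
#'   least two `list(duration = , freqs_hz = )` entries.
#' @return A list: `trajectory`, `boundaries` (length Nseg + 1), `truth`
#'   (per-segment truth records).
#' @export
generate_segmented <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  segs <- spec$segments
  if (is.null(segs) || length(segs) < 2L)
    mn_stop("generate_segmented needs a plan of >= 2 segments", "mn_config_error")
  parts <- vector("list", length(segs))
  truth <- vector("list", length(segs))
  for (s in seq_along(segs)) {
    sub <- synth_spec(n = length(segs[[s]]$freqs_hz),
                      freqs_hz = segs[[s]]$freqs_hz,
                      n_m = spec$n_m, markers = spec$markers,
                      duration = segs[[s]]$duration, rate = spec$rate,
                      noise_sd = spec$noise_sd,
                      seed = spec$seed + 7919L * s)
    g <- synth_motion(sub)
    parts[[s]] <- g$trajectory
    truth[[s]] <- g$truth
  }
  frames <- vapply(parts, function(p) length(p$times), integer(1))
  boundaries <- c(1L, cumsum(frames) + 1L)
  times <- synth_times(sum(vapply(segs, `[[`, numeric(1), "duration")),
                       spec$rate)
  markers <- parts[[1]]$markers
  coords <- lapply(markers, function(nm)
    do.call(rbind, lapply(parts, function(p) p$coords[[nm]])))
  names(coords) <- markers
  list(trajectory = marker_trajectory(times, coords, rate = spec$rate,
                                      units = "unit"),
       boundaries = boundaries, truth = truth)
}
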