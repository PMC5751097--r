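#' Switching module of the motion network
#'
#' A distar subsystem with one hub `z` and `m` satellites
#' \eqn{\tilde w_1 \dots \tilde w_m}:
#' \deqn{d\tilde w_i/dt = \sigma(\tilde b_i z - \tilde h_i) -
#'   \kappa^{-1} \tilde w_i}
#' \deqn{dz/dt = \sigma(\kappa^{-1} \sum_j \tilde a_j \tilde w_j - h) -
#'   \xi \bar\lambda z}
#' The decay term \eqn{\xi \bar\lambda z} sits outside the hub sigmoid,
#' so increasing the control parameter \eqn{\xi} steepens the decay line
#' and prunes stable rest points. In quasi-steady state
#' \eqn{\tilde w_i = \kappa\, \sigma(\tilde b_i z - \tilde h_i)}, and the
#' satellite staircase \eqn{\sum_j \tilde a_j \sigma(\tilde b_j z -
#' \tilde h_j)} against the line \eqn{\xi \bar\lambda z} determines the
#' multistable rest-point structure.
#'
#' @param a_tilde Positive hub-input gains, length m.
#' @param b_tilde Positive satellite gains, length m.
#' @param h_tilde Satellite thresholds, length m.
#' @param h Hub threshold.
#' @param kappa Small positive satellite timescale.
#' @param lambda_bar Positive hub decay coefficient.
#' @param xi Positive control parameter.
#' @param sigmoid_kind `"logistic"` or `"algebraic"`.
#' @return An object of class `switching_module`.
#' @export
switching_module <- function(a_tilde, b_tilde, h_tilde, h, kappa = 0.05,
                             lambda_bar = 1, xi = 1,
                             sigmoid_kind = c("logistic", "algebraic")) {
  m <- length(a_tilde)
  if (m < 1L || length(b_tilde) != m || length(h_tilde) != m)
    mn_stop("a_tilde, b_tilde, h_tilde must share a positive length",
            "mn_invalid_parameter")
  if (any(a_tilde <= 0) || any(b_tilde <= 0) || kappa <= 0 || lambda_bar <= 0)
    mn_stop("gains, kappa and lambda_bar must be positive", "mn_invalid_parameter")
  structure(list(m = m, a_tilde = as.numeric(a_tilde),
                 b_tilde = as.numeric(b_tilde),
                 h_tilde = as.numeric(h_tilde), h = h, kappa = kappa,
                 lambda_bar = lambda_bar, xi = xi,
                 sigmoid_kind = match.arg(sigmoid_kind)),
            class = "switching_module")
}

#' @export
print.switching_module <- function(x, ...) {
  cat(sprintf("<switching_module> m = %d satellites, kappa = %g, xi = %g, %s sigmoid\n",
              x$m, x$kappa, x$xi, x$sigmoid_kind))
  invisible(x)
}

#' Vector field of the switching module
#'
#' @param state Numeric state `c(w_tilde_1..m, z)`.
#' @param module A [switching_module()].
#' @param xi Optional override of the module's control parameter.
#' @return Derivative vector of length m + 1.
#' @export
switch_rhs <- function(state, module, xi = module$xi) {
  m <- module$m
  w <- state[seq_len(m)]; z <- state[m + 1L]
  dw <- sigmoid(module$b_tilde * z - module$h_tilde, module$sigmoid_kind) -
    w / module$kappa
  dz <- sigmoid(sum(module$a_tilde * w) / module$kappa - module$h,
                module$sigmoid_kind) - xi * module$lambda_bar * z
  c(dw, dz)
}

#' Integrate the switching module
#'
#' Adaptive integration of the full (m+1)-dimensional system from the
#' given initial state.
#'
#' @param module A [switching_module()].
#' @param state0 Initial state `c(w_tilde, z)`; a bare scalar is taken as
#'   `z(0)` with satellites at their quasi-steady values.
#' @param horizon Integration horizon (time units of the module).
#' @param xi Optional control override.
#' @param n_out Number of output samples.
#' @param rtol,atol Tolerances.
#' @return Data frame `time`, `w1..wm`, `z`; the final row is the settled
#'   state.
#' @export
simulate_switch <- function(module, state0, horizon = 50, xi = module$xi,
                            n_out = 500L, rtol = 1e-9, atol = 1e-11) {
  if (!is_number(horizon) || horizon <= 0)
    mn_stop("horizon must be positive", "mn_invalid_parameter")
  m <- module$m
  if (length(state0) == 1L)
    state0 <- c(module$kappa *
                  sigmoid(module$b_tilde * state0 - module$h_tilde,
                          module$sigmoid_kind), state0)
  if (length(state0) != m + 1L)
    mn_stop("state0 must have length m + 1 (or be a scalar z)", "mn_shape_error")
  times <- seq(0, horizon, length.out = n_out)
  rhs <- function(t, y, parms) list(switch_rhs(y, module, xi))
  out <- deSolve::ode(state0, times, rhs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (any(!is.finite(out)))
    mn_stop("switch integration blew up", "mn_integration_error")
  out <- as.data.frame(out)
  names(out) <- c("time", paste0("w", seq_len(m)), "z")
  out
}

## reduced scalar vector field for z after satellite quasi-steady-state
## elimination (the kappa factors cancel)
reduced_field <- function(z, module, xi = module$xi) {
  s <- vapply(z, function(zz)
    sum(module$a_tilde *
          sigmoid(module$b_tilde * zz - module$h_tilde, module$sigmoid_kind)),
    numeric(1))
  sigmoid(s - module$h, module$sigmoid_kind) - xi * module$lambda_bar * z
}

## full state with satellites at quasi-steady values for a hub value z
lift_state <- function(z, module) {
  c(module$kappa * sigmoid(module$b_tilde * z - module$h_tilde,
                           module$sigmoid_kind), z)
}

## forward-difference Jacobian of the full system at a state
switch_jacobian <- function(state, module, xi = module$xi) {
  n <- length(state)
  f0 <- switch_rhs(state, module, xi)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hstep <- 1e-7 * max(1, abs(state[j]))
    sp <- state; sp[j] <- sp[j] + hstep
    J[, j] <- (switch_rhs(sp, module, xi) - f0) / hstep
  }
  J
}

#' Locate and classify the rest points of the switching module
#'
#' Roots of the reduced scalar equation (hub sigmoid of the satellite
#' staircase equals the decay line) are bracketed on a dense `z` grid and
#' refined by bisection; each root is lifted to the full state and
#' classified by the eigenvalues of a forward-difference Jacobian of the
#' complete (m+1)-dimensional system. A point is stable when every
#' eigenvalue real part is negative; hyperbolicity requires
#' `|Re lambda| > 1e-6` throughout.
#'
#' @param module A [switching_module()].
#' @param xi Optional control override.
#' @param z_range Scan interval (default `(-0.5, m + 1.5)`).
#' @param grid_n Scan density (default 4000).
#' @return A `rest_point_report`: data frame `points` (z, max_re, stable,
#'   hyperbolic, residual) plus the full states in `$states` (one row per
#'   point). `points` is sorted by z; an empty frame means no roots.
#' @export
find_rest_points <- function(module, xi = module$xi,
                             z_range = c(-0.5, module$m + 1.5),
                             grid_n = 4000L) {
  zg <- seq(z_range[1], z_range[2], length.out = grid_n)
  g <- reduced_field(zg, module, xi)
  roots <- numeric(0)
  sgn <- sign(g)
  for (i in seq_len(grid_n - 1L)) {
    if (g[i] == 0) roots <- c(roots, zg[i])
    else if (sgn[i] * sgn[i + 1L] < 0) {
      r <- uniroot(reduced_field, c(zg[i], zg[i + 1L]), module = module,
                   xi = xi, tol = 1e-13)$root
      roots <- c(roots, r)
    }
  }
  if (g[grid_n] == 0) roots <- c(roots, zg[grid_n])
  roots <- sort(unique(roots))
  states <- t(vapply(roots, lift_state, numeric(module$m + 1L),
                     module = module))
  pts <- lapply(seq_along(roots), function(i) {
    st <- states[i, ]
    res <- sqrt(sum(switch_rhs(st, module, xi)^2))
    ev <- eigen(switch_jacobian(st, module, xi), only.values = TRUE)$values
    re <- Re(ev)
    data.frame(z = roots[i], max_re = max(re),
               stable = all(re < 0), hyperbolic = all(abs(re) > 1e-6),
               residual = res)
  })
  points <- if (length(pts)) do.call(rbind, pts)
            else data.frame(z = numeric(0), max_re = numeric(0),
                            stable = logical(0), hyperbolic = logical(0),
                            residual = numeric(0))
  structure(list(points = points,
                 states = if (length(roots)) states
                          else matrix(0, 0, module$m + 1L),
                 xi = xi),
            class = "rest_point_report")
}

#' @export
print.rest_point_report <- function(x, ...) {
  st <- x$points[x$points$stable, , drop = FALSE]
  cat(sprintf("<rest_point_report> xi = %g: %d rest point(s), %d stable\n",
              x$xi, nrow(x$points), nrow(st)))
  if (nrow(st)) {
    cat("  stable points:\n")
    print(format(st[, c("z", "max_re", "residual")], digits = 4),
          row.names = FALSE)
  }
  invisible(x)
}

#' Construct a switching module with a prescribed number of motions
#'
#' Deterministic recipe realizing m stable rest points with
#' \eqn{z_j \in (j - 1 + \beta, j + \beta)}: sharp logistic satellites
#' (`b_tilde = 50`) thresholded at \eqn{z = i - 1 + \beta/2} turn the
#' staircase step i on just before each target interval; equal hub gains
#' `a` and a hub threshold centered on the staircase make the plateau
#' heights nearly linear in the step index, so one decay slope
#' \eqn{\xi \bar\lambda} can cross every plateau inside its interval.
#' The admissible \eqn{\xi} interval is calibrated numerically with
#' [find_rest_points()], as is the smallest \eqn{\xi} beyond the interval
#' at which a single stable point survives.
#'
#' @param m Number of motions (stable rest points), >= 1.
#' @param beta Interval offset in (0, 1).
#' @param kappa Satellite timescale (default 0.05).
#' @param b_gain Satellite sigmoid gain (default 50).
#' @param gain_grid Hub-gain candidates tried during calibration.
#' @return A list: `module` (at the calibrated midpoint `xi`),
#'   `xi_interval` (numerically verified multistable range),
#'   `xi_single` (a value with exactly one stable point), `beta`.
#' @export
construct_switch <- function(m, beta = 0.5, kappa = 0.05, b_gain = 50,
                             gain_grid = c(1, 0.8, 1.2, 0.6, 1.5, 0.5, 2)) {
  m <- as.integer(m)
  if (m < 1L) mn_stop("m must be >= 1", "mn_invalid_parameter")
  if (!is_number(beta) || beta <= 0 || beta >= 1)
    mn_stop("beta must lie in (0, 1)", "mn_invalid_parameter")
  lower <- seq_len(m) - 1 + beta
  upper <- seq_len(m) + beta
  check <- function(module, xi) {
    rp <- find_rest_points(module, xi = xi)
    st <- rp$points[rp$points$stable, , drop = FALSE]
    nrow(st) == m && all(rp$points$hyperbolic) &&
      all(st$z > lower & st$z < upper)
  }
  for (a in gain_grid) {
    module <- switching_module(
      a_tilde = rep(a, m), b_tilde = rep(b_gain, m),
      h_tilde = b_gain * (seq_len(m) - 1 + beta / 2),
      h = a * (m + 1) / 2, kappa = kappa, lambda_bar = 1)
    # plateau heights after j staircase steps; feasible decay slopes keep
    # each plateau crossing inside its target interval
    plateau <- sigmoid(a * seq_len(m) - module$h, "logistic")
    xi_lo <- max(plateau / upper)
    xi_hi <- min(plateau / lower)
    if (xi_lo >= xi_hi) next
    xi_grid <- seq(xi_lo, xi_hi, length.out = 25)
    ok <- vapply(xi_grid, function(x) check(module, x), logical(1))
    if (!any(ok)) next
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    best <- which.max(runs$lengths * runs$values)
    lo_i <- ends[best] - runs$lengths[best] + 1L
    xi_int <- c(xi_grid[lo_i], xi_grid[ends[best]])
    module$xi <- mean(xi_int)
    # smallest scanned xi above the interval with exactly one stable point
    xi_single <- NA_real_
    for (x in xi_int[2] * c(2, 4, 8, 16, 32, 64)) {
      rp <- find_rest_points(module, xi = x)
      if (sum(rp$points$stable) == 1L) { xi_single <- x; break }
    }
    if (is.na(xi_single)) next
    return(list(module = module, xi = module$xi, xi_interval = xi_int,
                xi_single = xi_single, beta = beta))
  }
  mn_stop(sprintf("switch calibration failed for m = %d, beta = %g over gains %s",
                  m, beta, paste(gain_grid, collapse = ", ")),
          "mn_construction_error")
}

#' Library of stored motions
#'
#' Associates each stable hub value (z-anchor) with the frequencies,
#' weights, and basis of a fitted motion; [select_motion()] performs the
#' nearest-anchor lookup, breaking midpoint ties toward the smaller
#' anchor.
#'
#' @param anchors Strictly increasing z-anchors.
#' @param models List of `motion_model`s, one per anchor.
#' @return A `motion_library`.
#' @export
motion_library <- function(anchors, models) {
  if (length(anchors) == 0L || length(anchors) != length(models))
    mn_stop("need one model per anchor", "mn_invalid_parameter")
  if (any(diff(anchors) <= 0))
    mn_stop("anchors must be strictly increasing", "mn_invalid_parameter")
  if (!all(vapply(models, inherits, logical(1), "motion_model")))
    mn_stop("models must be motion_model objects", "mn_invalid_parameter")
  structure(list(anchors = as.numeric(anchors), models = models),
            class = "motion_library")
}

#' @export
print.motion_library <- function(x, ...) {
  cat(sprintf("<motion_library> %d motion(s) at z = %s\n",
              length(x$anchors),
              paste(signif(x$anchors, 4), collapse = ", ")))
  invisible(x)
}

#' Select the stored motion nearest a hub value
#'
#' @param library A [motion_library()].
#' @param z Hub value.
#' @return The `motion_model` of the nearest anchor (ties toward the
#'   smaller anchor), with attributes `anchor` and `index`.
#' @export
select_motion <- function(library, z) {
  stopifnot(inherits(library, "motion_library"))
  d <- abs(library$anchors - z)
  i <- which(d <= min(d) + 0)[1]
  out <- library$models[[i]]
  attr(out, "anchor") <- library$anchors[i]
  attr(out, "index") <- i
  out
}

#' Run the global switched motion model
#'
#' Piecewise generation: for each scheduled epoch the switching module is
#' integrated at the scheduled control value until it settles, the stored
#' motion nearest the settled hub value is selected, and its network
#' output is emitted for the epoch duration (each epoch restarts the
#' oscillators at the pinned phase). The oscillators never feed back on
#' the switch. If the hub has not settled near a stable rest point by the
#' end of the settle horizon, a warning is raised and the nearest anchor
#' is used regardless.
#'
#' @param library A [motion_library()].
#' @param switch_fit Result of [construct_switch()] (or a list with
#'   `module`, `xi`, `xi_single`).
#' @param schedule Data frame with columns `xi` (control value during the
#'   epoch) and `duration` (seconds of emitted motion). Zero rows produce
#'   an empty trajectory.
#' @param rate Output sampling rate in Hz (default 120).
#' @param settle Switch settle horizon per epoch (default 60 time units).
#' @param z0 Initial hub value (default 0).
#' @return A list: `trajectory` (K x C matrix of generated channels with
#'   a `times` attribute), `epochs` (per epoch: settled z, selected
#'   anchor/index), and the final switch state.
#' @export
run_global_model <- function(library, switch_fit, schedule, rate = 120,
                             settle = 60, z0 = 0) {
  stopifnot(inherits(library, "motion_library"))
  module <- switch_fit$module
  if (is.null(schedule) || nrow(schedule) == 0L) {
    return(list(trajectory = matrix(0, 0, nrow(library$models[[1]]$W)),
                epochs = data.frame(), state = lift_state(z0, module)))
  }
  state <- lift_state(z0, module)
  out <- NULL; times_all <- NULL; t_off <- 0
  epochs <- list()
  for (e in seq_len(nrow(schedule))) {
    path <- simulate_switch(module, state, horizon = settle,
                            xi = schedule$xi[e])
    state <- as.numeric(path[nrow(path), -1])
    z_end <- state[module$m + 1L]
    rp <- find_rest_points(module, xi = schedule$xi[e])
    stable_z <- rp$points$z[rp$points$stable]
    if (!length(stable_z) || min(abs(stable_z - z_end)) > 1e-3)
      warning("switch had not settled at a stable rest point; using nearest anchor")
    model <- select_motion(library, z_end)
    dur <- schedule$duration[e]
    if (dur > 0) {
      tt <- seq(0, dur - 1 / rate, by = 1 / rate)
      pred <- predict(model, model$t0 + tt)
      out <- rbind(out, pred)
      times_all <- c(times_all, t_off + tt)
      t_off <- t_off + dur
    }
    epochs[[e]] <- data.frame(epoch = e, xi = schedule$xi[e],
                              z = z_end, anchor = attr(model, "anchor"),
                              index = attr(model, "index"))
  }
  if (is.null(out)) out <- matrix(0, 0, nrow(library$models[[1]]$W))
  attr(out, "times") <- times_all
  list(trajectory = out, epochs = do.call(rbind, epochs), state = state)
}
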