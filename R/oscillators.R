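#' Bank of oscillator centers
#'
#' The centers of the network are independent oscillators. Harmonic centers
#' obey \eqn{d^2 q_i/dt^2 + \omega_i^2 q_i = 0} and are evaluated in closed
#' form. Nonlinear centers obey \eqn{d^2 q_i/dt^2 + z_{c,i} f(q_i) = 0} with
#' \eqn{f(q) = \sin q} (pendulum) or \eqn{f(q) = a q - b q^3} (Duffing) and
#' are integrated numerically. All centers start from \eqn{q_i(0) = 0},
#' \eqn{p_i(0) = p_0}, so the trajectory phase is pinned at the time origin
#' and amplitude/phase freedom is absorbed by the satellite weights.
#'
#' Frequencies are stored in rad/s; use [hz()] / [rad_s()] to convert
#' user-facing Hz values.
#'
#' @param kind `"harmonic"` or `"nonlinear"`.
#' @param omega Angular frequencies (rad/s), one per center; harmonic kind
#'   only. All must be positive.
#' @param z_c Positive control parameters, one per center; nonlinear kind
#'   only.
#' @param nonlinearity `"pendulum"` or `"duffing"` (nonlinear kind).
#' @param duffing_a,duffing_b Coefficients of the Duffing restoring force
#'   \eqn{f(q) = a q - b q^3}.
#' @param p0 Initial momentum per center. For harmonic centers the default
#'   `p0 = omega` gives unit-amplitude \eqn{q_i(t) = \sin(\omega_i t)}; for
#'   nonlinear centers `p0` sets the orbit amplitude and must be supplied
#'   (recycled to the number of centers).
#'
#' @return An object of class `oscillator_bank` with fields `n`, `kind`,
#'   `omega` or `z_c`, `nonlinearity`, `p0`.
#' @export
#' @examples
#' oscillator_bank(omega = rad_s(c(0.3, 0.72)))
#' oscillator_bank("nonlinear", z_c = 1, nonlinearity = "pendulum", p0 = 0.5)
oscillator_bank <- function(kind = c("harmonic", "nonlinear"), omega = NULL,
                            z_c = NULL, nonlinearity = c("pendulum", "duffing"),
                            duffing_a = 1, duffing_b = 0, p0 = NULL) {
  kind <- match.arg(kind)
  if (kind == "harmonic") {
    if (is.null(omega) || length(omega) < 1L || any(!is.finite(omega)) ||
        any(omega <= 0))
      mn_stop("harmonic bank needs positive frequencies omega (rad/s)",
              "mn_invalid_parameter")
    n <- length(omega)
    if (is.null(p0)) p0 <- omega
    p0 <- rep_len(as.numeric(p0), n)
    bank <- list(n = n, kind = kind, omega = as.numeric(omega), p0 = p0)
  } else {
    nonlinearity <- match.arg(nonlinearity)
    if (is.null(z_c) || length(z_c) < 1L || any(!is.finite(z_c)) || any(z_c <= 0))
      mn_stop("nonlinear bank needs positive control parameters z_c",
              "mn_invalid_parameter")
    if (is.null(p0))
      mn_stop("nonlinear bank needs initial momentum p0", "mn_invalid_parameter")
    n <- length(z_c)
    p0 <- rep_len(as.numeric(p0), n)
    bank <- list(n = n, kind = kind, z_c = as.numeric(z_c),
                 nonlinearity = nonlinearity,
                 duffing_a = duffing_a, duffing_b = duffing_b, p0 = p0)
  }
  structure(bank, class = "oscillator_bank")
}

#' @export
print.oscillator_bank <- function(x, ...) {
  if (x$kind == "harmonic") {
    cat(sprintf("<oscillator_bank> %d harmonic center(s), f = %s Hz\n",
                x$n, paste(signif(hz(x$omega), 6), collapse = ", ")))
  } else {
    cat(sprintf("<oscillator_bank> %d nonlinear center(s) [%s], z_c = %s, p0 = %s\n",
                x$n, x$nonlinearity,
                paste(signif(x$z_c, 6), collapse = ", "),
                paste(signif(x$p0, 6), collapse = ", ")))
  }
  invisible(x)
}

#' Convert between Hz and rad/s
#'
#' @param x Numeric vector.
#' @return `hz(x)` returns `x / (2 pi)` (rad/s to Hz); `rad_s(x)` returns
#'   `x * 2 pi` (Hz to rad/s).
#' @export
hz <- function(x) x / (2 * pi)

#' @rdname hz
#' @export
rad_s <- function(x) x * 2 * pi

## restoring force f(q) and its antiderivative F(q) with F(0) = 0
restoring_force <- function(bank) {
  switch(bank$nonlinearity,
    pendulum = list(f = function(q) sin(q),
                    F = function(q) 1 - cos(q)),
    duffing  = {
      a <- bank$duffing_a; b <- bank$duffing_b
      list(f = function(q) a * q - b * q^3,
           F = function(q) a * q^2 / 2 - b * q^4 / 4)
    },
    mn_stop("unknown nonlinearity", "mn_invalid_parameter"))
}

new_center_states <- function(times, q, p) {
  q <- as.matrix(q); p <- as.matrix(p)
  structure(list(times = as.numeric(times), q = q, p = p),
            class = "center_states")
}

#' @export
print.center_states <- function(x, ...) {
  cat(sprintf("<center_states> %d centers x %d samples on [%g, %g] s\n",
              ncol(x$q), nrow(x$q), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Closed-form harmonic center trajectories
#'
#' Evaluates \eqn{q_i(t) = \sin(\omega_i t)} and
#' \eqn{p_i(t) = \omega_i \cos(\omega_i t)} (the unit-amplitude convention
#' `p0 = omega`; a different `p0` rescales both by `p0 / omega`). No
#' integration is involved.
#'
#' @param bank A harmonic [oscillator_bank()].
#' @param times Nonempty increasing vector of times (seconds).
#' @return A `center_states` object: `times`, K x n matrices `q` and `p`.
#' @export
harmonic_states <- function(bank, times) {
  stopifnot(inherits(bank, "oscillator_bank"))
  if (bank$kind != "harmonic")
    mn_stop("harmonic_states needs a harmonic bank", "mn_invalid_parameter")
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0))
    mn_stop("times must be nonempty and increasing", "mn_invalid_parameter")
  amp <- bank$p0 / bank$omega
  wt <- outer(times, bank$omega)
  q <- sweep(sin(wt), 2, amp, `*`)
  p <- sweep(cos(wt), 2, amp * bank$omega, `*`)
  new_center_states(times, q, p)
}

#' Integrate nonlinear center trajectories
#'
#' Integrates \eqn{d^2 q/dt^2 + z_c f(q) = 0} from \eqn{(q, p) = (0, p_0)}
#' per center with an adaptive explicit Runge-Kutta scheme
#' (Dormand-Prince 4(5), `deSolve::ode(method = "ode45")`).
#'
#' @param bank A nonlinear [oscillator_bank()].
#' @param times Output times (seconds), nonempty, increasing, starting at 0.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @return A `center_states` object.
#' @export
simulate_nonlinear <- function(bank, times, rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(bank, "oscillator_bank"))
  if (bank$kind != "nonlinear")
    mn_stop("simulate_nonlinear needs a nonlinear bank", "mn_invalid_parameter")
  if (!is_number(rtol) || !is_number(atol) || rtol <= 0 || atol <= 0)
    mn_stop("tolerances must be positive", "mn_invalid_parameter")
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0))
    mn_stop("times must be nonempty and increasing", "mn_invalid_parameter")
  fr <- restoring_force(bank)
  K <- length(times)
  q <- matrix(NA_real_, K, bank$n)
  p <- matrix(NA_real_, K, bank$n)
  if (K == 1L && times[1] == 0) {
    q[1, ] <- 0
    p[1, ] <- bank$p0
    return(new_center_states(times, q, p))
  }
  t_out <- if (times[1] > 0) c(0, times) else times
  for (i in seq_len(bank$n)) {
    zc <- bank$z_c[i]
    rhs <- function(t, y, parms) list(c(y[2], -zc * fr$f(y[1])))
    out <- try(deSolve::ode(c(0, bank$p0[i]), t_out, rhs, parms = NULL,
                            method = "ode45", rtol = rtol, atol = atol),
               silent = TRUE)
    if (inherits(out, "try-error") || any(!is.finite(out)) ||
        nrow(out) < length(t_out))
      mn_stop(sprintf("integration failed for center %d (z_c = %g, p0 = %g)",
                      i, zc, bank$p0[i]), "mn_integration_error")
    keep <- if (times[1] > 0) -1L else TRUE
    q[, i] <- out[keep, 2]
    p[, i] <- out[keep, 3]
  }
  new_center_states(times, q, p)
}

#' Generic center-state evaluation
#'
#' Dispatches on the bank kind: closed form for harmonic centers, numerical
#' integration otherwise.
#'
#' @inheritParams simulate_nonlinear
#' @param ... Passed to [simulate_nonlinear()] for nonlinear banks.
#' @return A `center_states` object.
#' @export
center_states <- function(bank, times, ...) {
  if (bank$kind == "harmonic") harmonic_states(bank, times)
  else simulate_nonlinear(bank, times, ...)
}

#' Mechanical energy of nonlinear centers
#'
#' Computes the conserved motion integral
#' \eqn{E_i(t) = p_i^2/2 + F(q_i, z_{c,i})} with \eqn{F} the antiderivative
#' of \eqn{z_c f}, normalized so \eqn{F(0) = 0} (pendulum:
#' \eqn{F = z_c (1 - \cos q)}; Duffing:
#' \eqn{F = z_c (a q^2/2 - b q^4/4)}).
#'
#' @param states A `center_states` object.
#' @param bank The nonlinear [oscillator_bank()] that produced it.
#' @return K x n matrix of energies.
#' @export
energy <- function(states, bank) {
  stopifnot(inherits(states, "center_states"), inherits(bank, "oscillator_bank"))
  if (bank$kind != "nonlinear")
    mn_stop("energy is defined for nonlinear banks", "mn_invalid_parameter")
  if (ncol(states$q) != bank$n)
    mn_stop("states and bank disagree on the number of centers", "mn_shape_error")
  fr <- restoring_force(bank)
  E <- states$p^2 / 2
  for (i in seq_len(bank$n)) E[, i] <- E[, i] + bank$z_c[i] * fr$F(states$q[, i])
  E
}

#' Amplitude-dependent oscillation frequency of a nonlinear center
#'
#' The orbit of a nonlinear center through \eqn{(0, p_0)} is periodic; its
#' period is detected as the first return of the integrated orbit to
#' \eqn{q = 0} with \eqn{p > 0}, located by the integrator's own root
#' finding (`lsodar`), and the frequency is \eqn{\omega = 2\pi/T}.
#'
#' For the pendulum the orbit is closed (librating) only below the
#' separatrix energy \eqn{E < 2 z_c}; the rotating regime is rejected.
#'
#' @param bank A nonlinear [oscillator_bank()].
#' @param center_index Which center (default 1).
#' @param rtol,atol Integration tolerances.
#' @return Angular frequency in rad/s.
#' @export
oscillation_frequency <- function(bank, center_index = 1L,
                                  rtol = 1e-11, atol = 1e-13) {
  stopifnot(inherits(bank, "oscillator_bank"))
  if (bank$kind != "nonlinear")
    mn_stop("oscillation_frequency is defined for nonlinear banks",
            "mn_invalid_parameter")
  i <- as.integer(center_index)
  if (i < 1L || i > bank$n)
    mn_stop("center_index out of range", "mn_invalid_parameter")
  zc <- bank$z_c[i]; p0 <- bank$p0[i]
  if (bank$nonlinearity == "pendulum" && p0^2 / 2 >= 2 * zc)
    mn_stop("pendulum orbit is not closed (rotation regime: E >= 2 z_c)",
            "mn_domain_error")
  fr <- restoring_force(bank)
  rhs <- function(t, y, parms) list(c(y[2], -zc * fr$f(y[1])))
  # small-amplitude guess for the horizon; the true period can be much
  # longer near the separatrix, so extend geometrically until a full
  # return is seen
  w0 <- sqrt(max(zc * abs(if (bank$nonlinearity == "pendulum") 1
                          else bank$duffing_a), .Machine$double.eps))
  horizon <- 4 * 2 * pi / w0
  for (trial in 1:8) {
    out <- deSolve::ode(c(0, p0), c(0, horizon), rhs, parms = NULL,
                        method = "lsodar", rtol = rtol, atol = atol,
                        rootfunc = function(t, y, parms) y[1],
                        events = list(func = function(t, y, parms) y,
                                      root = TRUE))
    troot <- attr(out, "troot")
    valroot <- attr(out, "valroot")
    if (!is.null(troot)) {
      ok <- troot > 1e-9 * horizon & valroot[2, ] > 0
      if (any(ok)) return(2 * pi / troot[which(ok)[1]])
    }
    horizon <- horizon * 4
  }
  mn_stop("no full return to q = 0 with p > 0 found; orbit may not be closed",
          "mn_domain_error")
}
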