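#' Least-squares satellite weights
#'
#' Solves \eqn{\min_W \|Y - \Phi W^T\|_F^2 + \lambda \|W\|_F^2} for the
#' weight matrix W (rows = output channels, columns = satellites). At
#' `ridge = 0` the minimum-norm least-squares solution is returned
#' (SVD pseudoinverse with a rank cutoff at `1e-12` of the leading
#' singular value), which makes rank-deficient designs deterministic.
#'
#' @param design K x P design matrix (from [eval_basis()]).
#' @param targets K x C matrix of output channels.
#' @param ridge Nonnegative ridge penalty (absolute scale).
#' @return C x P weight matrix.
#' @export
fit_weights <- function(design, targets, ridge = 0) {
  design <- as.matrix(design); targets <- as.matrix(targets)
  if (any(!is.finite(design)) || any(!is.finite(targets)))
    mn_stop("non-finite values in design or targets", "mn_data_error")
  if (nrow(design) != nrow(targets))
    mn_stop("design and targets disagree on the number of frames", "mn_shape_error")
  if (!is_number(ridge) || ridge < 0)
    mn_stop("ridge must be a nonnegative scalar", "mn_invalid_parameter")
  if (ridge == 0) {
    sv <- svd(design)
    keep <- sv$d > 1e-12 * max(sv$d, 0) & sv$d > 0
    if (!any(keep)) return(matrix(0, ncol(targets), ncol(design),
                                  dimnames = list(colnames(targets),
                                                  colnames(design))))
    Wt <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% targets) / sv$d[keep])
  } else {
    G <- crossprod(design)
    diag(G) <- diag(G) + ridge
    Wt <- solve(G, crossprod(design, targets))
  }
  W <- t(Wt)
  dimnames(W) <- list(colnames(targets), colnames(design))
  W
}

## default ridge used by the fitters: a tiny multiple of the mean Gram
## diagonal, enough to stabilize nearly collinear radial columns without
## visibly biasing the fit
default_ridge <- function(design, rel = 1e-10) {
  rel * mean(colSums(design^2))
}

#' Fit a motion model at fixed center frequencies
#'
#' Builds the center trajectories at the given frequencies (time is taken
#' relative to the first frame so every fit starts at the pinned phase
#' q(0) = 0), places the satellite basis on them, and solves for the
#' weights of all requested markers in one least-squares problem.
#'
#' @param trajectory A [marker_trajectory()].
#' @param omega Angular frequencies of the harmonic centers (rad/s),
#'   length n.
#' @param markers Markers to fit (default all).
#' @param basis A [basis_config()] (or arguments for one via `n_m`).
#' @param n_m Convenience: satellite count for a default Gaussian-rbf
#'   basis when `basis` is not given.
#' @param ridge Ridge penalty; `NULL` (default) uses
#'   `1e-10 * mean(diag(Gram))`.
#' @return A `motion_model`: fields `bank`, `basis`, `W`, `channels`,
#'   `t0`, plus the `report` from [accuracy_report()].
#' @export
fit_motion <- function(trajectory, omega, markers = trajectory$markers,
                       basis = NULL, n_m = 25L, ridge = NULL) {
  stopifnot(inherits(trajectory, "marker_trajectory"))
  omega <- sort(as.numeric(omega))
  bank <- oscillator_bank(omega = omega)
  if (is.null(basis)) basis <- basis_config("rbf", n_m = n_m)
  tau <- trajectory$times - trajectory$times[1]
  states <- harmonic_states(bank, tau)
  Phi <- eval_basis(states, basis)
  basis <- attr(Phi, "config")
  Y <- channel_matrix(trajectory, markers)
  if (is.null(ridge)) ridge <- default_ridge(Phi)
  W <- fit_weights(Phi, Y, ridge)
  model <- structure(
    list(bank = bank, basis = basis, W = W,
         channels = data.frame(marker = rep(markers, each = 3L),
                               axis = rep(c("x", "y", "z"), length(markers)),
                               stringsAsFactors = FALSE),
         t0 = trajectory$times[1], units = trajectory$units),
    class = "motion_model")
  model$report <- accuracy_report(trajectory, predict(model, trajectory$times),
                                  markers)
  model
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf("<motion_model> %d center(s) @ %s Hz, %d satellite(s) [%s], %d channel(s)\n",
              x$bank$n,
              paste(signif(hz(x$bank$omega), 4), collapse = "/"),
              x$basis$n_m, x$basis$family, nrow(x$W)))
  if (!is.null(x$report))
    cat(sprintf("  integral relative accuracy (rms over markers): %.4g\n",
                sqrt(mean(x$report$eps_r^2))))
  invisible(x)
}

#' Predict marker channels from a motion model
#'
#' Evaluates \eqn{x_k(t) = \sum_j W_{kj} \Phi_j(q(t))} with the model's own
#' oscillator bank and basis. Times are absolute; the model's stored time
#' origin `t0` pins the oscillator phase.
#'
#' @param object A `motion_model`.
#' @param times Times (seconds) at which to evaluate.
#' @param ... Unused.
#' @return K x C matrix of predicted channels (named as in the fit).
#' @export
predict.motion_model <- function(object, times, ...) {
  tau <- as.numeric(times) - object$t0
  states <- center_states(object$bank, tau)
  Phi <- eval_basis(states, object$basis)
  out <- Phi %*% t(object$W)
  colnames(out) <- rownames(object$W)
  out
}

#' Fit-accuracy report
#'
#' Per marker k and axis X, the squared error is
#' \eqn{\epsilon_X^2(k) = \sum_m (X_k(t_m) - \hat x_k(t_m))^2}; the
#' relative form divides by the raw second moment \eqn{\sum_m X_k(t_m)^2}
#' (uncentered, so offsets inflate the denominator -- a documented
#' property of the criterion, not a bug). The integral relative accuracy
#' is the mean of the three squared relative errors,
#' \eqn{\epsilon_{r,k}^2 = (\epsilon_{r,X}^2 + \epsilon_{r,Y}^2 +
#' \epsilon_{r,Z}^2)/3}, reported both squared (`eps_r2`) and as its
#' square root (`eps_r`). `abs_err` is the mean per-frame Euclidean
#' distance between observed and predicted 3-D position, in input units.
#'
#' @param trajectory A [marker_trajectory()] with the observed channels.
#' @param predicted K x C matrix of predictions with columns named
#'   `<marker>.<axis>` (as returned by [predict.motion_model()]).
#' @param markers Markers to report on (default all in the trajectory).
#' @return Data frame with one row per marker: `marker`, `eps2_x/y/z`,
#'   `eps2_rx/ry/rz`, `eps_r2`, `eps_r`, `abs_err`.
#' @export
accuracy_report <- function(trajectory, predicted,
                            markers = trajectory$markers) {
  stopifnot(inherits(trajectory, "marker_trajectory"))
  predicted <- as.matrix(predicted)
  if (nrow(predicted) != length(trajectory$times))
    mn_stop("predicted and observed frame counts differ", "mn_shape_error")
  rows <- lapply(markers, function(nm) {
    obs <- trajectory$coords[[nm]]
    cols <- paste0(nm, ".", c("x", "y", "z"))
    if (!all(cols %in% colnames(predicted)))
      mn_stop(sprintf("predictions lack channels for marker '%s'", nm),
              "mn_shape_error")
    prd <- predicted[, cols, drop = FALSE]
    e2 <- colSums((obs - prd)^2)
    den <- colSums(obs^2)
    if (any(den == 0))
      mn_stop(sprintf("marker '%s': axis %s has zero second moment; relative accuracy undefined",
                      nm, paste(c("X", "Y", "Z")[den == 0], collapse = ",")),
              "mn_degenerate_channel")
    r2 <- e2 / den
    data.frame(marker = nm,
               eps2_x = e2[1], eps2_y = e2[2], eps2_z = e2[3],
               eps2_rx = r2[1], eps2_ry = r2[2], eps2_rz = r2[3],
               eps_r2 = mean(r2), eps_r = sqrt(mean(r2)),
               abs_err = mean(sqrt(rowSums((obs - prd)^2))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Corrected Akaike information criterion for a least-squares fit
#'
#' \deqn{AICc = n \ln(RSS/n) + 2k + 2k(k+1)/(n - k - 1)}
#' with n observations and k estimated parameters. For motion models, k
#' counts every fitted weight plus the searched frequencies, and n is the
#' total number of scalar residuals (3 K per marker).
#'
#' @param rss Residual sum of squares, > 0.
#' @param n_obs Number of observations.
#' @param k_params Number of parameters; requires `n_obs - k_params - 1 > 0`.
#' @return AICc value.
#' @export
aicc <- function(rss, n_obs, k_params) {
  if (!is_number(rss) || rss <= 0)
    mn_stop("rss must be positive", "mn_invalid_parameter")
  if (n_obs - k_params - 1 <= 0)
    mn_stop("AICc undefined: need n_obs > k_params + 1", "mn_small_sample")
  n_obs * log(rss / n_obs) + 2 * k_params +
    2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
}
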