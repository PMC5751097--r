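#' Satellite basis configuration
#'
#' Each satellite computes one basis function of the center-state vector
#' \eqn{q \in R^n}. Three families are supported:
#' \describe{
#'   \item{`"rbf"` (B)}{Gaussian radial units
#'     \eqn{\Phi_j(q) = \exp(-b^2 |q - \bar q^{(j)}|^2 / 2)} with Euclidean
#'     norm, sharpness `b` and per-satellite centers `centers`. The design
#'     matrix gets a constant intercept column appended by default
#'     (`intercept = TRUE`) so channel offsets need not be carried by the
#'     radial units; set `intercept = FALSE` for the bare map.}
#'   \item{`"harmonic"` (A)}{Cosine units
#'     \eqn{\Phi_j(q) = \cos(b_j \langle q, u\rangle)} with
#'     \eqn{b_j = (j-1) \pi / x_0} (the cosine series on `[-x0, x0]`,
#'     whose first member is the constant term), applied to the
#'     projection of `q` onto the unit vector `u` (default: first
#'     coordinate axis); `x0` is the characteristic maximal amplitude of
#'     the projected motion.}
#'   \item{`"polynomial"` (C)}{Monomials \eqn{\Phi_j(q) = q^{j-1}}, scalar
#'     centers only (`n = 1`).}
#' }
#'
#' @param family `"rbf"`, `"harmonic"` or `"polynomial"`.
#' @param n_m Number of satellites (basis functions), >= 1.
#' @param b Sharpness (rbf) or base frequency scale (harmonic). For the rbf
#'   family `NULL` means "derive from the centers" via [default_sharpness()].
#' @param centers N_m x n matrix of radial centers (rbf family only).
#' @param x0 Amplitude normalization of the harmonic family (default 1, the
#'   amplitude of unit harmonic centers).
#' @param u Projection direction for the harmonic family (unit vector of
#'   length n, default first axis).
#' @param intercept Append a constant column (rbf family only; default TRUE).
#' @return An object of class `basis_config`.
#' @export
basis_config <- function(family = c("rbf", "harmonic", "polynomial"),
                         n_m, b = NULL, centers = NULL, x0 = 1, u = NULL,
                         intercept = TRUE) {
  family <- match.arg(family)
  n_m <- as.integer(n_m)
  if (n_m < 1L) mn_stop("n_m must be >= 1", "mn_invalid_parameter")
  if (!is.null(b) && (!is_number(b) || b <= 0))
    mn_stop("b must be a positive scalar", "mn_invalid_parameter")
  if (family == "rbf") {
    if (!is.null(centers)) {
      centers <- as.matrix(centers)
      if (nrow(centers) != n_m)
        mn_stop("centers must have n_m rows", "mn_shape_error")
    }
  } else {
    if (!is.null(centers))
      mn_stop("centers are only meaningful for the rbf family", "mn_invalid_parameter")
    intercept <- FALSE
  }
  if (family == "harmonic" && (!is_number(x0) || x0 <= 0))
    mn_stop("x0 must be a positive scalar", "mn_invalid_parameter")
  structure(list(family = family, n_m = n_m, b = b, centers = centers,
                 x0 = x0, u = u, intercept = isTRUE(intercept)),
            class = "basis_config")
}

#' @export
print.basis_config <- function(x, ...) {
  cat(sprintf("<basis_config> family %s, %d satellite(s)%s%s\n",
              x$family, x$n_m,
              if (!is.null(x$b)) sprintf(", b = %.6g", x$b) else "",
              if (x$intercept) ", +intercept" else ""))
  invisible(x)
}

#' Gaussian radial basis function
#'
#' @param r Nonnegative radius (vectorized).
#' @return `exp(-r^2 / 2)`, in (0, 1].
#' @export
gaussian_rbf <- function(r) {
  if (any(!is.finite(r)) || any(r < 0))
    mn_stop("radius must be finite and nonnegative", "mn_invalid_argument")
  exp(-r^2 / 2)
}

#' Sigmoid functions used by the switching module
#'
#' Both choices are smooth, strictly increasing, and saturate at 0 and 1:
#' the logistic \eqn{1/(1+e^{-h})} and the algebraic
#' \eqn{(h/\sqrt{1+h^2} + 1)/2}. Overflow-safe for `|h|` up to at least 1e6.
#'
#' @param h Numeric vector.
#' @param kind `"logistic"` or `"algebraic"`.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(h, kind = c("logistic", "algebraic")) {
  kind <- match.arg(kind)
  if (kind == "logistic") plogis(h) else (h / sqrt(1 + h^2) + 1) / 2
}

#' Place radial centers along the center-state trajectory
#'
#' Centers \eqn{\bar q^{(j)}} are the center states sampled at `n_m` time
#' indices equally spaced over the segment (first and last frames
#' included), with exact duplicate rows removed. Deterministic.
#'
#' @param q_states A `center_states` object (or a K x n matrix of states).
#' @param n_m Number of centers requested; needs K >= n_m samples.
#' @return Matrix of centers (rows), at most `n_m` after deduplication.
#' @export
place_centers <- function(q_states, n_m) {
  q <- if (inherits(q_states, "center_states")) q_states$q else as.matrix(q_states)
  K <- nrow(q)
  n_m <- as.integer(n_m)
  if (K < n_m)
    mn_stop(sprintf("need at least n_m = %d samples, have %d", n_m, K),
            "mn_insufficient_samples")
  idx <- center_indices(K, n_m)
  centers <- q[idx, , drop = FALSE]
  centers[!duplicated(centers), , drop = FALSE]
}

## equally spaced 1-based indices, first and last included
center_indices <- function(K, n_m) {
  if (n_m == 1L) return(1L)
  unique(as.integer(round(seq(1, K, length.out = n_m))))
}

#' Default radial sharpness from the center layout
#'
#' `b` is the reciprocal of the median nearest-neighbour Euclidean distance
#' among the centers, so neighbouring radial bumps overlap at order one
#' standard deviation. Exact duplicate centers are ignored when measuring
#' spacing.
#'
#' @param centers Matrix of centers (rows).
#' @return Positive scalar sharpness.
#' @export
default_sharpness <- function(centers) {
  centers <- as.matrix(centers)
  centers <- centers[!duplicated(centers), , drop = FALSE]
  if (nrow(centers) < 2L)
    mn_stop("need at least 2 distinct centers to set a sharpness",
            "mn_degenerate_centers")
  d <- as.matrix(dist(centers))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  b <- 1 / median(nn)
  if (!is.finite(b) || b <= 0)
    mn_stop("degenerate center layout", "mn_degenerate_centers")
  b
}

#' Evaluate the satellite design matrix
#'
#' Maps K sampled center states through the satellite basis, producing the
#' K x N_m design matrix (K x (N_m + 1) when the rbf intercept is on).
#'
#' @param q_states A `center_states` object or K x n matrix.
#' @param config A [basis_config()]. For the rbf family with `centers =
#'   NULL`, centers are placed on the trajectory via [place_centers()] and
#'   a missing `b` is derived via [default_sharpness()]; the resolved
#'   config is attached as attribute `"config"`.
#' @return Design matrix with attribute `"config"` (the fully resolved
#'   [basis_config()]).
#' @export
eval_basis <- function(q_states, config) {
  stopifnot(inherits(config, "basis_config"))
  q <- if (inherits(q_states, "center_states")) q_states$q else as.matrix(q_states)
  K <- nrow(q); n <- ncol(q)
  Phi <- switch(config$family,
    rbf = {
      centers <- config$centers
      if (is.null(centers)) centers <- place_centers(q, config$n_m)
      if (ncol(centers) != n)
        mn_stop("center dimension does not match the state dimension",
                "mn_shape_error")
      b <- config$b
      if (is.null(b)) b <- default_sharpness(centers)
      config$centers <- centers
      config$n_m <- nrow(centers)
      config$b <- b
      d2 <- outer(rowSums(q^2), rowSums(centers^2), `+`) -
        2 * q %*% t(centers)
      d2[d2 < 0] <- 0
      M <- exp(-b^2 * d2 / 2)
      if (config$intercept) M <- cbind(M, 1)
      M
    },
    polynomial = {
      if (n > 1L)
        mn_stop("polynomial basis is defined for scalar centers (n = 1) only",
                "mn_unsupported_dimension")
      outer(drop(q), seq_len(config$n_m) - 1L, `^`)
    },
    harmonic = {
      u <- config$u
      if (is.null(u)) u <- c(1, rep(0, n - 1L))
      if (length(u) != n)
        mn_stop("projection vector u must have length n", "mn_shape_error")
      u <- u / sqrt(sum(u^2))
      s <- drop(q %*% u)
      bj <- (seq_len(config$n_m) - 1L) * pi / config$x0
      if (!is.null(config$b)) bj <- bj * config$b
      cos(outer(s, bj))
    })
  colnames(Phi) <- c(paste0("phi", seq_len(ncol(Phi) - config$intercept)),
                     if (config$intercept) "intercept")
  attr(Phi, "config") <- config
  Phi
}

#' @importFrom stats plogis dist
NULL
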