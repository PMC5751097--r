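#' Frequency-search configurations
#'
#' The center frequencies are found by minimizing the integral relative
#' accuracy over candidate frequency vectors. `search_grid()` describes an
#' exhaustive search over a uniform Hz grid (practical for n <= 2 centers,
#' where candidates are all non-decreasing frequency tuples);
#' `search_random()` draws `budget` frequency vectors uniformly from
#' `[lo, hi]^n` under a mandatory seed (for n >= 3).
#'
#' The default grid 0.05--5 Hz in steps of 0.01 Hz brackets the slow
#' (~0.3 Hz) and fast (~0.7 Hz) components typical of whole-body motion
#' while resolving them to the grid step.
#'
#' @param lo,hi Grid bounds in Hz.
#' @param step Grid step in Hz.
#' @param budget Number of random draws.
#' @param seed Integer seed (required for the random search).
#' @return A search-configuration list.
#' @export
search_grid <- function(lo = 0.05, hi = 5, step = 0.01) {
  if (!is_number(lo) || !is_number(hi) || !is_number(step) ||
      lo <= 0 || step <= 0 || hi < lo)
    mn_stop("invalid frequency grid", "mn_config_error")
  structure(list(type = "grid", lo = lo, hi = hi, step = step),
            class = "mn_search")
}

#' @rdname search_grid
#' @export
search_random <- function(lo = 0.05, hi = 5, budget = 2000, seed) {
  if (missing(seed) || !is_number(seed))
    mn_stop("random search requires an explicit integer seed", "mn_config_error")
  if (!is_number(budget) || budget < 1)
    mn_stop("budget must be >= 1", "mn_config_error")
  structure(list(type = "random", lo = lo, hi = hi,
                 budget = as.integer(budget), seed = as.integer(seed)),
            class = "mn_search")
}

## candidate frequency vectors in Hz, rows sorted ascending, lexicographic
## row order (so ties resolve to the smallest tuple)
candidate_frequencies <- function(search, n) {
  if (search$type == "grid") {
    g <- seq(search$lo, search$hi, by = search$step)
    if (length(g) == 0) mn_stop("empty frequency grid", "mn_config_error")
    if (n == 1L) {
      cand <- matrix(g, ncol = 1)
    } else if (n == 2L) {
      idx <- which(outer(seq_along(g), seq_along(g), `<=`), arr.ind = TRUE)
      cand <- cbind(g[idx[, 1]], g[idx[, 2]])
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    } else {
      mn_stop("exhaustive grid search is supported for n <= 2 centers; use search_random()",
              "mn_config_error")
    }
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(search$seed)
    cand <- matrix(runif(search$budget * n, search$lo, search$hi),
                   ncol = n)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    cand <- t(apply(cand, 1, sort))
    if (n == 1L) cand <- matrix(cand, ncol = 1)
    cand <- cand[do.call(order, split(cand, col(cand))), , drop = FALSE]
  }
  cand
}

## evaluate the search objective for all candidates: per-channel relative
## squared errors (ncand x C). The Gaussian-rbf family runs through the
## compiled kernel; other families fall back to a plain R loop over
## candidates (intended for modest grids).
objective_channels <- function(trajectory, markers, cand_hz, n_m,
                               intercept = TRUE, ridge_rel = 1e-10,
                               basis_template = NULL) {
  Y <- channel_matrix(trajectory, markers)
  tau <- trajectory$times - trajectory$times[1]
  K <- length(tau)
  if (K < n_m)
    mn_stop(sprintf("segment of %d frames is shorter than n_m = %d satellites",
                    K, n_m), "mn_insufficient_samples")
  if (is.null(basis_template) || basis_template$family == "rbf") {
    idx <- center_indices(K, n_m)
    return(.rel_err_grid_cpp(tau, Y, rad_s(cand_hz), idx, intercept,
                             ridge_rel))
  }
  den <- colSums(Y^2)
  out <- matrix(NA_real_, nrow(cand_hz), ncol(Y))
  for (i in seq_len(nrow(cand_hz))) {
    bank <- oscillator_bank(omega = rad_s(cand_hz[i, ]))
    Phi <- eval_basis(harmonic_states(bank, tau), basis_template)
    W <- fit_weights(Phi, Y, default_ridge(Phi, ridge_rel))
    out[i, ] <- colSums((Y - Phi %*% t(W))^2) / den
  }
  out
}

## pick the minimizing row with a lexicographic tie-break: all candidates
## within a 1e-12 relative band of the minimum count as tied, and the
## first (lexicographically smallest, by construction) wins
argmin_lex <- function(values) {
  v <- ifelse(is.finite(values), values, Inf)
  m <- min(v)
  which(v <= m + 1e-12 * (1 + abs(m)))[1]
}

#' Search center frequencies for one marker
#'
#' For every candidate frequency vector the harmonic centers are
#' evaluated, the satellite basis is placed on their trajectory, the
#' weights are fit by least squares, and the integral relative accuracy
#' \eqn{\epsilon_{r,k}^2(\omega)} of the marker is computed; the
#' minimizing vector is returned (frequencies sorted ascending; exact
#' ties resolve to the lexicographically smallest tuple).
#'
#' @param trajectory A [marker_trajectory()].
#' @param marker Marker name whose channels drive the search.
#' @param n Number of centers (1--5).
#' @param search A [search_grid()] (n <= 2) or [search_random()] config.
#' @param n_m Satellite count of the basis.
#' @param basis Optional [basis_config()] template overriding the default
#'   Gaussian-rbf basis (its radial centers, if any, are re-placed on each
#'   candidate's center trajectory; non-rbf families are evaluated by a
#'   plain R loop and suit modest grids).
#' @param intercept Include the intercept column (rbf family; default TRUE).
#' @param ridge_rel Relative ridge used during the search (default 1e-10
#'   of the mean Gram diagonal).
#' @return A `fit_result`: `omega` (rad/s, sorted), `omega_hz`, `model`
#'   (the final [fit_motion()] at the optimum), `report`, `objective`
#'   (the minimized \eqn{\epsilon_{r,k}^2}), and the search `trace`
#'   (candidates in Hz with their objective values).
#' @export
search_frequencies <- function(trajectory, marker, n = 2L,
                               search = search_grid(), n_m = 25L,
                               basis = NULL, intercept = TRUE,
                               ridge_rel = 1e-10) {
  stopifnot(inherits(trajectory, "marker_trajectory"),
            inherits(search, "mn_search"))
  n <- as.integer(n)
  if (n < 1L || n > 5L)
    mn_stop("n must be between 1 and 5 centers", "mn_config_error")
  if (length(marker) != 1L || !marker %in% trajectory$markers)
    mn_stop("marker must name one marker of the trajectory", "mn_data_error")
  if (is.null(basis)) basis <- basis_config("rbf", n_m = n_m,
                                            intercept = intercept)
  cand <- candidate_frequencies(search, n)
  rel <- objective_channels(trajectory, marker, cand, basis$n_m,
                            basis$intercept, ridge_rel, basis)
  obj <- rowMeans(rel)
  best <- argmin_lex(obj)
  omega_hz <- cand[best, ]
  model <- fit_motion(trajectory, rad_s(omega_hz), markers = marker,
                      basis = basis)
  structure(
    list(omega = rad_s(omega_hz), omega_hz = omega_hz, marker = marker,
         model = model, report = model$report,
         objective = model$report$eps_r2[1],
         trace = data.frame(cand_hz = I(cand), eps_r2 = obj)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> marker %s: f* = %s Hz, eps_r = %.4g (%d candidates)\n",
              paste(x$marker, collapse = "+"),
              paste(signif(x$omega_hz, 4), collapse = "/"),
              sqrt(x$objective), nrow(x$trace)))
  invisible(x)
}

#' Search center frequencies averaged over markers
#'
#' Same search as [search_frequencies()] but the objective is the sum over
#' markers of the per-marker integral relative accuracies,
#' \eqn{\sum_k \epsilon_{r,k}^2(\omega)}.
#'
#' @inheritParams search_frequencies
#' @param markers Markers entering the summed objective (default all).
#' @return A `fit_result` whose model carries all requested markers.
#' @export
average_marker_search <- function(trajectory, markers = trajectory$markers,
                                  n = 2L, search = search_grid(), n_m = 25L,
                                  intercept = TRUE, ridge_rel = 1e-10) {
  stopifnot(inherits(trajectory, "marker_trajectory"))
  cand <- candidate_frequencies(search, as.integer(n))
  rel <- objective_channels(trajectory, markers, cand, n_m,
                            intercept, ridge_rel)
  M <- length(markers)
  per_marker <- sapply(seq_len(M), function(k)
    rowMeans(rel[, 3 * (k - 1) + 1:3, drop = FALSE]))
  obj <- if (M == 1L) drop(per_marker) else rowSums(per_marker)
  best <- argmin_lex(obj)
  omega_hz <- cand[best, ]
  model <- fit_motion(trajectory, rad_s(omega_hz), markers = markers,
                      basis = basis_config("rbf", n_m = n_m,
                                           intercept = intercept))
  structure(
    list(omega = rad_s(omega_hz), omega_hz = omega_hz, marker = markers,
         model = model, report = model$report,
         objective = sum(model$report$eps_r2),
         trace = data.frame(cand_hz = I(cand), objective = obj)),
    class = "fit_result")
}

#' Transfer learned frequencies to other markers
#'
#' Keeps the frequency vector fixed and refits only the satellite weights
#' for each requested marker, returning their accuracies. This is the
#' cross-marker transfer step: frequencies learned from one marker serve
#' all markers driven by the same centers.
#'
#' @param fit A `fit_result` (or a numeric frequency vector in rad/s).
#' @param trajectory A [marker_trajectory()].
#' @param markers Markers to refit (default all).
#' @inheritParams search_frequencies
#' @return A `motion_model` covering `markers`, with its `report`.
#' @export
transfer_fit <- function(fit, trajectory, markers = trajectory$markers,
                         n_m = 25L, intercept = TRUE) {
  omega <- if (inherits(fit, "fit_result")) fit$omega else as.numeric(fit)
  fit_motion(trajectory, omega, markers = markers,
             basis = basis_config("rbf", n_m = n_m, intercept = intercept))
}

#' Fit a segmented motion
#'
#' Splits the motion at the given frame boundaries, runs an independent
#' frequency search per segment (each with its own time origin, so every
#' segment starts at the pinned oscillator phase), and assembles the
#' piecewise prediction. Boundaries follow the 1-based convention
#' `T_1 < ... < T_{Nseg+1}`: segment i covers frames `[T_i, T_{i+1})`,
#' the last segment is closed (and `T_{Nseg+1} = K + 1` is accepted as
#' "up to the end").
#'
#' @param trajectory A [marker_trajectory()].
#' @param boundaries Integer frame boundaries, length Nseg + 1.
#' @param marker Marker driving the per-segment searches.
#' @inheritParams search_frequencies
#' @return A `segmented_fit`: per-segment `fits` (list of `fit_result`),
#'   `frames` (per-segment first/last frame), the assembled K x C
#'   `prediction`, a `seams` data frame (per boundary: predicted
#'   inter-frame jump, in input units), and `total_rss`.
#' @export
fit_segmented <- function(trajectory, boundaries, marker, n = 1L,
                          search = search_grid(), n_m = 25L,
                          intercept = TRUE, ridge_rel = 1e-10) {
  K <- length(trajectory$times)
  boundaries <- as.integer(boundaries)
  nseg <- length(boundaries) - 1L
  if (nseg < 1L || any(diff(boundaries) <= 0) || boundaries[1] < 1L ||
      boundaries[nseg + 1L] > K + 1L)
    mn_stop("boundaries must be strictly increasing frames within [1, K+1]",
            "mn_config_error")
  first <- boundaries[-(nseg + 1L)]
  last <- c(boundaries[-1L][-nseg] - 1L, min(boundaries[nseg + 1L], K))
  fits <- vector("list", nseg)
  pred <- NULL
  for (s in seq_len(nseg)) {
    seg <- trajectory_window(trajectory, first[s], last[s])
    fits[[s]] <- search_frequencies(seg, marker, n = n, search = search,
                                    n_m = n_m, intercept = intercept,
                                    ridge_rel = ridge_rel)
    p <- predict(fits[[s]]$model, seg$times)
    pred <- rbind(pred, p)
  }
  if (nrow(pred) != K)
    mn_stop("segments do not cover every frame exactly once", "mn_config_error")
  seams <- if (nseg > 1L) {
    jumps <- sapply(seq_len(nseg - 1L), function(s) {
      a <- pred[last[s], ]; b <- pred[first[s + 1L], ]
      sqrt(sum((b - a)^2) / (length(a) / 3))
    })
    data.frame(boundary_frame = first[-1L], jump = jumps)
  } else data.frame(boundary_frame = integer(0), jump = numeric(0))
  obs <- channel_matrix(trajectory, fits[[1]]$marker)
  total_rss <- sum((obs - pred[, colnames(obs), drop = FALSE])^2)
  structure(list(fits = fits, boundaries = boundaries,
                 frames = data.frame(segment = seq_len(nseg),
                                     first = first, last = last),
                 prediction = pred, seams = seams, total_rss = total_rss),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("<segmented_fit> %d segment(s)\n", length(x$fits)))
  for (s in seq_along(x$fits))
    cat(sprintf("  [%d] frames %d-%d: f* = %s Hz, eps_r = %.4g\n",
                s, x$frames$first[s], x$frames$last[s],
                paste(signif(x$fits[[s]]$omega_hz, 4), collapse = "/"),
                sqrt(x$fits[[s]]$objective)))
  invisible(x)
}

#' Scan model sizes by AICc
#'
#' Runs a frequency search for every combination of center count and
#' satellite count and scores each optimum by [aicc()], with
#' `k = length(W) + n` (every fitted weight plus the searched
#' frequencies) and `n_obs = 3 K` per marker. Grid search is used for
#' n <= 2 and seeded random search above that.
#'
#' @param trajectory A [marker_trajectory()].
#' @param marker Marker driving the scan.
#' @param centers Candidate center counts (subset of 1..5).
#' @param satellites Candidate satellite counts.
#' @param search A [search_grid()] giving the Hz range/step for n <= 2;
#'   its range is reused for the random draws.
#' @param budget Random-search budget for n >= 3.
#' @param seed Seed for the random searches (one per center count,
#'   derived as `seed + n`).
#' @inheritParams search_frequencies
#' @return A `model_scan`: `table` (n, n_m, rss, k, n_obs, AICc),
#'   `best` (the minimizing pair), and the underlying `fits`.
#' @export
model_scan <- function(trajectory, marker, centers = 1:4,
                       satellites = c(25, 50, 100), search = search_grid(),
                       budget = 2000, seed = 1L, n_m = NULL,
                       intercept = TRUE, ridge_rel = 1e-10) {
  rows <- list(); fits <- list()
  K <- length(trajectory$times)
  Y <- channel_matrix(trajectory, marker)
  den <- colSums(Y^2)
  for (n in centers) {
    cfg <- if (n <= 2L) search
           else search_random(search$lo, search$hi, budget, seed = seed + n)
    for (nm in satellites) {
      fit <- search_frequencies(trajectory, marker, n = n, search = cfg,
                                n_m = nm, intercept = intercept,
                                ridge_rel = ridge_rel)
      rep1 <- fit$report
      rss <- rep1$eps2_x + rep1$eps2_y + rep1$eps2_z
      k <- length(fit$model$W) + n
      key <- sprintf("n%d_m%d", n, nm)
      fits[[key]] <- fit
      rows[[key]] <- data.frame(n = n, n_m = nm, rss = rss, k = k,
                                n_obs = 3 * K,
                                aicc = aicc(rss, 3 * K, k))
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  best <- table[which.min(table$aicc), ]
  structure(list(table = table,
                 best = list(n = best$n, n_m = best$n_m, aicc = best$aicc),
                 fits = fits),
            class = "model_scan")
}

#' @export
print.model_scan <- function(x, ...) {
  cat("<model_scan> AICc over centers x satellites\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  best: %d center(s), %d satellite(s)\n", x$best$n, x$best$n_m))
  invisible(x)
}
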