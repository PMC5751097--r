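test_that("compiled search objective agrees with the R fitting path", {
  g <- short_motion(seed = 3, n_m = 15)
  traj <- g$trajectory
  cand <- rbind(c(0.4, 1.2), c(0.48, 1.27), c(0.7, 0.9))
  rel <- mocapnet:::objective_channels(traj, "marker1", cand, n_m = 15)
  Y <- channel_matrix(traj, "marker1")
  den <- colSums(Y^2)
  for (i in seq_len(nrow(cand))) {
    m <- fit_motion(traj, rad_s(cand[i, ]), markers = "marker1", n_m = 15)
    ref <- c(m$report$eps2_rx, m$report$eps2_ry, m$report$eps2_rz)
    expect_equal(rel[i, ], ref, tolerance = 1e-7)
  }
})

test_that("grid search recovers generating frequencies on clean data", {
  g <- short_motion(seed = 21)
  fr <- search_frequencies(g$trajectory, "marker1", n = 2,
                           search = search_grid(0.3, 1.5, 0.01), n_m = 15)
  expect_true(grid_step_match(fr$omega_hz, c(0.5, 1.3)))
  expect_lt(fr$report$eps_r, 1e-3)
  expect_equal(nrow(fr$trace), 121 * 122 / 2)
})

test_that("constant channels tie and resolve to the smallest grid point", {
  t <- seq(0, 3, by = 1 / 60)
  traj <- marker_trajectory(t, list(m = cbind(rep(2, length(t)),
                                              rep(1, length(t)),
                                              rep(-1, length(t)))))
  fr <- search_frequencies(traj, "m", n = 1,
                           search = search_grid(0.2, 0.6, 0.1), n_m = 10)
  expect_equal(fr$omega_hz, 0.2)
})

test_that("harmonic-family search locates the driving frequency of an even signal", {
  t <- seq(0, 10, by = 1 / 120)
  y <- cos(2 * sin(2 * pi * t))
  traj <- marker_trajectory(t, list(m = cbind(y, y + 3, 2 * y)))
  fr <- search_frequencies(traj, "m", n = 1,
                           search = search_grid(0.5, 1.5, 0.05),
                           basis = basis_config("harmonic", n_m = 8, x0 = 1))
  expect_equal(fr$omega_hz, 1.0)
})

test_that("random search is seeded and reproducible", {
  g <- short_motion(seed = 6)
  s <- search_random(0.3, 1.5, budget = 150, seed = 99)
  f1 <- search_frequencies(g$trajectory, "marker1", n = 3, search = s, n_m = 15)
  f2 <- search_frequencies(g$trajectory, "marker1", n = 3, search = s, n_m = 15)
  expect_identical(f1$omega_hz, f2$omega_hz)
  expect_error(search_random(0.3, 1.5, budget = 10),
               class = "mn_config_error")      # seed mandatory
  expect_error(search_frequencies(g$trajectory, "marker1", n = 3,
                                  search = search_grid(0.3, 1.5, 0.1)),
               class = "mn_config_error")      # exhaustive grid only n <= 2
})

test_that("transferred frequencies serve all markers of a shared generator", {
  g <- short_motion(seed = 30, markers = 3L)
  fr <- search_frequencies(g$trajectory, "marker1", n = 2,
                           search = search_grid(0.3, 1.5, 0.01), n_m = 15)
  tm <- transfer_fit(fr, g$trajectory, n_m = 15)
  expect_true(all(tm$report$eps_r < 1e-3))
  # transfer back to the source marker reproduces the original fit
  self <- transfer_fit(fr, g$trajectory, markers = "marker1", n_m = 15)
  expect_equal(self$report$eps_r, fr$report$eps_r, tolerance = 1e-10)
})

test_that("transfer to a differently driven marker is worse than its own search", {
  a <- short_motion(seed = 31, freqs_hz = c(0.5, 1.3))
  b <- short_motion(seed = 32, freqs_hz = c(0.4, 0.9))
  traj <- marker_trajectory(a$trajectory$times,
                            list(m1 = a$trajectory$coords$marker1,
                                 m2 = b$trajectory$coords$marker1))
  fr1 <- search_frequencies(traj, "m1", n = 2,
                            search = search_grid(0.3, 1.5, 0.01), n_m = 15)
  transferred <- transfer_fit(fr1, traj, markers = "m2", n_m = 15)
  own <- search_frequencies(traj, "m2", n = 2,
                            search = search_grid(0.3, 1.5, 0.01), n_m = 15)
  expect_gt(transferred$report$eps_r, own$report$eps_r)
})

test_that("averaged-marker objective is the sum of per-marker objectives", {
  g <- short_motion(seed = 33, markers = 2L)
  avg <- average_marker_search(g$trajectory, n = 2,
                               search = search_grid(0.3, 1.5, 0.05), n_m = 15)
  rows <- c(1, 50, 100)
  cand <- avg$trace$cand_hz[rows, , drop = FALSE]
  rel <- mocapnet:::objective_channels(g$trajectory,
                                       g$trajectory$markers, cand, 15)
  per <- sapply(1:2, function(k) rowMeans(rel[, 3 * (k - 1) + 1:3]))
  expect_equal(avg$trace$objective[rows], rowSums(per), tolerance = 1e-9)
  # a single marker reduces to the plain search
  g1 <- short_motion(seed = 34)
  a1 <- average_marker_search(g1$trajectory, n = 2,
                              search = search_grid(0.3, 1.5, 0.05), n_m = 15)
  s1 <- search_frequencies(g1$trajectory, "marker1", n = 2,
                           search = search_grid(0.3, 1.5, 0.05), n_m = 15)
  expect_equal(a1$omega_hz, s1$omega_hz)
})

test_that("segmented fitting respects boundary conventions", {
  g <- short_motion(seed = 40, freqs_hz = 0.7, n_m = 12)
  K <- length(g$trajectory$times)
  seg <- fit_segmented(g$trajectory, c(1, K + 1), "marker1", n = 1,
                       search = search_grid(0.3, 1.5, 0.05), n_m = 12)
  expect_equal(nrow(seg$frames), 1L)
  expect_equal(seg$frames$last, K)
  whole <- search_frequencies(g$trajectory, "marker1", n = 1,
                              search = search_grid(0.3, 1.5, 0.05), n_m = 12)
  expect_equal(seg$fits[[1]]$omega_hz, whole$omega_hz)
  expect_equal(seg$fits[[1]]$report$eps_r, whole$report$eps_r,
               tolerance = 1e-10)
  expect_error(fit_segmented(g$trajectory, c(1, 10, 5), "marker1"),
               class = "mn_config_error")
})

test_that("two-segment motions are recovered segment by segment", {
  sp <- synth_spec(n = 1, freqs_hz = 0.5, n_m = 12, seed = 55,
                   segments = list(list(duration = 3, freqs_hz = 0.5),
                                   list(duration = 3, freqs_hz = 1.5)))
  g <- generate_segmented(sp)
  seg <- fit_segmented(g$trajectory, g$boundaries, "marker1", n = 1,
                       search = search_grid(0.3, 1.8, 0.01), n_m = 12)
  expect_true(grid_step_match(seg$fits[[1]]$omega_hz, 0.5))
  expect_true(grid_step_match(seg$fits[[2]]$omega_hz, 1.5))
  single <- search_frequencies(g$trajectory, "marker1", n = 1,
                               search = search_grid(0.3, 1.8, 0.01), n_m = 12)
  obs <- channel_matrix(g$trajectory, "marker1")
  rss_single <- sum((obs - predict(single$model, g$trajectory$times))^2)
  expect_lt(seg$total_rss, rss_single)
  expect_equal(nrow(seg$seams), 1L)
})

test_that("the minimized objective is invariant to whole-period time shifts", {
  g <- short_motion(seed = 60, freqs_hz = c(0.5, 1.0), n_m = 15)
  traj <- g$trajectory
  # 0.5 and 1.0 Hz share a 2 s common period; shift by exactly 2 s
  shifted <- marker_trajectory(traj$times + 2, traj$coords,
                               rate = traj$rate)
  f0 <- search_frequencies(traj, "marker1", n = 2,
                           search = search_grid(0.4, 1.1, 0.05), n_m = 15)
  f1 <- search_frequencies(shifted, "marker1", n = 2,
                           search = search_grid(0.4, 1.1, 0.05), n_m = 15)
  expect_equal(f1$omega_hz, f0$omega_hz)
  expect_lt(abs(f1$objective - f0$objective), 1e-6)
})

test_that("model scan scores sizes by AICc and is internally consistent", {
  g <- short_motion(seed = 70, n_m = 15)
  sc <- model_scan(g$trajectory, "marker1", centers = 1:2,
                   satellites = c(10, 15),
                   search = search_grid(0.3, 1.5, 0.02), seed = 7)
  expect_equal(nrow(sc$table), 4L)
  # table entries equal pointwise aicc() on the stored fits
  for (i in seq_len(nrow(sc$table))) {
    row <- sc$table[i, ]
    expect_equal(row$aicc, aicc(row$rss, row$n_obs, row$k))
    key <- sprintf("n%d_m%d", row$n, row$n_m)
    rep1 <- sc$fits[[key]]$report
    expect_equal(row$rss, rep1$eps2_x + rep1$eps2_y + rep1$eps2_z)
  }
  expect_equal(sc$best$n, 2L)
  # a single candidate is returned trivially
  sc1 <- model_scan(g$trajectory, "marker1", centers = 2, satellites = 15,
                    search = search_grid(0.3, 1.5, 0.02), seed = 7)
  expect_equal(nrow(sc1$table), 1L)
  expect_equal(sc1$best$n_m, 15)
})
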