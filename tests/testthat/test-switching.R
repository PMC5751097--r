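make_module <- function(m = 2, xi = 0.4) {
  switching_module(a_tilde = rep(1, m), b_tilde = rep(50, m),
                   h_tilde = 50 * (seq_len(m) - 1 + 0.25),
                   h = (m + 1) / 2, kappa = 0.05, xi = xi)
}

test_that("the vector field matches an independent hand-coded evaluation", {
  mod <- make_module(3)
  set.seed(14)
  st <- c(runif(3, 0, 0.05), runif(1, 0, 3))
  d <- switch_rhs(st, mod)
  # independent re-evaluation, scalar arithmetic only
  sig <- function(x) 1 / (1 + exp(-x))
  dw <- numeric(3)
  for (i in 1:3) dw[i] <- sig(mod$b_tilde[i] * st[4] - mod$h_tilde[i]) -
    st[i] / mod$kappa
  dz <- sig(sum(mod$a_tilde * st[1:3]) / mod$kappa - mod$h) -
    mod$xi * mod$lambda_bar * st[4]
  expect_equal(d, c(dw, dz), tolerance = 1e-14)

  # satellite nullcline: quasi-steady satellites have zero derivative
  z <- 1.3
  st2 <- c(mod$kappa * sig(mod$b_tilde * z - mod$h_tilde), z)
  expect_equal(switch_rhs(st2, mod)[1:3], rep(0, 3), tolerance = 1e-14)
})

test_that("with negligible gains the hub decays as sigma(-h) forcing vs xi lambda z", {
  mod <- switching_module(a_tilde = rep(1e-12, 2), b_tilde = rep(1e-12, 2),
                          h_tilde = c(0, 0), h = 40, kappa = 0.05, xi = 0.7)
  d <- switch_rhs(c(0, 0, 2), mod)
  expect_equal(d[3], -0.7 * 2, tolerance = 1e-10)
  # decoupled case: the unique rest point solves sigma(-h) = xi lambda z
  rp <- find_rest_points(mod)
  expect_equal(sum(rp$points$stable), 1L)
  z_star <- uniroot(function(z) plogis(-40) - 0.7 * z, c(-0.1, 1))$root
  expect_equal(rp$points$z[rp$points$stable], z_star, tolerance = 1e-8)
})

test_that("constructed modules realize the prescribed multistable structure", {
  sw <- construct_switch(3, beta = 0.5, kappa = 0.05)
  rp <- find_rest_points(sw$module)
  st <- rp$points[rp$points$stable, ]
  expect_equal(nrow(st), 3L)
  expect_true(all(rp$points$hyperbolic))
  for (j in 1:3) expect_true(st$z[j] > j - 0.5 && st$z[j] < j + 0.5)
  expect_true(all(rp$points$residual < 1e-8))
  # single stable point above the calibrated bound
  rp1 <- find_rest_points(sw$module, xi = sw$xi_single)
  expect_equal(sum(rp1$points$stable), 1L)
  # m = 1 construction
  sw1 <- construct_switch(1, beta = 0.5)
  rp1 <- find_rest_points(sw1$module)
  z1 <- rp1$points$z[rp1$points$stable]
  expect_equal(length(z1), 1L)
  expect_true(z1 > 0.5 && z1 < 1.5)
  # determinism
  sw2 <- construct_switch(3, beta = 0.5, kappa = 0.05)
  expect_identical(sw$module, sw2$module)
  expect_identical(sw$xi_interval, sw2$xi_interval)
  expect_error(construct_switch(2, beta = 1.5), class = "mn_invalid_parameter")
})

test_that("multistability holds on the interval and collapses above it", {
  sw <- construct_switch(2, beta = 0.5)
  for (xi in seq(sw$xi_interval[1], sw$xi_interval[2], length.out = 5)) {
    rp <- find_rest_points(sw$module, xi = xi)
    expect_equal(sum(rp$points$stable), 2L)
  }
  rp <- find_rest_points(sw$module, xi = sw$xi_single * 2)
  expect_equal(sum(rp$points$stable), 1L)
})

test_that("stability labels agree with perturbed long-horizon simulation", {
  sw <- construct_switch(2, beta = 0.5)
  rp <- find_rest_points(sw$module)
  for (i in seq_len(nrow(rp$points))) {
    st <- rp$states[i, ]
    z <- rp$points$z[i]
    for (dz in c(-1e-3, 1e-3)) {
      path <- simulate_switch(sw$module, st + c(numeric(sw$module$m), dz),
                              horizon = 200)
      z_end <- path$z[nrow(path)]
      if (rp$points$stable[i]) {
        expect_lt(abs(z_end - z), 1e-4)
      } else {
        expect_gt(abs(z_end - z), 1e-2)   # repelled along z
      }
    }
  }
})

test_that("simulation stays at rest points and relaxes satellites at rate 1/kappa", {
  sw <- construct_switch(2, beta = 0.5)
  rp <- find_rest_points(sw$module)
  st <- rp$states[which(rp$points$stable)[1], ]
  path <- simulate_switch(sw$module, st, horizon = 50)
  expect_lt(max(abs(as.numeric(path[nrow(path), -1]) - st)), 1e-6)

  # perturb one satellite; near-frozen z implies w(t) ~ w* + dw exp(-t/kappa)
  st2 <- st; st2[1] <- st2[1] + 0.01
  path2 <- simulate_switch(sw$module, st2, horizon = 0.2, n_out = 200)
  w_pred <- st[1] + 0.01 * exp(-path2$time / sw$module$kappa)
  expect_lt(max(abs(path2$w1 - w_pred)), 1e-3)
})

test_that("basin membership determines the settled attractor", {
  sw <- construct_switch(3, beta = 0.5)
  rp <- find_rest_points(sw$module)
  zs <- rp$points$z[rp$points$stable]
  for (j in 1:3) {
    path <- simulate_switch(sw$module, zs[j] + 0.05, horizon = 150)
    expect_lt(abs(path$z[nrow(path)] - zs[j]), 1e-4)
  }
})

test_that("motion selection uses nearest anchors with lower-tie preference", {
  g <- short_motion(seed = 2, freqs_hz = 0.5, n_m = 10)
  m1 <- fit_motion(g$trajectory, g$truth$omega, n_m = 10)
  g2 <- short_motion(seed = 3, freqs_hz = 1.1, n_m = 10)
  m2 <- fit_motion(g2$trajectory, g2$truth$omega, n_m = 10)
  lib <- motion_library(c(1, 2), list(m1, m2))
  expect_equal(attr(select_motion(lib, 1), "index"), 1L)
  expect_equal(attr(select_motion(lib, 1.9), "index"), 2L)
  expect_equal(attr(select_motion(lib, 1.5), "index"), 1L)  # tie -> lower
  expect_error(select_motion(motion_library(1, list(m1)), "a"))
  expect_error(motion_library(numeric(0), list()),
               class = "mn_invalid_parameter")
})

test_that("the global model plays stored motions selected by the switch", {
  sw <- construct_switch(2, beta = 0.5)
  rp <- find_rest_points(sw$module)
  anchors <- rp$points$z[rp$points$stable]
  mk <- function(f, seed) {
    g <- study_motion(seed = seed, freqs_hz = f, n_m = 10, duration = 4)
    g$truth$model
  }
  lib <- motion_library(anchors, list(mk(0.5, 1), mk(1.25, 2)))

  # no pulses, start in basin 1: identical to predicting entry 1
  sched <- data.frame(xi = sw$xi, duration = 2)
  out <- run_global_model(lib, sw, sched, rate = 120, z0 = anchors[1])
  tt <- attr(out$trajectory, "times")
  expect_equal(unname(out$trajectory),
               unname(predict(lib$models[[1]], tt)), tolerance = 1e-8,
               ignore_attr = TRUE)

  # empty schedule: empty trajectory
  out0 <- run_global_model(lib, sw, data.frame(xi = numeric(0),
                                               duration = numeric(0)))
  expect_equal(nrow(out0$trajectory), 0L)

  # low-xi pulse drives the hub high (motion 2), a large-xi pulse resets
  # to the low attractor (motion 1): dominant frequency follows
  sched2 <- data.frame(xi = c(sw$xi_interval[1] * 0.75, sw$xi_single),
                       duration = c(4, 4))
  out2 <- run_global_model(lib, sw, sched2, rate = 120, z0 = anchors[1])
  expect_equal(out2$epochs$index, c(2L, 1L))
  # each epoch reproduces the selected library entry exactly
  tt2 <- attr(out2$trajectory, "times")
  expect_equal(unname(out2$trajectory[1:480, ]),
               unname(predict(lib$models[[2]],
                              lib$models[[2]]$t0 + tt2[1:480])),
               tolerance = 1e-8, ignore_attr = TRUE)
  # and the dominant period changes across the transition
  dom <- function(x, rate) {
    sp <- Mod(fft(x - mean(x)))[2:(length(x) / 2)]
    which.max(sp) * rate / length(x)
  }
  f1 <- dom(out2$trajectory[1:480, 1], 120)
  f2 <- dom(out2$trajectory[481:960, 1], 120)
  expect_false(isTRUE(all.equal(f1, f2)))
})
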