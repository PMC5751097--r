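test_that("marker CSV writes round-trip and keep deterministic column order", {
  g <- short_motion(seed = 1, markers = 2L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_markers_csv(g$trajectory, f)
  back <- read_markers_csv(f, units = "unit")
  expect_equal(back$markers, sort(g$trajectory$markers))
  for (nm in back$markers)
    expect_lt(max(abs(back$coords[[nm]] - g$trajectory$coords[[nm]])), 1e-12)
  expect_lt(max(abs(back$times - g$trajectory$times)), 1e-12)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_markers_csv(g$trajectory, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("a minimal two-frame file yields K = 2 and the implied rate", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,time_s,hip_x,hip_y,hip_z",
               "1,0,1,2,3",
               "2,0.02,1.5,2.5,3.5"), f)
  traj <- read_markers_csv(f)
  expect_equal(length(traj$times), 2L)
  expect_equal(traj$rate, 50)
  expect_equal(traj$coords$hip[2, ], c(x = 1.5, y = 2.5, z = 3.5))
})

test_that("malformed marker CSVs are rejected, not repaired", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,time_s,hip_x,hip_y", "1,0,1,2", "2,0.02,1,2"), f)
  expect_error(read_markers_csv(f), class = "mn_parse_error")

  writeLines(c("frame,time_s,hip_x,hip_y,hip_z",
               "1,0,1,2,3", "2,0.02,NA,2,3"), f)
  expect_error(read_markers_csv(f), "row 2", class = "mn_parse_error")

  writeLines(c("frame,time_s,hip_x,hip_y,hip_z",
               "1,0.05,1,2,3", "2,0.02,1,2,3"), f)
  expect_error(read_markers_csv(f), class = "mn_parse_error")

  writeLines(c("time_s,hip_x,hip_y,hip_z", "0,1,2,3"), f)
  expect_error(read_markers_csv(f), class = "mn_parse_error")
})

write_trc_fixture <- function(path, drop_units = FALSE) {
  hdr2 <- c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
            "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames")
  val2 <- c("100", "100", "3", "2", "mm", "100", "1", "3")
  if (drop_units) {
    hdr2 <- hdr2[-5]; val2 <- val2[-5]
  }
  lines <- c(
    "PathFileType\t4\t(X/Y/Z)\tfixture.trc",
    paste(hdr2, collapse = "\t"),
    paste(val2, collapse = "\t"),
    "Frame#\tTime\theel\t\t\twrist\t\t",
    "\t\tX1\tY1\tZ1\tX2\tY2\tZ2",
    "1\t0\t1.5\t2.5\t3.5\t-1\t0\t1",
    "2\t0.01\t1.6\t2.4\t3.4\t-1.1\t0.1\t1.1",
    "3\t0.02\t1.7\t2.3\t3.3\t-1.2\t0.2\t1.2")
  writeLines(lines, path)
}

test_that("TRC files parse with header validation", {
  f <- withr::local_tempfile(fileext = ".trc")
  write_trc_fixture(f)
  traj <- read_trc(f)
  expect_equal(traj$markers, c("heel", "wrist"))
  expect_equal(length(traj$times), 3L)
  expect_equal(traj$rate, 100)
  expect_equal(traj$units, "mm")
  expect_equal(traj$coords$wrist[3, ], c(x = -1.2, y = 0.2, z = 1.2))

  # values survive conversion to the CSV dialect
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_markers_csv(traj, f2)
  back <- read_markers_csv(f2)
  expect_equal(back$coords$heel, traj$coords$heel)

  f3 <- withr::local_tempfile(fileext = ".trc")
  write_trc_fixture(f3, drop_units = TRUE)
  expect_error(read_trc(f3), class = "mn_parse_error")
})

test_that("TRC frame-count mismatches are errors", {
  f <- withr::local_tempfile(fileext = ".trc")
  write_trc_fixture(f)
  lines <- readLines(f)
  writeLines(lines[-length(lines)], f)   # drop a data row
  expect_error(read_trc(f), class = "mn_parse_error")
})

test_that("model files round-trip within 1e-12 on predictions", {
  g <- short_motion(seed = 5, n_m = 12)
  m <- fit_motion(g$trajectory, g$truth$omega, n_m = 12)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  p1 <- predict(m, g$trajectory$times)
  p2 <- predict(m2, g$trajectory$times)
  expect_lt(max(abs(p1 - p2)), 1e-12)
  expect_equal(m2$bank$omega, m$bank$omega)
  expect_equal(m2$basis$b, m$basis$b)
})

test_that("segmented and library model files round-trip", {
  sp <- synth_spec(n = 1, freqs_hz = 0.5, n_m = 10, seed = 9,
                   segments = list(list(duration = 2, freqs_hz = 0.5),
                                   list(duration = 2, freqs_hz = 1.4)))
  g <- generate_segmented(sp)
  seg <- fit_segmented(g$trajectory, g$boundaries, "marker1", n = 1,
                       search = search_grid(0.3, 1.6, 0.05), n_m = 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(seg, f)
  back <- read_model(f)
  expect_equal(back$boundaries, g$boundaries)
  expect_equal(back$models[[2]]$bank$omega, seg$fits[[2]]$model$bank$omega)

  sw <- construct_switch(2, beta = 0.5)
  rp <- find_rest_points(sw$module)
  anchors <- rp$points$z[rp$points$stable]
  m1 <- seg$fits[[1]]$model; m2 <- seg$fits[[2]]$model
  lib <- motion_library(anchors, list(m1, m2))
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model(list(library = lib, switch = sw$module), f2)
  back2 <- read_model(f2)
  expect_equal(back2$library$anchors, anchors)
  expect_equal(back2$switch$h_tilde, sw$module$h_tilde)
  rp2 <- find_rest_points(back2$switch)
  expect_equal(rp2$points$z, rp$points$z, tolerance = 1e-10)
})
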