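test_that("write then read round-trips a track set at 6-decimal precision", {
  set.seed(21)
  ts <- simulate_prw(prw_sim_config(speed_S = 7, persistence_P = 1.2,
                                    n_cells = 4, n_frames = 8,
                                    frame_interval = 1.5, seed = 21,
                                    group_label = "roundtrip"))
  p1 <- tempfile(fileext = ".csv")
  write_tracks(ts, p1)
  back <- read_tracks(p1)
  expect_identical(names(back$trajectories), names(ts$trajectories))
  for (id in names(ts$trajectories)) {
    expect_equal(back$trajectories[[id]]$x_um,
                 round(ts$trajectories[[id]]$x_um, 6))
    expect_equal(back$trajectories[[id]]$y_um,
                 round(ts$trajectories[[id]]$y_um, 6))
  }
  expect_identical(back$group_label, "roundtrip")
  expect_identical(back$frame_interval, 1.5)
  # a second write of the re-read set is byte-identical
  p2 <- tempfile(fileext = ".csv")
  write_tracks(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("metadata sidecar preserves calibration verbatim", {
  ts <- track_set(list(a = trajectory(0:3, 0:3, frame_interval = 0.5)),
                  frame_interval = 0.5, group_label = "meta",
                  replicate_id = "mouse_1", pixel_size = 0.65)
  p <- tempfile(fileext = ".csv")
  write_tracks(ts, p)
  meta <- yaml::read_yaml(paste0(p, ".meta.yaml"))
  expect_identical(meta$pixel_size, 0.65)
  expect_identical(meta$frame_interval, 0.5)
  expect_identical(meta$replicate_id, "mouse_1")
})

test_that("empty track set writes a header-only file without error", {
  ts <- track_set(list(), frame_interval = 1.5, group_label = "empty")
  p <- tempfile(fileext = ".csv")
  write_tracks(ts, p)
  expect_identical(readLines(p), "cell_id,frame,time_min,x_um,y_um")
})

write_imagej <- function(df, sep = ",") {
  p <- tempfile(fileext = ".csv")
  utils::write.table(df, p, sep = sep, row.names = FALSE, quote = FALSE)
  p
}

test_that("ImageJ Manual Tracking pixels are calibrated to micrometres", {
  p <- write_imagej(data.frame(
    "Track n" = c(1, 1, 1), "Slice n" = 1:3, X = c(10, 11, 12),
    Y = c(20, 20, 21), check.names = FALSE))
  ts <- read_tracks(p, format = "imagej_manual_tracking", pixel_size = 0.65,
                    frame_interval = 1.5)
  tr <- ts$trajectories[["track_1"]]
  expect_equal(tr$x_um[1], 6.5)
  expect_equal(tr$y_um[1], 13.0)
  # first frame maps to t = 0 under 1-based slice numbering
  expect_equal(tr$time_min, c(0, 1.5, 3))
})

test_that("tab-delimited input is autodetected", {
  p <- write_imagej(data.frame(
    "Track n" = c(1, 1, 1), "Slice n" = 1:3, X = 0:2, Y = 0:2,
    check.names = FALSE), sep = "\t")
  ts <- read_tracks(p, format = "imagej_manual_tracking", pixel_size = 1,
                    frame_interval = 1)
  expect_length(ts, 1)
})

test_that("calibration is linear: doubling pixel size doubles coordinates", {
  p <- write_imagej(data.frame(
    "Track n" = rep(1, 4), "Slice n" = 1:4, X = c(3, 5, 8, 2),
    Y = c(1, 4, 2, 9), check.names = FALSE))
  a <- read_tracks(p, format = "imagej_manual_tracking", pixel_size = 0.4,
                   frame_interval = 1.5)
  b <- read_tracks(p, format = "imagej_manual_tracking", pixel_size = 0.8,
                   frame_interval = 1.5)
  expect_equal(b$trajectories[[1]]$x_um, 2 * a$trajectories[[1]]$x_um)
  expect_equal(b$trajectories[[1]]$y_um, 2 * a$trajectories[[1]]$y_um)
})

test_that("tracks with fewer than 3 positions are excluded and reported", {
  p <- write_imagej(data.frame(
    "Track n" = c(1, 1, 1, 2, 2), "Slice n" = c(1:3, 1:2),
    X = c(0, 1, 2, 5, 6), Y = c(0, 0, 0, 5, 5), check.names = FALSE))
  expect_message(
    ts <- read_tracks(p, format = "imagej_manual_tracking", pixel_size = 1,
                      frame_interval = 1.5),
    "excluded 1 track")
  expect_length(ts, 1)
  excl <- attr(ts, "excluded")
  expect_identical(nrow(excl), 1L)
  expect_identical(excl$cell_id, "track_2")
})

test_that("format errors name the missing columns and offending track", {
  p <- write_imagej(data.frame("Track n" = 1, X = 1, check.names = FALSE))
  expect_error(read_tracks(p, format = "imagej_manual_tracking",
                           pixel_size = 1, frame_interval = 1),
               "Slice")
  p2 <- write_imagej(data.frame(
    "Track n" = c(1, 1, 1), "Slice n" = c(1, 3, 2), X = 0:2, Y = 0:2,
    check.names = FALSE))
  expect_error(read_tracks(p2, format = "imagej_manual_tracking",
                           pixel_size = 1, frame_interval = 1),
               "track_1")
  p3 <- write_imagej(data.frame(bogus = 1))
  expect_error(read_tracks(p3, frame_interval = 1), "cell_id")
})

test_that("pixel size is a required input for ImageJ exports", {
  p <- write_imagej(data.frame(
    "Track n" = c(1, 1, 1), "Slice n" = 1:3, X = 0:2, Y = 0:2,
    check.names = FALSE))
  expect_error(read_tracks(p, format = "imagej_manual_tracking",
                           frame_interval = 1.5), "pixel_size")
})

test_that("trajectory validation rejects malformed inputs", {
  expect_error(trajectory(c(0, 1), c(0, NA), frame_interval = 1),
               "non-finite")
  expect_error(trajectory(0:3, 0:3, times = c(0, 1, 1, 2)),
               "strictly increasing")
  expect_error(trajectory(0:3, 0:3, times = c(0, 1, 2, 4)),
               "uniformly spaced")
  expect_error(track_set(list(a = trajectory(0:3, 0:3, frame_interval = 1)),
                         frame_interval = 2),
               "frame interval")
})
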