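# Receptive-field mapping schedules.

test_that("bar sweep advances at speed/frame_rate degrees per frame", {
  s <- bar_sweep_schedule(speed = 10, extent = 120, frame_rate_hz = 60)
  # frame 60 is displaced 10 degrees from the start
  expect_equal(s$sweep_offset_deg[s$frame_index == 60] -
                 s$sweep_offset_deg[s$frame_index == 0], 10)
  # a 120-degree sweep at 10 deg/s lasts 12 s of frames
  expect_equal(attr(s, "total_frames"), 12 * 60)
  expect_equal(nrow(s), 720L)
  expect_error(bar_sweep_schedule(speed = 1e6, extent = 1,
                                  frame_rate_hz = 60), "one frame")
  expect_error(bar_sweep_schedule(extent = 260), "coverage")
})

test_that("bar sweep centers are strictly monotone along the sweep axis
           for random parameters", {
  set.seed(6)
  for (i in 1:25) {
    s <- bar_sweep_schedule(orientation = runif(1, 0, 180),
                            sweep_direction = runif(1, 0, 360),
                            speed = runif(1, 2, 40),
                            strip_width = runif(1, 1, 10),
                            extent = runif(1, 20, 240),
                            frame_rate_hz = 60)
    expect_true(all(diff(s$sweep_offset_deg) > 0))
    expect_true(all(dome_polar_angle(s$azimuth, s$elevation) <=
                      DOME_MAX_POLAR_DEG + 1e-9))
  }
})

test_that("flash grid covers each location exactly once per repetition
           with exact frame accounting", {
  s <- flash_grid_schedule(azimuths = c(-20, 0, 20),
                           elevations = c(-10, 0, 10),
                           flash_frames = 3L, gap_frames = 2L, seed = 2L)
  expect_equal(length(unique(s$flash_index)), 9L)
  pos <- unique(s[c("azimuth", "elevation")])
  expect_equal(nrow(pos), 9L)
  expect_equal(attr(s, "total_frames"), 9L * 5L)
  expect_equal(nrow(s), 9L * 3L)          # visible frames only
  # durations and gaps honored exactly
  per_flash <- split(s$frame_index, s$flash_index)
  expect_true(all(vapply(per_flash, function(fi)
    identical(fi, seq(min(fi), length.out = 3L)), TRUE)))
  starts <- vapply(per_flash, min, 0)
  expect_equal(unname(diff(sort(starts))), rep(5, 8))

  s2 <- flash_grid_schedule(azimuths = c(-20, 0, 20),
                            elevations = c(-10, 0, 10),
                            flash_frames = 3L, gap_frames = 2L, seed = 2L)
  expect_identical(as.data.frame(s), as.data.frame(s2))  # determinism
  s3 <- flash_grid_schedule(azimuths = c(-20, 0, 20),
                            elevations = c(-10, 0, 10), seed = 3L)
  expect_false(identical(s$azimuth, s3$azimuth))
  expect_error(flash_grid_schedule(numeric(), 0), "empty")
  expect_error(flash_grid_schedule(179, 0), "coverage")
  # two repetitions: every location exactly twice
  s4 <- flash_grid_schedule(c(-20, 0, 20), c(-10, 0, 10),
                            flash_frames = 1L, gap_frames = 0L,
                            repetitions = 2L, seed = 1L)
  tab <- table(paste(s4$azimuth, s4$elevation))
  expect_true(all(tab == 2L))
})

test_that("sparse noise is reproducible, respects its frame budget, and
           stays on the lattice", {
  s <- sparse_noise_schedule(squares_per_frame = 4L, n_frames = 50L,
                             seed = 7L)
  expect_true(all(table(s$frame_index) == 4L))
  expect_equal(nrow(s), 200L)
  expect_true(all(s$azimuth %% 5 == 0 & s$elevation %% 5 == 0))
  expect_true(all(dome_polar_angle(s$azimuth, s$elevation) <=
                    DOME_MAX_POLAR_DEG))
  expect_true(all(s$value %in% c(-1, 1)))
  # no within-frame duplicates (sampling without replacement)
  dup <- tapply(paste(s$azimuth, s$elevation), s$frame_index,
                function(x) anyDuplicated(x) > 0)
  expect_false(any(dup))
  s2 <- sparse_noise_schedule(squares_per_frame = 4L, n_frames = 50L,
                              seed = 7L)
  expect_identical(as.data.frame(s), as.data.frame(s2))
  expect_error(sparse_noise_schedule(spacing_deg = 200,
                                     squares_per_frame = 10L), "lattice")
})

test_that("sparse noise occupancy is uniform and polarity balanced", {
  s <- sparse_noise_schedule(square_size_deg = 4, spacing_deg = 25,
                             squares_per_frame = 2L, n_frames = 10000L,
                             seed = 13L)
  cell <- paste(s$azimuth, s$elevation)
  counts <- table(cell)
  # chi-square against uniform occupancy at alpha 0.01
  p <- stats::chisq.test(as.numeric(counts))$p.value
  expect_gt(p, 0.01)
  # white fraction within a 3.3-sigma binomial band of 0.5
  n <- nrow(s)
  expect_lt(abs(mean(s$value == 1) - 0.5), 3.3 * sqrt(0.25 / n))
})

test_that("the flicker pattern initializes at 0.5 and cycles
           1, 0.3, 1, 0", {
  f <- flicker_sequence(8)
  expect_equal(f[1], 0.5)
  expect_equal(f[2:5], c(1, 0.3, 1, 0))
  running <- f[-1]
  expect_equal(running[1 + 4], running[1])   # period 4
  expect_equal(running[seq(1, 8, by = 4)], rep(1, 2))
  expect_equal(flicker_sequence(0), 0.5)
  # consecutive running values always differ (a switch on every frame)
  f2 <- flicker_sequence(100)
  expect_true(all(diff(f2) != 0))
})

test_that("schedules serialize into log records and back through a file", {
  s <- sparse_noise_schedule(squares_per_frame = 2L, n_frames = 5L,
                             seed = 1L)
  recs <- schedule_records(s, object_id = 42L, frame_period_s = 1 / 60)
  expect_equal(sum(recs$line_type == "CUSTOM"), nrow(s))
  expect_equal(sum(recs$line_type == "STIMULUS_CREATE"), 1L)
  f <- tempfile(fileext = ".log")
  write_log(recs, make_header(), f)
  back <- parse_log(f, types = "CUSTOM", convert = FALSE)
  expect_equal(nrow(back$records), nrow(s))
  expect_match(back$records$payload[1], "azimuth=")
})
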