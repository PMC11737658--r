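# Game-time to screen-time conversion.

test_that("fixed display delay is pipeline periods plus projector delay", {
  expect_equal(fixed_display_delay(timing_config(100, 1L, 0)), 10)
  expect_equal(fixed_display_delay(timing_config(123.4, 0L, 0)), 0)
  expect_equal(fixed_display_delay(timing_config(59.952, 2L, 18)),
               2 * 1000 / 59.952 + 18)
  expect_equal(round(fixed_display_delay(timing_config(59.952, 2L, 18)), 3),
               51.360)
})

test_that("timing configuration validates and round-trips through its
           file form", {
  expect_error(timing_config(0), "frame_rate_hz")
  expect_error(timing_config(60, -1L), "pipeline_frames")
  f <- tempfile(fileext = ".cfg")
  write_timing_config(timing_config(59.952, 2L, 18), f)
  cfg <- read_timing_config(f)
  expect_equal(cfg$frame_rate_hz, 59.952)
  expect_equal(cfg$pipeline_frames, 2L)
  expect_equal(cfg$display_delay_ms, 18)
})

# frame/marker record data frames at more decimal places than the log
# dialect, to exercise the conversion arithmetic at full precision
high_precision_frames <- function(prep, flip, idx) {
  data.frame(time = prep, payload = sprintf("%d\t%.12f", idx, flip))
}
high_precision_markers <- function(game, hr) {
  data.frame(time = game, payload = sprintf("%d\t%.12f", 2100L, hr))
}

test_that("frame table recovers clock anchors and each frame's own flip", {
  cfg <- timing_config(60, 2L, 0)
  P <- 1 / 60
  n <- 40L
  idx <- 3:n
  flip_own <- 100 + (seq_len(n)) * P       # true flips of frames 1..n
  prep <- flip_own - 2 * P - 5             # clock offset 5 s
  fr <- high_precision_frames(prep[idx], flip_own[idx - 2L], idx)
  mk <- high_precision_markers(prep[idx], prep[idx] + 5)
  ft <- build_frame_table(fr, mk, cfg)
  expect_equal(ft$frame_index[1], 3L)      # logging starts at frame 3
  nt <- nrow(ft)
  expect_equal(ft$flip_time[seq_len(nt - 2L)], flip_own[idx[seq_len(nt - 2L)]],
               tolerance = 1e-12)
  expect_true(all(ft$extrapolated[(nt - 1L):nt]))
  # constant clock offset of 5 s recovered by the anchor map
  expect_equal(anchor_clock_map(c(101, 102.5), ft) - c(101, 102.5),
               c(5, 5), tolerance = 1e-9)
  # zero-offset session: anchor map is the identity
  mk0 <- high_precision_markers(prep[idx] + 5, prep[idx] + 5)
  ft0 <- build_frame_table(fr, mk0, cfg)
  expect_equal(anchor_clock_map(105.25, ft0), 105.25, tolerance = 1e-9)
})

test_that("frame table rejects degenerate input", {
  cfg <- timing_config(60, 2L, 0)
  expect_error(build_frame_table(high_precision_frames(1, 2, 3L),
                                 NULL, cfg), "at least 2")
  fr <- high_precision_frames(c(1, 1.02), c(2.02, 2.00), 3:4)
  expect_error(build_frame_table(fr, NULL, cfg), "strictly increasing")
  fr2 <- high_precision_frames(c(1, 1.02), c(2.00, 2.02), c(3L, 5L))
  expect_error(build_frame_table(fr2, NULL, cfg), "contiguous")
})

test_that("frame skips are flagged from doubled flip intervals", {
  cfg <- timing_config(59.952, 0L, 0)
  P <- frame_period_ms(cfg) / 1000
  flips <- cumsum(c(1, P, P, 2 * P, P)) # 16.68, 16.68, 33.36, 16.68 ms
  fr <- high_precision_frames(flips, flips, 3:7)
  ft <- build_frame_table(fr, NULL, cfg)
  expect_equal(detect_frame_skips(ft, cfg), 5L)  # third interval's frame
  flips2 <- cumsum(c(1, rep(P, 5)))
  ft2 <- build_frame_table(high_precision_frames(flips2, flips2, 3:8),
                           NULL, cfg)
  expect_length(detect_frame_skips(ft2, cfg), 0L)
})

test_that("a zero-delay configuration with flip == prep is the identity", {
  cfg <- timing_config(50, 0L, 0)
  P <- 1 / 50
  t <- 1 + (0:19) * P
  ft <- build_frame_table(high_precision_frames(t, t, 3:22), NULL, cfg)
  st <- to_screen_time(t, ft, cfg)
  expect_equal(as.numeric(st), t, tolerance = 1e-12)
})

test_that("conversion matches simulator ground truth exactly, also through
           skips", {
  cfg <- timing_config(59.952, 2L, 18)
  p <- simulation_params(n_frames = 400L, timing = cfg,
                         skip_probability = 0.05, noise_sd_fraction = 0,
                         seed = 5L)
  s <- simulate_session(p)
  gt <- s$ground_truth
  rec <- s$records
  fr <- rec[rec$line_type == "FRAME", ]
  mk <- rec[rec$line_type == "EVENT_MARKER", ]
  ft <- build_frame_table(fr, mk, cfg)
  # events at mid-frame of every tabulated, non-extrapolated frame
  tab <- !ft$extrapolated
  k <- ft$frame_index[tab]
  ev <- gt$prep_game_time[k] + 0.3 * diff(gt$prep_game_time)[k]
  st <- to_screen_time(ev, ft, cfg)
  truth <- gt$flip_time[k] + 18 / 1000
  # log times are snapped to 0.1 us, so agreement is at that resolution
  expect_lt(max(abs(as.numeric(st) - truth)), 2e-7)
  # with the exact same flips at full precision the arithmetic is exact
  ftx <- build_frame_table(
    high_precision_frames(gt$prep_game_time[3:400],
                          gt$flip_time[(3:400) - 2L], 3:400), NULL, cfg)
  stx <- to_screen_time(gt$prep_game_time[3:396], ftx, cfg)
  expect_lt(max(abs(as.numeric(stx) - (gt$flip_time[3:396] + 0.018))),
            1e-9)
})

test_that("events in a stuck frame inherit the late flip (one period
           later than the no-skip prediction)", {
  cfg <- timing_config(60, 2L, 10)
  P <- 1 / 60
  n <- 30L
  stuck_at <- 15L
  d <- rep(P, n); d[stuck_at + 1L] <- 2 * P
  flip <- 10 + cumsum(d)
  flip_ns <- 10 + cumsum(rep(P, n))        # the no-skip timeline
  prep <- flip - 2 * P
  prep_ns <- flip_ns - 2 * P
  mkft <- function(fl, pr) build_frame_table(
    high_precision_frames(pr[3:n], fl[(3:n) - 2L], 3:n), NULL, cfg)
  ev_frame <- 16L                          # prepared right after the stall
  st_skip <- to_screen_time(prep[ev_frame] + 0.002, mkft(flip, prep), cfg)
  st_nosk <- to_screen_time(prep_ns[ev_frame] + 0.002,
                            mkft(flip_ns, prep_ns), cfg)
  expect_equal(as.numeric(st_skip) - as.numeric(st_nosk), P,
               tolerance = 1e-9)
})

test_that("to_screen_time is monotone and flags pre-table events", {
  cfg <- timing_config(60, 2L, 18)
  p <- simulation_params(n_frames = 300L, skip_probability = 0.05,
                         timing = cfg, seed = 9L)
  s <- simulate_session(p)
  pl <- parse_log(write_temp_session(s), convert = FALSE)
  ft <- build_frame_table(pl, config = cfg)
  gt <- s$ground_truth
  set.seed(1)
  tt <- sort(runif(500, gt$prep_game_time[3], gt$prep_game_time[300]))
  st <- to_screen_time(tt, ft, cfg)
  expect_true(all(diff(as.numeric(st)) >= 0))
  # an event from before the first tabulated frame is flagged
  early <- to_screen_time(gt$prep_game_time[1], ft, cfg)
  expect_false(attr(early, "adjusted"))
  expect_true(all(attr(st, "adjusted")))
  # fallback is close to truth on a skip-free stretch
  expect_lt(abs(as.numeric(early) -
                  (gt$flip_time[1] + 0.018)), 2.5 * 1 / 60)
})
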