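# The synthetic-session simulator.

test_that("identical parameters and seed give byte-identical sessions", {
  p <- simulation_params(n_frames = 300L, seed = 17L, n_trials = 5L)
  a <- simulate_session(p)
  b <- simulate_session(p)
  expect_identical(serialize_records(a$records),
                   serialize_records(b$records))
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(as.data.frame(a$markers), as.data.frame(b$markers))
  c <- simulate_session(simulation_params(n_frames = 300L, seed = 18L,
                                          n_trials = 5L))
  expect_false(identical(a$trace$samples, c$trace$samples))
})

test_that("without skips all flip intervals equal the nominal period", {
  p <- simulation_params(n_frames = 200L, skip_probability = 0, seed = 1L)
  s <- simulate_session(p)
  iv <- diff(s$ground_truth$flip_time)
  expect_equal(iv, rep(frame_period_ms(p$timing) / 1000, 199),
               tolerance = 1e-12)
})

test_that("an injected pause blacks out the photodiode trace", {
  p <- simulation_params(
    n_frames = 400L, skip_probability = 0, noise_sd_fraction = 0,
    pauses = data.frame(at_frame = 200L, duration_frames = 30L),
    seed = 2L)
  s <- simulate_session(p)
  gt <- s$ground_truth
  expect_true(all(gt$brightness[gt$paused] == 0))
  # trace samples well inside the pause (past the rise support) are black
  t0 <- gt$display_time[200L] + 0.02
  t1 <- gt$display_time[229L]
  i <- which(s$trace$start_timestamp +
               (seq_along(s$trace$samples) - 1) / s$trace$sample_rate_hz >=
               t0 &
               s$trace$start_timestamp +
               (seq_along(s$trace$samples) - 1) / s$trace$sample_rate_hz <
               t1)
  expect_lt(max(abs(s$trace$samples[i])), 1e-6)
  # pause boundaries carry the provoked frame skips
  expect_true(gt$stuck[199L] && gt$stuck[230L])
})

test_that("markers exactly mirror the commanded brightness switches", {
  p <- simulation_params(n_frames = 500L, skip_probability = 0.02,
                         seed = 3L)
  s <- simulate_session(p)
  gt <- s$ground_truth
  n_switch <- sum(diff(gt$brightness) != 0)
  expect_equal(nrow(s$markers), n_switch)
  mk <- s$records[s$records$line_type == "EVENT_MARKER", ]
  expect_equal(nrow(mk), n_switch)
  # ids decode to the new brightness of each switch frame
  sw <- which(c(FALSE, diff(gt$brightness) != 0))
  expect_equal(brightness_marker_value(s$markers$marker_id),
               gt$brightness[sw])
})

test_that("the synthesized trace has the stated sampling, noise and step
           placement", {
  # noiseless, instantaneous photodiode: steps land on the rounded sample
  p0 <- simulation_params(n_frames = 120L, skip_probability = 0,
                          noise_sd_fraction = 0, rise_tau_ms = 0,
                          seed = 4L)
  s0 <- simulate_session(p0)
  gt <- s0$ground_truth
  tr <- s0$trace
  expect_equal(length(tr$samples),
               floor(trace_duration(tr) * tr$sample_rate_hz))
  k <- 60L   # a mid-session switch frame
  i_step <- round((gt$display_time[k] - tr$start_timestamp) *
                    tr$sample_rate_hz) + 1L
  expect_equal(tr$samples[i_step + 1L], 2 * gt$brightness[k],
               tolerance = 1e-9)
  expect_equal(tr$samples[i_step - 2L], 2 * gt$brightness[k - 1L],
               tolerance = 1e-9)

  # noise sd on flat segments matches the configured fraction within 5%
  pn <- simulation_params(n_frames = 400L, skip_probability = 0,
                          noise_sd_fraction = 0.02, rise_tau_ms = 0,
                          seed = 5L)
  sn <- simulate_session(pn)
  trn <- sn$trace
  gtn <- sn$ground_truth
  sds <- vapply(seq(20L, 380L, by = 7L), function(k) {
    i0 <- ceiling((gtn$display_time[k] - trn$start_timestamp) *
                    trn$sample_rate_hz) + 30L
    i1 <- floor((gtn$display_time[k + 1L] - trn$start_timestamp) *
                  trn$sample_rate_hz) - 30L
    stats::sd(trn$samples[i0:i1])
  }, 0)
  expect_equal(mean(sds), 0.02 * 2, tolerance = 0.05)
})

test_that("overlapping transitions warn and pause specs validate", {
  expect_error(simulation_params(n_frames = 2L), "n_frames")
  expect_error(simulation_params(skip_probability = 1.5), "probability")
  expect_error(simulation_params(
    n_frames = 100L,
    pauses = data.frame(at_frame = 90L, duration_frames = 30L)), "outside")
  p <- simulation_params(n_frames = 100L, rise_tau_ms = 20,
                         noise_sd_fraction = 0, seed = 1L)
  expect_warning(simulate_session(p), "overlap")
})

test_that("simulated trials feed the performance pipeline", {
  p <- simulation_params(n_frames = 1200L, seed = 6L, n_trials = 40L,
                         p_correct = 0.7)
  s <- simulate_session(p)
  suppressWarnings(iv <- extract_state_intervals(s$records))
  ps <- performance_summary(iv, c("CorrectResponse", "WrongResponse"),
                            "CorrectResponse", window = 20L)
  expect_equal(sum(ps$counts), 40L)
  expect_length(ps$series, 40L)
  expect_true(all(ps$series >= 0 & ps$series <= 1))
})

test_that("session artifacts write to and read back from a directory", {
  p <- simulation_params(n_frames = 150L, seed = 8L)
  s <- simulate_session(p)
  d <- tempfile()
  write_session(s, d, abbrev_verbosity = 0L)
  expect_true(file.exists(file.path(d, "session.log")))
  pl <- parse_log(file.path(d, "session.log"), convert = FALSE)
  expect_equal(nrow(pl$records), nrow(s$records))
  ab <- parse_log(file.path(d, "session_abbrev.log"), convert = FALSE)
  expect_true(all(ab$records$line_type %in% verbosity_line_types(0L)))
  mk <- read_marker_channel(file.path(d, "markers.tsv"))
  expect_identical(as.data.frame(mk), as.data.frame(s$markers))
})

test_that("the full pipeline recovers ground truth on a clean small
           session", {
  p <- simulation_params(n_frames = 800L, seed = 10L)
  s <- simulate_session(p)
  res <- verify_session(parse_log(write_temp_session(s)), s$trace,
                        s$markers, p$timing)
  expect_gt(res$n_transitions, 150L)
  expect_gte(res$stats$fraction_within(0.2), 0.98)
  expect_lt(abs(res$stats$median), 0.05)
})
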