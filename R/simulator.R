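# Synthetic sessions: a complete, ground-truthed stand-in for a recorded
# experiment -- session log, event-marker channel, photodiode trace -- so
# parsing, screen-time conversion and photodiode verification are testable
# without any hardware.

#' Simulation parameters
#'
#' @param n_frames number of game frames (>= 3; frame timing is logged from
#'   the 3rd frame onwards, as on the real system).
#' @param timing a [timing_config()]; its frame rate and pipeline depth
#'   drive the simulated engine, and its display delay is the *configured*
#'   delay an analyst would use -- the simulator's physical truth is
#'   `true_display_delay_ms`.
#' @param skip_probability per-frame probability of a stuck frame (shown
#'   for twice the nominal period).
#' @param pauses optional data frame with columns `at_frame` and
#'   `duration_frames`: during a pause the state machine stops, the screen
#'   is black, no markers are sent, and deterministic frame skips are
#'   injected at the pause boundaries (pausing is how skips are provoked on
#'   the real system).
#' @param clock_offset_s constant offset of the high-resolution clock
#'   relative to the game-thread clock.
#' @param true_display_delay_ms physical delay from graphics-card flip to
#'   light on the screen.
#' @param sample_rate_hz photodiode acquisition rate (30 kHz reference).
#' @param noise_sd_fraction Gaussian noise sd on the trace as a fraction of
#'   the full brightness amplitude.
#' @param rise_tau_ms first-order time constant of the photodiode's
#'   response to a luminance step.
#' @param seed integer seed; identical parameters and seed give
#'   byte-identical sessions.
#' @param state_start_frame frame (1-based) at which the running state
#'   machine (and with it the brightness flicker) starts.
#' @param n_trials optional number of simulated trials whose outcome states
#'   are written to the log (for performance-analysis tests).
#' @param p_correct probability a simulated trial ends in the correct
#'   outcome state.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(n_frames = 6000L, timing = timing_config(),
                              skip_probability = 0.02, pauses = NULL,
                              clock_offset_s = 0,
                              true_display_delay_ms = 18,
                              sample_rate_hz = 30000,
                              noise_sd_fraction = 0.02, rise_tau_ms = 0.5,
                              seed = 1L, state_start_frame = 5L,
                              n_trials = 0L, p_correct = 0.75) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 3L) stop("n_frames must be >= 3")
  if (skip_probability < 0 || skip_probability > 1)
    stop("skip_probability must be in [0, 1]")
  if (!is.null(pauses)) {
    stopifnot(all(c("at_frame", "duration_frames") %in% names(pauses)))
    if (any(pauses$at_frame <= 1L | pauses$at_frame +
            pauses$duration_frames > n_frames))
      stop("pause specification outside the session")
  }
  structure(list(n_frames = n_frames, timing = timing,
                 skip_probability = skip_probability, pauses = pauses,
                 clock_offset_s = clock_offset_s,
                 true_display_delay_ms = true_display_delay_ms,
                 sample_rate_hz = sample_rate_hz,
                 noise_sd_fraction = noise_sd_fraction,
                 rise_tau_ms = rise_tau_ms, seed = as.integer(seed),
                 state_start_frame = as.integer(state_start_frame),
                 n_trials = as.integer(n_trials), p_correct = p_correct),
            class = "simulation_params")
}

# object ids used by the simulator (monotone counter convention)
.SIM_IDS <- list(logger = 0L, block_machine = 1L, trial_machine = 2L,
                 flicker = 3L, player = 4L)

#' Simulate a complete session
#'
#' Generates frame flips spaced one nominal period apart except at stuck
#' frames (two periods), a session log (FRAME lines from the 3rd frame
#' onwards carrying the displayed frame's flip timestamp, EVENT_MARKER
#' lines with high-resolution timestamps at every brightness switch, INPUT
#' and POSITION lines for a wandering test object, STATE lines for the
#' running machine and optional trials), the 16-bit marker channel as the
#' acquisition system records it, the photodiode trace, and a ground-truth
#' table of every frame's true display time.
#'
#' @param params a [simulation_params()].
#' @return object of class `synthetic_session`: list with `header`,
#'   `records` (game-time log records), `markers` (a [marker_channel()]),
#'   `trace` (a [photodiode_trace()]), `ground_truth` (data frame:
#'   `frame_index`, `prep_game_time`, `flip_time`, `display_time`,
#'   `brightness`, `stuck`, `paused`), and `params`.
#' @export
simulate_session <- function(params = simulation_params()) {
  p <- params
  .with_seed(p$seed, {
    n <- p$n_frames
    q <- p$timing$pipeline_frames
    P <- frame_period_ms(p$timing) / 1000

    stuck <- stats::runif(n) < p$skip_probability
    paused <- rep(FALSE, n)
    if (!is.null(p$pauses)) {
      for (i in seq_len(nrow(p$pauses))) {
        f <- p$pauses$at_frame[i]; m <- p$pauses$duration_frames[i]
        paused[f:(f + m - 1L)] <- TRUE
        # loading hitches at the pause boundaries provoke stuck frames
        stuck[f - 1L] <- TRUE
        if (f + m <= n) stuck[f + m] <- TRUE
      }
    }

    # flip time of frame k on the high-resolution clock: one period after
    # the previous flip, two if the previous frame was stuck
    d <- c(0.5, P * (1 + as.numeric(stuck[-n])))
    flip <- cumsum(d)
    prep <- flip - q * P - p$clock_offset_s          # game-thread clock
    disp <- flip + p$true_display_delay_ms / 1000    # light on screen

    # brightness: 0.5 until the state machine starts, pattern while
    # running, black while paused; the pattern freezes during pauses
    running <- seq_len(n) >= p$state_start_frame & !paused
    pat <- flicker_sequence(sum(running))
    bright <- rep(0.5, n)
    bright[running] <- pat[-1]
    bright[paused] <- 0

    # markers at every commanded switch (running frames only)
    prev <- c(0.5, bright[-n])
    switch_f <- which(running & bright != prev)
    mk_rec <- marker_record(prep[switch_f], .SIM_IDS$flicker,
                            brightness_marker_id(bright[switch_f]),
                            prep[switch_f] + p$clock_offset_s)

    # FRAME lines from the 3rd game frame onwards; the logged flip
    # timestamp is the flip of the frame being displayed (k - pipeline)
    fr_idx <- seq.int(max(3L, q + 1L), n)
    fr_rec <- frame_record(prep[fr_idx], .SIM_IDS$logger, fr_idx,
                           flip[fr_idx - q])

    # wandering test object: smooth random walk, logged every frame
    head_deg <- cumsum(stats::rnorm(n, 0, 4)) %% 360
    vx <- cos(.deg2rad(head_deg)); vy <- sin(.deg2rad(head_deg))
    px <- cumsum(vx * P); py <- cumsum(vy * P)
    in_rec <- input_record(prep, .SIM_IDS$player, vx, vy, 0)
    dome <- cartesian_to_dome(px + 1e-9, py, rep(0, n))
    po_rec <- position_record(prep, .SIM_IDS$player, px, py, 0, head_deg,
                              dome$azimuth, dome$elevation)

    # state machine: Running intervals between pauses, optional trials
    st_list <- list()
    run_edge <- diff(c(FALSE, running))
    starts <- which(run_edge == 1L); stops <- which(run_edge == -1L) - 1L
    if (length(stops) < length(starts)) stops <- c(stops, n)
    for (i in seq_along(starts)) {
      st_list[[length(st_list) + 1L]] <-
        state_record(prep[starts[i]], .SIM_IDS$block_machine, "Running",
                     TRUE)
      st_list[[length(st_list) + 1L]] <-
        state_record(prep[stops[i]] + P / 2, .SIM_IDS$block_machine,
                     "Running", FALSE)
    }
    if (p$n_trials > 0L) {
      tf <- seq(p$state_start_frame, n - 1L,
                length.out = p$n_trials + 1L)
      outc <- ifelse(stats::runif(p$n_trials) < p$p_correct,
                     "CorrectResponse", "WrongResponse")
      for (i in seq_len(p$n_trials)) {
        t0 <- prep[ceiling(tf[i])]; t1 <- prep[floor(tf[i + 1L])]
        tm <- t0 + 0.75 * (t1 - t0)
        st_list[[length(st_list) + 1L]] <- bind_records(
          state_record(t0, .SIM_IDS$trial_machine, "Trial", TRUE),
          state_record(tm, .SIM_IDS$trial_machine, outc[i], TRUE),
          state_record(t1 - P / 4, .SIM_IDS$trial_machine, outc[i], FALSE),
          state_record(t1, .SIM_IDS$trial_machine, "Trial", FALSE))
      }
    }

    records <- do.call(bind_records,
                       c(list(mk_rec, fr_rec, in_rec, po_rec), st_list))

    trace <- synthesize_photodiode(disp, bright, p)
    markers <- marker_channel(
      round((prep[switch_f] + p$clock_offset_s - trace$start_timestamp) *
              p$sample_rate_hz),
      brightness_marker_id(bright[switch_f]))

    header <- session_header(
      level_start_time = "1970-01-01T00:00:00Z",
      subject = "synthetic", experimenter = "simulator",
      experiment = sprintf("synthetic seed %d", p$seed),
      level_name = "FlickerTest", verbosity = 3L)

    structure(list(header = header, records = records, markers = markers,
                   trace = trace,
                   ground_truth = data.frame(
                     frame_index = seq_len(n), prep_game_time = prep,
                     flip_time = flip, display_time = disp,
                     brightness = bright, stuck = stuck, paused = paused),
                   params = p),
              class = "synthetic_session")
  })
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_session> %d frames, %d records, %d ",
                     "markers, %.1f s trace\n"),
              x$params$n_frames, nrow(x$records), nrow(x$markers),
              trace_duration(x$trace)))
  invisible(x)
}

#' Synthesize the photodiode trace of a displayed brightness sequence
#'
#' Piecewise-constant luminance (frame k's brightness from its display time
#' until the next) passed through a first-order response of time constant
#' `rise_tau_ms`, mapped affinely to voltage (black 0 V, full brightness
#' 2 V), sampled at `sample_rate_hz` with additive Gaussian noise of sd
#' `noise_sd_fraction` of the full amplitude. The trace starts 50 ms before
#' the first display time and ends 50 ms after the last frame.
#'
#' Draws from the current RNG state (i.e. from the session seed when called
#' inside [simulate_session()]).
#'
#' @param display_times increasing vector of true display times (seconds,
#'   acquisition clock).
#' @param brightness brightness value of each frame, same length.
#' @param params a [simulation_params()].
#' @return a [photodiode_trace()].
#' @export
synthesize_photodiode <- function(display_times, brightness, params) {
  if (is.unsorted(display_times, strictly = TRUE))
    stop("display times must be increasing")
  fs <- params$sample_rate_hz
  tau <- params$rise_tau_ms / 1000
  if (tau > 0 && any(diff(display_times) < 3 * tau))
    warning("some display intervals are shorter than the rise support; ",
            "transitions will overlap")
  amp <- 2                       # volts at full brightness
  t0 <- display_times[1] - 0.05
  t_end <- display_times[length(display_times)] +
    stats::median(diff(display_times)) + 0.05
  ns <- floor((t_end - t0) * fs)
  ts <- t0 + (seq_len(ns) - 1L) / fs
  target <- amp * brightness[pmax(1L, findInterval(ts, display_times))]
  target[ts < display_times[1]] <- amp * 0   # dark before the first frame
  if (tau <= 0) {
    v <- target
  } else {
    # exact first-order response: each luminance step launches an
    # exponential from the analog state at the (continuous) display time,
    # so edge positions in the trace are not quantized to the sample grid
    v <- numeric(ns)
    seg_t <- c(t0, display_times)                 # segment start times
    seg_L <- c(0, amp * brightness)               # segment target levels
    first <- findInterval(seg_t - t0, (seq_len(ns) - 1L) / fs) + 1L
    first[1] <- 1L
    last <- c(first[-1] - 1L, ns)
    state <- 0
    for (b in seq_along(seg_t)) {
      L <- seg_L[b]
      if (last[b] >= first[b]) {
        tt <- ts[first[b]:last[b]] - seg_t[b]
        v[first[b]:last[b]] <- L + (state - L) * exp(-tt / tau)
      }
      t_next <- if (b < length(seg_t)) seg_t[b + 1L] else t_end
      state <- L + (state - L) * exp(-(t_next - seg_t[b]) / tau)
    }
  }
  if (params$noise_sd_fraction > 0)
    v <- v + stats::rnorm(ns, 0, params$noise_sd_fraction * amp)
  photodiode_trace(v, fs, t0)
}

#' Write the artifacts of a synthetic session to a directory
#'
#' Writes `session.log` (continuous), `session_abbrev.log` (at the given
#' verbosity), `markers.tsv`, `trace.tsv` (two-column time / voltage text)
#' and `ground_truth.tsv`.
#'
#' @param session a [simulate_session()] result.
#' @param dir output directory (created if needed).
#' @param abbrev_verbosity verbosity of the abbreviated log, or `NULL` to
#'   skip it.
#' @param write_trace logical; the trace file is large (one line per
#'   sample) and only needed for external tools.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, abbrev_verbosity = 0L,
                          write_trace = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_log(session$records, session$header, file.path(dir, "session.log"))
  if (!is.null(abbrev_verbosity))
    write_log(session$records, session$header,
              file.path(dir, "session_abbrev.log"),
              verbosity = abbrev_verbosity)
  write_marker_channel(session$markers, file.path(dir, "markers.tsv"))
  utils::write.table(session$ground_truth,
                     file.path(dir, "ground_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (write_trace) {
    tr <- session$trace
    df <- data.frame(
      time = sprintf("%.7f", tr$start_timestamp +
                       (seq_along(tr$samples) - 1L) / tr$sample_rate_hz),
      voltage = sprintf("%.6f", tr$samples))
    utils::write.table(df, file.path(dir, "trace.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
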