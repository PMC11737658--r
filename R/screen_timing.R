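# Conversion of game-thread event times to on-screen display times.
#
# A game engine prepares frames ahead of display: an event logged at
# game-thread time t during the preparation of frame k is not visible until
# frame k is flipped by the graphics card and, after the projector's own
# latency, physically shown. The raw log records, on every FRAME line, the
# index of the frame being prepared together with the flip timestamp of the
# frame being *displayed* at that moment (pipeline_frames earlier). The
# frame table re-indexes those flip timestamps so each frame is paired with
# its own actual flip, which makes the conversion exact even across frame
# skips (stuck frames shown for twice the nominal period).

#' Display-timing configuration
#'
#' @param frame_rate_hz display refresh rate in Hz (the reference dome setup
#'   runs at 59.952 Hz).
#' @param pipeline_frames number of frames between a frame's preparation and
#'   its flip; the multi-camera dome projection needs two.
#' @param display_delay_ms delay from graphics-card flip to physical
#'   appearance on the screen (a projector latency; 18 ms for the reference
#'   setup).
#' @return object of class `timing_config`.
#' @export
timing_config <- function(frame_rate_hz = 59.952, pipeline_frames = 2L,
                          display_delay_ms = 18) {
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("frame_rate_hz must be > 0")
  pipeline_frames <- as.integer(pipeline_frames)
  if (is.na(pipeline_frames) || pipeline_frames < 0L)
    stop("pipeline_frames must be a non-negative integer")
  if (!is.numeric(display_delay_ms) || display_delay_ms < 0)
    stop("display_delay_ms must be >= 0")
  structure(list(frame_rate_hz = frame_rate_hz,
                 pipeline_frames = pipeline_frames,
                 display_delay_ms = display_delay_ms),
            class = "timing_config")
}

#' @export
print.timing_config <- function(x, ...) {
  cat(sprintf(paste0("<timing_config> %.4g Hz (period %.4f ms), pipeline %d",
                     " frame(s), display delay %.3f ms\n"),
              x$frame_rate_hz, frame_period_ms(x), x$pipeline_frames,
              x$display_delay_ms))
  invisible(x)
}

#' @rdname timing_config
#' @param config a `timing_config`.
#' @return `frame_period_ms()`: the nominal frame period in milliseconds.
#' @export
frame_period_ms <- function(config) 1000 / config$frame_rate_hz

#' Fixed display delay of a configuration
#'
#' The a-priori latency between an event's game-thread frame and its physical
#' appearance: `pipeline_frames` nominal frame periods of rendering pipeline
#' plus the projector delay. For the reference dome configuration
#' (59.952 Hz, 2 frames, 18 ms) this is 51.360 ms.
#'
#' @param config a [timing_config()].
#' @return fixed delay in milliseconds.
#' @export
fixed_display_delay <- function(config) {
  config$pipeline_frames * frame_period_ms(config) + config$display_delay_ms
}

#' Read / write a timing configuration file
#'
#' Plain `key: value` text with keys `frame_rate_hz`, `pipeline_frames`,
#' `display_delay_ms`; missing keys take the defaults of [timing_config()].
#'
#' @param path file path.
#' @return [read_timing_config()]: a `timing_config`.
#' @export
read_timing_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl(":", lines, fixed = TRUE) & !startsWith(lines, "#")]
  keys <- trimws(sub(":.*$", "", lines))
  vals <- as.numeric(trimws(sub("^[^:]*:", "", lines)))
  kv <- stats::setNames(as.list(vals), keys)
  d <- timing_config()
  timing_config(
    frame_rate_hz = if (is.null(kv$frame_rate_hz)) d$frame_rate_hz
    else kv$frame_rate_hz,
    pipeline_frames = if (is.null(kv$pipeline_frames)) d$pipeline_frames
    else kv$pipeline_frames,
    display_delay_ms = if (is.null(kv$display_delay_ms)) d$display_delay_ms
    else kv$display_delay_ms)
}

#' @rdname read_timing_config
#' @param config a [timing_config()] to write.
#' @export
write_timing_config <- function(config, path) {
  writeLines(c(sprintf("frame_rate_hz: %.10g", config$frame_rate_hz),
               sprintf("pipeline_frames: %d", config$pipeline_frames),
               sprintf("display_delay_ms: %.10g", config$display_delay_ms)),
             path)
  invisible(path)
}

#' Build the frame table of a log
#'
#' Turns the FRAME records of a log (frame index being prepared + flip
#' timestamp of the frame being displayed) into a table pairing each frame's
#' preparation interval with that frame's *own* actual flip timestamp. The
#' flip of frame k is read from the FRAME line of frame `k + pipeline_frames`
#' (where it was the displayed frame); the last `pipeline_frames` frames
#' have no such line yet and are extrapolated at the nominal period
#' (flagged in the `extrapolated` column).
#'
#' EVENT_MARKER records, which carry both a game-thread time and a
#' high-resolution timestamp, provide anchor pairs for a piecewise-linear
#' monotone map between the two clocks, used by the fallback conversion for
#' events logged before the first tabulated frame.
#'
#' @param frame_records data frame of parsed FRAME records (columns `time`
#'   and `payload`), or a `log_records` / `parsed_log` containing them.
#' @param marker_records data frame of parsed EVENT_MARKER records (columns
#'   `time` and `payload`); may be empty.
#' @param config a [timing_config()].
#' @return object of class `frame_table`: a data frame with columns
#'   `frame_index`, `prep_game_time`, `flip_time`, `extrapolated`, plus
#'   attributes `anchors` (game time / high-resolution timestamp pairs) and
#'   `fallback_offset_s` (median logged flip minus preparation time).
#' @export
build_frame_table <- function(frame_records, marker_records = NULL, config) {
  if (inherits(frame_records, "parsed_log")) {
    rec <- frame_records$records
    if (is.null(marker_records))
      marker_records <- rec[rec$line_type == "EVENT_MARKER", , drop = FALSE]
    frame_records <- rec[rec$line_type == "FRAME", , drop = FALSE]
  }
  if (is.null(marker_records))
    marker_records <- data.frame(time = numeric(), payload = character())
  n <- nrow(frame_records)
  if (is.null(n) || n < 2L)
    stop("need at least 2 FRAME records to build a frame table")
  p <- strsplit(frame_records$payload, "\t", fixed = TRUE)
  idx <- as.integer(vapply(p, `[`, "", 1L))
  flip_logged <- as.numeric(vapply(p, `[`, "", 2L))
  o <- order(idx)
  idx <- idx[o]; flip_logged <- flip_logged[o]
  prep <- frame_records$time[o]
  if (any(diff(idx) != 1L))
    stop("frame indices are not contiguous from the first logged frame")
  if (any(diff(flip_logged) <= 0))
    stop("flip timestamps are not strictly increasing")
  q <- config$pipeline_frames
  P <- frame_period_ms(config) / 1000
  flip_own <- rep(NA_real_, n)
  extrap <- rep(FALSE, n)
  if (q == 0L) {
    flip_own <- flip_logged
  } else {
    head_n <- n - q
    if (head_n > 0L) flip_own[seq_len(head_n)] <- flip_logged[-seq_len(q)]
    tail_i <- seq.int(max(head_n + 1L, 1L), n)
    flip_own[tail_i] <- flip_logged[n] + (tail_i - head_n) * P
    extrap[tail_i] <- TRUE
  }
  anchors <- NULL
  if (nrow(marker_records)) {
    mp <- strsplit(marker_records$payload, "\t", fixed = TRUE)
    hr <- as.numeric(vapply(mp, `[`, "", 2L))
    anchors <- data.frame(game_time = marker_records$time, hr_time = hr)
    anchors <- anchors[order(anchors$game_time), , drop = FALSE]
    anchors <- anchors[!duplicated(anchors$game_time), , drop = FALSE]
    if (is.unsorted(anchors$hr_time))
      warning("clock anchors are not monotone; fallback conversion may be ",
              "inaccurate")
  }
  out <- data.frame(frame_index = idx, prep_game_time = prep,
                    flip_time = flip_own, extrapolated = extrap)
  attr(out, "anchors") <- anchors
  attr(out, "fallback_offset_s") <- stats::median(flip_logged - prep)
  class(out) <- c("frame_table", "data.frame")
  out
}

#' Map a game-thread time onto the high-resolution clock
#'
#' Piecewise-linear interpolation between the event-marker clock anchors of
#' a frame table, with linear extrapolation beyond the first and last anchor.
#'
#' @param game_time numeric vector of game-thread times (seconds).
#' @param table a [build_frame_table()] result.
#' @return numeric vector of high-resolution clock times; if the table has
#'   fewer than 2 anchors, a constant-offset map from the available anchor
#'   (or the fallback offset) is used.
#' @export
anchor_clock_map <- function(game_time, table) {
  a <- attr(table, "anchors")
  if (is.null(a) || nrow(a) < 2L) {
    # without two anchors, fall back to a constant offset: the single anchor
    # if present, else the median logged flip - preparation offset (which
    # carries the clock offset in steady state)
    off <- if (!is.null(a) && nrow(a) == 1L) a$hr_time - a$game_time
    else attr(table, "fallback_offset_s")
    return(game_time + off)
  }
  n <- nrow(a)
  y <- stats::approx(a$game_time, a$hr_time, xout = game_time,
                     rule = 2)$y
  # linear extrapolation at the edges (approx rule=2 clamps)
  lo <- game_time < a$game_time[1]
  hi <- game_time > a$game_time[n]
  if (any(lo)) {
    s <- (a$hr_time[2] - a$hr_time[1]) / (a$game_time[2] - a$game_time[1])
    y[lo] <- a$hr_time[1] + s * (game_time[lo] - a$game_time[1])
  }
  if (any(hi)) {
    s <- (a$hr_time[n] - a$hr_time[n - 1]) /
      (a$game_time[n] - a$game_time[n - 1])
    y[hi] <- a$hr_time[n] + s * (game_time[hi] - a$game_time[n])
  }
  y
}

#' Detect frame skips in a frame table
#'
#' A stuck frame is shown for twice the nominal period, so the flip interval
#' that follows it is about two periods long. Any flip interval longer than
#' 1.5 nominal periods (the midpoint between one and two periods, robust to
#' jitter far below half a period) is reported as a skip of the frame on its
#' left.
#'
#' @param table a [build_frame_table()] result.
#' @param config a [timing_config()].
#' @return integer vector of frame indices that were stuck (empty if none).
#' @export
detect_frame_skips <- function(table, config) {
  P <- frame_period_ms(config) / 1000
  iv <- diff(table$flip_time)
  table$frame_index[which(iv > 1.5 * P)]
}

#' Convert game-thread times to on-screen display times
#'
#' An event belongs to the frame whose preparation interval (half-open on
#' preparation start times) contains its game-thread time; its screen time
#' is that frame's actual flip timestamp plus the configured display delay.
#' Events logged during a stuck frame therefore inherit that frame's late
#' actual flip. Events before the first tabulated frame fall back to the
#' anchor clock map plus [fixed_display_delay()] and are flagged as
#' unadjusted approximations.
#'
#' @param game_time numeric vector of game-thread times (seconds).
#' @param table a [build_frame_table()] result.
#' @param config a [timing_config()].
#' @return numeric vector of screen times (seconds, high-resolution clock)
#'   with a logical attribute `adjusted` (`FALSE` where the fallback was
#'   used).
#' @export
to_screen_time <- function(game_time, table, config) {
  k <- findInterval(game_time, table$prep_game_time)
  out <- numeric(length(game_time))
  adj <- k >= 1L
  if (any(adj))
    out[adj] <- table$flip_time[k[adj]] + config$display_delay_ms / 1000
  if (any(!adj)) {
    # median(logged flip - prep) carries the clock offset; the fixed delay
    # adds the pipeline and projector latency
    out[!adj] <- game_time[!adj] + attr(table, "fallback_offset_s") +
      fixed_display_delay(config) / 1000
  }
  attr(out, "adjusted") <- adj
  out
}
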