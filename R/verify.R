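# End-to-end timing verification: log + photodiode trace + marker channel
# -> residual statistics.

#' Brightness-switch marker ids
#'
#' The brightness-switching object sends one event marker per brightness
#' change. The toolkit reserves marker ids 2000--2100 for these, encoding
#' the new brightness level in hundredths: id = 2000 + round(100 * value).
#'
#' @param value brightness in `[0, 1]`.
#' @param id marker id.
#' @return the marker id, or the decoded brightness.
#' @export
brightness_marker_id <- function(value) 2000L + as.integer(round(100 * value))

#' @rdname brightness_marker_id
#' @export
brightness_marker_value <- function(id) (as.integer(id) - 2000L) / 100

#' @rdname brightness_marker_id
#' @export
is_brightness_marker <- function(id) id >= 2000L & id <= 2100L

#' Verify display timing against a photodiode recording
#'
#' Runs the full verification pipeline: parse the session log with
#' screen-time conversion, select the brightness-switch event markers of a
#' chosen transition (by default the full-contrast falling transition from
#' brightness 1 to 0, the transition used for the reference timing
#' analysis), map the predicted screen times onto the acquisition clock via
#' the marker channel, measure each transition's max-change time in the
#' low-pass-filtered trace, and summarize the residuals.
#'
#' The log's high-resolution clock and the acquisition clock are related by
#' a least-squares linear fit between the markers' logged timestamps and
#' their recorded acquisition times, so a constant offset and slow drift are
#' both absorbed.
#'
#' @param log a log file path or a [parse_log()] result (parsed with
#'   `convert = TRUE`).
#' @param trace a [photodiode_trace()].
#' @param markers a [marker_channel()].
#' @param config a [timing_config()].
#' @param from,to brightness levels selecting the analyzed transition;
#'   `to < from` gives falling polarity.
#' @param window_ms analysis half-window around each prediction.
#' @param cutoff_hz,order Butterworth design for the trace filtering.
#' @param edge_tau_ms photodiode rise time constant for the
#'   instrument-response correction (see [transition_residual()]).
#' @return list with `stats` (an [alignment_stats()]), `residuals_ms`,
#'   `predicted`, `n_transitions`, and `clock_fit` (intercept/slope of the
#'   log-to-acquisition clock map).
#' @export
verify_session <- function(log, trace, markers, config = timing_config(),
                           from = 1, to = 0, window_ms = 5,
                           cutoff_hz = 500, order = 4, edge_tau_ms = 0.5) {
  if (!inherits(log, "parsed_log"))
    log <- parse_log(log, types = "EVENT_MARKER", convert = TRUE,
                     config = config)
  if (!log$converted)
    stop("the log must be parsed with convert = TRUE")
  rec <- log$records
  rec <- rec[rec$line_type == "EVENT_MARKER", , drop = FALSE]
  p <- strsplit(rec$payload, "\t", fixed = TRUE)
  ids <- as.integer(vapply(p, `[`, "", 1L))
  hr <- as.numeric(vapply(p, `[`, "", 2L))
  bright <- is_brightness_marker(ids)
  if (!any(bright)) stop("the log contains no brightness-switch markers")
  rec <- rec[bright, , drop = FALSE]
  ids <- ids[bright]; hr <- hr[bright]

  # pair log markers with acquisition markers by order within the
  # brightness-marker stream
  acq <- markers[is_brightness_marker(markers$marker_id), , drop = FALSE]
  if (nrow(acq) != length(ids))
    stop("marker channel has ", nrow(acq), " brightness markers but the ",
         "log has ", length(ids), "; cannot pair them")
  if (any(acq$marker_id != ids))
    stop("marker id sequences of log and acquisition channel disagree")
  acq_time <- trace$start_timestamp + acq$sample_index / trace$sample_rate_hz
  clock_fit <- if (length(hr) >= 2L) {
    f <- stats::lm.fit(cbind(1, hr), acq_time)
    c(intercept = unname(f$coefficients[1]),
      slope = unname(f$coefficients[2]))
  } else c(intercept = acq_time - hr, slope = 1)

  vals <- brightness_marker_value(ids)
  sel <- which(vals == to & c(NA, vals[-length(vals)]) == from)
  if (!length(sel))
    stop("no ", from, " -> ", to, " brightness transitions in the log")
  predicted_hr <- rec$time[sel]             # screen times (hr clock)
  predicted <- clock_fit["intercept"] + clock_fit["slope"] * predicted_hr

  filt <- lowpass_filter(trace, cutoff_hz, order)
  polarity <- if (to < from) "falling" else "rising"
  residuals_ms <- vapply(predicted, function(tp)
    transition_residual(filt, tp, window_ms = window_ms,
                        polarity = polarity, cutoff_hz = cutoff_hz,
                        order = order, edge_tau_ms = edge_tau_ms,
                        filtered = TRUE), 0)
  list(stats = alignment_stats(residuals_ms), residuals_ms = residuals_ms,
       predicted = predicted, n_transitions = length(predicted),
       clock_fit = clock_fit)
}
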