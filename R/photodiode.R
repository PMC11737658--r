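# Photodiode-based verification of display timing.
#
# A brightness-switching object rendered over a photodiode produces one
# luminance transition per displayed frame. Aligning the measured transition
# times to the screen times predicted from the log quantifies the end-to-end
# timing accuracy of the whole display chain.

#' Photodiode voltage trace
#'
#' @param samples numeric vector of voltages.
#' @param sample_rate_hz sampling rate (30 kHz on the reference acquisition
#'   system).
#' @param start_timestamp acquisition-clock time of the first sample
#'   (seconds).
#' @return object of class `photodiode_trace`.
#' @export
photodiode_trace <- function(samples, sample_rate_hz = 30000,
                             start_timestamp = 0) {
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be > 0")
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz,
                 start_timestamp = start_timestamp),
            class = "photodiode_trace")
}

#' @export
print.photodiode_trace <- function(x, ...) {
  cat(sprintf("<photodiode_trace> %d samples at %g Hz (%.3f s from t=%.4f)\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz, x$start_timestamp))
  invisible(x)
}

#' Trace duration in seconds
#' @param trace a [photodiode_trace()].
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$sample_rate_hz

#' Event-marker channel
#'
#' 16-bit event markers as recorded by the acquisition system: a sample
#' index on the acquisition clock plus the marker id.
#'
#' @param sample_index strictly increasing integer sample indices (0-based,
#'   relative to the first trace sample).
#' @param marker_id integer marker codes, 0--65535.
#' @return data frame of class `marker_channel`.
#' @export
marker_channel <- function(sample_index, marker_id) {
  sample_index <- as.integer(round(sample_index))
  marker_id <- as.integer(marker_id)
  if (any(marker_id < 0L | marker_id > 65535L))
    stop("marker_id must fit in 16 bits (0..65535)")
  if (is.unsorted(sample_index, strictly = TRUE))
    stop("sample indices must be strictly increasing")
  structure(data.frame(sample_index = sample_index, marker_id = marker_id),
            class = c("marker_channel", "data.frame"))
}

#' Read / write a marker channel file
#'
#' Two-column tab-separated text: sample_index, marker_id.
#'
#' @param path file path.
#' @return [read_marker_channel()]: a [marker_channel()].
#' @export
read_marker_channel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  marker_channel(df$sample_index, df$marker_id)
}

#' @rdname read_marker_channel
#' @param markers a [marker_channel()].
#' @export
write_marker_channel <- function(markers, path) {
  utils::write.table(as.data.frame(markers), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Filtering ------------------------------------------------------------------

#' Low-pass filter a photodiode trace
#'
#' Butterworth low-pass of the stated order. By default the filter is
#' applied forward and backward (zero phase), so filtering introduces no
#' delay into measured transition times; `zero_phase = FALSE` gives the
#' causal single pass (with the textbook -3 dB gain at the cutoff).
#'
#' @param trace a [photodiode_trace()] (or bare numeric vector, returned as
#'   such).
#' @param cutoff_hz cutoff frequency (500 Hz for the reference analysis).
#' @param order filter order (4 for the reference analysis).
#' @param zero_phase logical; forward-backward application.
#' @return the filtered trace, same class and length as the input.
#' @export
lowpass_filter <- function(trace, cutoff_hz = 500, order = 4,
                           zero_phase = TRUE) {
  x <- if (inherits(trace, "photodiode_trace")) trace$samples else trace
  fs <- if (inherits(trace, "photodiode_trace")) trace$sample_rate_hz
  else attr(trace, "sample_rate_hz")
  if (is.null(fs)) stop("sample rate unknown; pass a photodiode_trace")
  if (cutoff_hz >= fs / 2)
    stop("cutoff (", cutoff_hz, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  y <- if (zero_phase) .filtfilt_padded(bf, x, fs, cutoff_hz, order)
  else as.numeric(signal::filter(bf, x))
  if (inherits(trace, "photodiode_trace")) {
    trace$samples <- y
    trace
  } else structure(y, sample_rate_hz = fs)
}

#' Analytic Butterworth amplitude response
#'
#' Magnitude of the order-n Butterworth low-pass at frequency `f`:
#' `1 / sqrt(1 + (f / cutoff)^(2 * order))`. Used as the closed-form oracle
#' for the filter implementation.
#'
#' @param f frequency (same units as `cutoff_hz`).
#' @param cutoff_hz cutoff frequency.
#' @param order filter order.
#' @return single-pass amplitude gain.
#' @export
butterworth_gain <- function(f, cutoff_hz, order = 4) {
  1 / sqrt(1 + (f / cutoff_hz)^(2 * order))
}

# zero-phase filtering with odd-symmetric reflection padding, so edge
# transients (from the implicit zero initial conditions) stay out of the
# signal; pad length covers several filter settling times
.filtfilt_padded <- function(bf, x, fs, cutoff_hz, order) {
  n <- length(x)
  pad <- min(n - 1L, max(3L * (order + 1L),
                         as.integer(round(6 * fs / cutoff_hz))))
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[seq(pad + 1L, pad + n)]
}

# Transition timing ----------------------------------------------------------

# Deterministic offset of the max-change estimator for a first-order edge of
# time constant tau passed through the zero-phase filter: measured by
# running template edges through the identical pipeline, averaged over
# sub-sample phases. Cached per (fs, cutoff, order, tau).
.bias_cache <- new.env(parent = emptyenv())

estimator_edge_bias <- function(sample_rate_hz, cutoff_hz, order,
                                edge_tau_ms) {
  key <- sprintf("%g|%g|%g|%g", sample_rate_hz, cutoff_hz, order,
                 edge_tau_ms)
  if (!is.null(.bias_cache[[key]])) return(.bias_cache[[key]])
  dt <- 1 / sample_rate_hz
  tau <- edge_tau_ms / 1000
  n <- max(4096L, as.integer(round(0.2 * sample_rate_hz)))
  t <- (seq_len(n) - 1L) * dt
  t0c <- t[n %/% 2]
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2), type = "low")
  phases <- (0:7) / 8 * dt
  bias <- vapply(phases, function(ph) {
    t0 <- t0c + ph
    v <- if (tau <= 0) ifelse(t < t0, 1, 0)
    else ifelse(t < t0, 1, exp(-(t - t0) / tau))
    d <- diff(.filtfilt_padded(bf, v, sample_rate_hz, cutoff_hz, order))
    i <- which.min(d)
    .parabolic_peak_time(d, i, dt) - t0
  }, 0)
  .bias_cache[[key]] <- mean(bias)
  .bias_cache[[key]]
}

# sub-sample refinement: quadratic vertex through d[i-1], d[i], d[i+1];
# d[i] spans samples i..i+1, so its time is (i - 0.5) * dt (0-based start)
.parabolic_peak_time <- function(d, i, dt) {
  off <- 0
  if (i > 1L && i < length(d)) {
    den <- d[i - 1] - 2 * d[i] + d[i + 1]
    if (is.finite(den) && abs(den) > 0)
      off <- 0.5 * (d[i - 1] - d[i + 1]) / den
    if (!is.finite(off) || abs(off) > 1) off <- 0
  }
  (i - 0.5 + off) * dt
}

#' Measure one brightness-transition residual
#'
#' Finds the time of maximum signal change (the extreme of the first
#' difference of the low-pass-filtered trace, sign-selected by `polarity`)
#' inside a window around the predicted screen time, and returns
#' measured minus predicted time in milliseconds.
#'
#' Two refinements make the statistic usable at sub-sample precision: the
#' extreme is interpolated parabolically between samples, and when
#' `edge_tau_ms` is given the deterministic displacement that the filter
#' induces on a first-order edge of that time constant is subtracted
#' (instrument-response correction; see the package vignette). A transition
#' whose matching-polarity extreme does not rise above the noise floor
#' (5 times the median absolute first difference of the window's flanks),
#' or is dominated by an opposite-polarity change, yields `NA`.
#'
#' @param trace a [photodiode_trace()]; pass `filtered = TRUE` if it has
#'   already been zero-phase filtered (one whole-trace filtering pass is
#'   much faster when measuring many transitions).
#' @param predicted_time predicted screen time of the transition on the
#'   acquisition clock (seconds).
#' @param window_ms half-width of the analysis window around the prediction.
#' @param polarity `"falling"` or `"rising"`.
#' @param cutoff_hz,order filter design (used for filtering when
#'   `filtered = FALSE`, and always for the edge-bias correction).
#' @param edge_tau_ms photodiode first-order rise time constant used for the
#'   instrument-response correction; `NULL` disables the correction.
#' @param filtered logical; see `trace`.
#' @return residual in milliseconds (possibly `NA`).
#' @export
transition_residual <- function(trace, predicted_time, window_ms = 5,
                                polarity = c("falling", "rising"),
                                cutoff_hz = 500, order = 4,
                                edge_tau_ms = NULL, filtered = FALSE) {
  polarity <- match.arg(polarity)
  fs <- trace$sample_rate_hz
  dt <- 1 / fs
  w <- window_ms / 1000
  t_rel <- predicted_time - trace$start_timestamp
  n <- length(trace$samples)
  i0 <- floor((t_rel - w) * fs) + 1L
  i1 <- ceiling((t_rel + w) * fs) + 1L
  if (i0 < 1L || i1 > n)
    stop("analysis window [", t_rel - w, ", ", t_rel + w,
         "] s lies (partly) outside the trace")
  x <- if (filtered) trace$samples else {
    pad <- as.integer(round(0.01 * fs))
    j0 <- max(1L, i0 - pad); j1 <- min(n, i1 + pad)
    seg <- lowpass_filter(photodiode_trace(trace$samples[j0:j1], fs),
                          cutoff_hz, order)$samples
    full <- trace$samples
    full[j0:j1] <- seg
    full
  }
  d <- diff(x[i0:i1])
  nd <- length(d)
  flank <- c(seq_len(max(1L, nd %/% 4)),
             seq.int(nd - max(1L, nd %/% 4) + 1L, nd))
  floor_lvl <- 5 * stats::median(abs(d[flank]))
  if (polarity == "falling") {
    i <- which.min(d); amp <- -d[i]; opp <- max(d)
  } else {
    i <- which.max(d); amp <- d[i]; opp <- -min(d)
  }
  if (!is.finite(amp) || amp <= floor_lvl || amp < 0.5 * opp)
    return(NA_real_)
  t_meas <- trace$start_timestamp + (i0 - 1L) * dt +
    .parabolic_peak_time(d, i, dt)
  if (!is.null(edge_tau_ms))
    t_meas <- t_meas - estimator_edge_bias(fs, cutoff_hz, order, edge_tau_ms)
  (t_meas - predicted_time) * 1000
}

# Residual statistics ---------------------------------------------------------

#' Summarize alignment residuals
#'
#' @param residuals_ms numeric vector of per-transition residuals in
#'   milliseconds (measured max-change time minus predicted screen time);
#'   `NA` entries (missed transitions) are counted and dropped.
#' @return object of class `alignment_stats` with fields `residuals`,
#'   `n`, `n_missing`, `median`, `p05`, `p95`, and functions
#'   `fraction_within(tol_ms)` (fraction of residuals with `|r| <= tol`) and
#'   `central_width(p)` (width of the central `p` interval of the residual
#'   distribution, the convention in which "90% aligned to within X ms"
#'   means the 5th-to-95th percentile range spans X ms). Percentiles use
#'   linear interpolation between order statistics.
#' @export
alignment_stats <- function(residuals_ms) {
  n_missing <- sum(is.na(residuals_ms))
  r <- residuals_ms[!is.na(residuals_ms)]
  if (!length(r)) stop("no residuals to summarize")
  q <- stats::quantile(r, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  structure(list(
    residuals = r, n = length(r), n_missing = n_missing,
    median = q[2], p05 = q[1], p95 = q[3],
    fraction_within = function(tol_ms) mean(abs(r) <= tol_ms),
    central_width = function(p) {
      qq <- stats::quantile(r, c((1 - p) / 2, (1 + p) / 2), names = FALSE,
                            type = 7)
      qq[2] - qq[1]
    }), class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(sprintf(paste0("<alignment_stats> n = %d (%d missed)\n",
                     "  median %.4f ms, p05 %.4f ms, p95 %.4f ms\n",
                     "  within 0.1667 ms: %.1f%%   within 0.2 ms: %.1f%%\n"),
              x$n, x$n_missing, x$median, x$p05, x$p95,
              100 * x$fraction_within(0.1667), 100 * x$fraction_within(0.2)))
  invisible(x)
}
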