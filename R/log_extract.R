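# Extraction of analysis-ready tables from parsed logs.

.records_of <- function(log) {
  if (inherits(log, "parsed_log")) log$records else log
}

.payload_cols <- function(payload) strsplit(payload, "\t", fixed = TRUE)

#' Extract the trajectory of one object
#'
#' Collects all POSITION records of `object_id`, in time order, into one
#' sample per logged frame.
#'
#' @param log a `parsed_log` (see [parse_log()]) or a `log_records` data
#'   frame.
#' @param object_id integer identity of the tracked object.
#' @return data frame with columns `time`, `x`, `y`, `z`, `rotation` and,
#'   when the log carries dome angles, `azimuth` and `elevation`.
#' @export
extract_trajectory <- function(log, object_id) {
  rec <- .records_of(log)
  rec <- rec[rec$line_type == "POSITION" & rec$object_id == object_id, ,
             drop = FALSE]
  if (!nrow(rec)) {
    warning("no POSITION records for object ", object_id)
    return(data.frame(time = numeric(), x = numeric(), y = numeric(),
                      z = numeric(), rotation = numeric()))
  }
  rec <- rec[order(rec$time, method = "radix"), , drop = FALSE]
  p <- .payload_cols(rec$payload)
  out <- data.frame(time = rec$time,
                    x = as.numeric(vapply(p, `[`, "", 1L)),
                    y = as.numeric(vapply(p, `[`, "", 2L)),
                    z = as.numeric(vapply(p, `[`, "", 3L)),
                    rotation = as.numeric(vapply(p, `[`, "", 4L)))
  if (all(lengths(p) >= 6L)) {
    out$azimuth <- as.numeric(vapply(p, `[`, "", 5L))
    out$elevation <- as.numeric(vapply(p, `[`, "", 6L))
  }
  rownames(out) <- NULL
  out
}

#' Path length of a trajectory
#'
#' @param trajectory a data frame from [extract_trajectory()].
#' @return total Euclidean path length in engine units.
#' @export
trajectory_path_length <- function(trajectory) {
  if (nrow(trajectory) < 2L) return(0)
  d <- sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2 +
              diff(trajectory$z)^2)
  sum(d)
}

#' Extract state intervals from a log
#'
#' Pairs STATE_ENTER/STATE_EXIT records per state machine (identified by its
#' object id) in stack order, so nested machines (a block containing trials)
#' produce nested, consistent intervals.
#'
#' A STATE_EXIT without a matching STATE_ENTER is an error naming the state;
#' states still open at the end of the file (a truncated session) produce an
#' interval with `exit_time = NA` and a warning.
#'
#' @param log a `parsed_log` or `log_records` data frame.
#' @return data frame with columns `state_name`, `enter_time`, `exit_time`,
#'   `machine_id`, ordered by `enter_time`.
#' @export
extract_state_intervals <- function(log) {
  rec <- .records_of(log)
  rec <- rec[rec$line_type %in% c("STATE_ENTER", "STATE_EXIT"), ,
             drop = FALSE]
  empty <- data.frame(state_name = character(), enter_time = numeric(),
                      exit_time = numeric(), machine_id = integer())
  if (!nrow(rec)) return(empty)
  o <- order(rec$time, method = "radix")
  rec <- rec[o, , drop = FALSE]
  out_name <- character(); out_enter <- numeric(); out_exit <- numeric()
  out_mid <- integer()
  stacks <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(rec))) {
    mid <- as.character(rec$object_id[i])
    st <- if (exists(mid, envir = stacks)) get(mid, envir = stacks)
    else list()
    nm <- sub("\t.*$", "", rec$payload[i])
    if (rec$line_type[i] == "STATE_ENTER") {
      st[[length(st) + 1L]] <- list(name = nm, t = rec$time[i])
      assign(mid, st, envir = stacks)
    } else {
      if (!length(st))
        stop("STATE_EXIT of '", nm, "' (machine ", mid, ", record ", i,
             ") without a matching STATE_ENTER")
      top <- st[[length(st)]]
      if (!identical(top$name, nm))
        stop("STATE_EXIT of '", nm, "' (machine ", mid, ", record ", i,
             ") does not match open state '", top$name, "'")
      out_name <- c(out_name, nm)
      out_enter <- c(out_enter, top$t)
      out_exit <- c(out_exit, rec$time[i])
      out_mid <- c(out_mid, rec$object_id[i])
      st[[length(st)]] <- NULL
      assign(mid, st, envir = stacks)
    }
  }
  open_n <- 0L
  for (mid in ls(stacks)) {
    st <- get(mid, envir = stacks)
    for (s in st) {
      out_name <- c(out_name, s$name)
      out_enter <- c(out_enter, s$t)
      out_exit <- c(out_exit, NA_real_)
      out_mid <- c(out_mid, as.integer(mid))
      open_n <- open_n + 1L
    }
  }
  if (open_n)
    warning(open_n, " state(s) still open at end of log (truncated ",
            "session); exit_time set to NA")
  out <- data.frame(state_name = out_name, enter_time = out_enter,
                    exit_time = out_exit, machine_id = out_mid)
  out <- out[order(out$enter_time, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trial-outcome counts and sliding performance
#'
#' Counts how often each outcome state occurred and computes the sliding
#' proportion of correct outcomes over the most recent `window` outcomes --
#' the performance measure shown on experiment control charts (a 20-trial
#' window by convention).
#'
#' @param intervals a data frame from [extract_state_intervals()].
#' @param outcome_states character vector of state names that count as trial
#'   outcomes.
#' @param correct_states subset of `outcome_states` that count as correct.
#' @param window integer window length (>= 1) in trials.
#' @return list with `counts` (named integer vector over `outcome_states`),
#'   `series` (numeric vector: element i is the fraction of correct outcomes
#'   among outcomes `max(1, i-window+1) .. i`), and `outcomes` (the ordered
#'   outcome names).
#' @export
performance_summary <- function(intervals, outcome_states, correct_states,
                                window = 20L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  if (!all(correct_states %in% outcome_states))
    stop("correct_states must be a subset of outcome_states")
  counts <- stats::setNames(integer(length(outcome_states)), outcome_states)
  idx <- intervals$state_name %in% outcome_states
  if (!any(idx))
    return(list(counts = counts, series = numeric(), outcomes = character()))
  oc <- intervals$state_name[idx][order(intervals$enter_time[idx],
                                        method = "radix")]
  tab <- table(oc)
  counts[names(tab)] <- as.integer(tab)
  correct <- as.numeric(oc %in% correct_states)
  cs <- cumsum(correct)
  n <- length(correct)
  i <- seq_len(n)
  lo <- pmax(i - window, 0L)
  series <- (cs - c(0, cs)[lo + 1L]) / pmin(i, window)
  list(counts = counts, series = series, outcomes = oc)
}
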