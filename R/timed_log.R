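#' @keywords internal
"_PACKAGE"

# Log dialect constants ------------------------------------------------------

#' Line types of the timed session log
#'
#' Every line of a session log after the header has at least four
#' tab-separated columns: game-thread time, object identifier, line type, and
#' one or more payload columns whose meaning depends on the line type.
#'
#' @format Character vector of the recognized line-type tokens.
#' @export
LOG_LINE_TYPES <- c("EVENT_MARKER", "INPUT", "POSITION", "STATE_ENTER",
                    "STATE_EXIT", "STIMULUS_CREATE", "STIMULUS_DESTROY",
                    "FRAME", "CUSTOM")

# minimum payload columns per line type (so total columns >= 4 always)
.payload_min <- c(EVENT_MARKER = 2L, INPUT = 3L, POSITION = 4L,
                  STATE_ENTER = 1L, STATE_EXIT = 1L, STIMULUS_CREATE = 2L,
                  STIMULUS_DESTROY = 2L, FRAME = 2L, CUSTOM = 1L)

#' Snap a time to the log's 7-decimal resolution
#'
#' Log times are written with seven decimal places (0.1 microsecond
#' resolution); snapping numeric times through the same text representation
#' makes serialization and parsing exact inverses.
#'
#' @param x numeric vector of seconds.
#' @return numeric vector equal to `x` rounded to the printed resolution.
#' @export
snap_log_time <- function(x) as.numeric(sprintf("%.7f", x))

.fmt_time <- function(x) sprintf("%.7f", x)

# Session header -------------------------------------------------------------

#' Create a session header
#'
#' The header block at the top of every session log records session-wide
#' metadata: when the level was started, who was tested by whom, which
#' experiment and level were run, and the verbosity of the (abbreviated) log.
#'
#' @param level_start_time wall-clock timestamp text, e.g. an ISO 8601 string.
#' @param subject,experimenter,experiment,level_name non-empty strings.
#' @param verbosity integer 0--3. 0 keeps only state transitions and event
#'   markers; 3 keeps everything (identical to the continuous log). See
#'   [verbosity_line_types()].
#' @return object of class `session_header`.
#' @export
session_header <- function(level_start_time, subject, experimenter,
                           experiment, level_name, verbosity = 3L) {
  txt <- list(level_start_time = level_start_time, subject = subject,
              experimenter = experimenter, experiment = experiment,
              level_name = level_name)
  for (nm in names(txt)) {
    v <- txt[[nm]]
    if (!is.character(v) || length(v) != 1L || !nzchar(v))
      stop("header field '", nm, "' must be a non-empty string")
    if (grepl("[\t\n]", v))
      stop("header field '", nm, "' must not contain tabs or newlines")
  }
  verbosity <- as.integer(verbosity)
  if (is.na(verbosity) || verbosity < 0L)
    stop("verbosity must be a non-negative integer")
  structure(c(txt, list(verbosity = verbosity)), class = "session_header")
}

#' @export
print.session_header <- function(x, ...) {
  cat("<session_header>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, x[[nm]]))
  invisible(x)
}

.serialize_header <- function(header) {
  c("# timed session log v1",
    vapply(names(header),
           function(nm) sprintf("# %s: %s", nm, header[[nm]]), ""))
}

.parse_header <- function(lines) {
  kv <- lines[grepl("^#\\s*\\S+\\s*:", lines)]
  keys <- sub("^#\\s*([^:]+?)\\s*:.*$", "\\1", kv, perl = TRUE)
  vals <- sub("^#\\s*[^:]+?\\s*:\\s*", "", kv, perl = TRUE)
  h <- as.list(vals)
  names(h) <- keys
  need <- c("level_start_time", "subject", "experimenter", "experiment",
            "level_name")
  if (!all(need %in% keys)) {
    # tolerate partial headers: fill with placeholders so foreign logs load
    for (nm in setdiff(need, keys)) h[[nm]] <- "(unknown)"
  }
  session_header(h$level_start_time, h$subject, h$experimenter,
                 h$experiment, h$level_name,
                 if (is.null(h$verbosity)) 3L else as.integer(h$verbosity))
}

# Record constructors --------------------------------------------------------

.new_records <- function(time, object_id, line_type, payload) {
  df <- data.frame(time = snap_log_time(time),
                   object_id = as.integer(object_id),
                   line_type = as.character(line_type),
                   payload = as.character(payload),
                   stringsAsFactors = FALSE)
  class(df) <- c("log_records", "data.frame")
  df
}

#' Construct log records
#'
#' Each constructor builds one (vectorized) typed line of the session log as
#' a one-row-per-record data frame with columns `time`, `object_id`,
#' `line_type` and `payload` (the payload already formatted as the
#' tab-separated text that will be written). Times are snapped to the
#' 7-decimal log resolution.
#'
#' @param time game-thread time in seconds.
#' @param object_id non-negative integer identity of the logging object.
#' @param payload character vector of pre-formatted payload column text, one
#'   element per record, columns joined by tabs (for [log_record()]).
#' @param line_type one of [LOG_LINE_TYPES] (for [log_record()]).
#' @return a `log_records` data frame.
#' @examples
#' marker_record(1.25, 3L, 2100L, 6.25)
#' input_record(1.25, 7L, 0.5, 0, -1)
#' @export
log_record <- function(time, object_id, line_type, payload) {
  bad <- setdiff(unique(line_type), LOG_LINE_TYPES)
  if (length(bad))
    stop("unknown line type: ", paste(bad, collapse = ", "))
  ncols <- lengths(strsplit(payload, "\t", fixed = TRUE))
  need <- .payload_min[line_type]
  if (any(ncols < need))
    stop("payload of a ", line_type[which(ncols < need)[1]],
         " record needs at least ", need[which(ncols < need)[1]],
         " columns")
  .new_records(time, object_id, line_type, payload)
}

#' @rdname log_record
#' @param marker_id 16-bit event-marker code (0--65535).
#' @param timestamp high-resolution clock timestamp (seconds) taken when the
#'   marker was sent.
#' @export
marker_record <- function(time, object_id, marker_id, timestamp) {
  marker_id <- as.integer(marker_id)
  if (any(marker_id < 0L | marker_id > 65535L))
    stop("marker_id must fit in 16 bits (0..65535)")
  .new_records(time, object_id, "EVENT_MARKER",
               sprintf("%d\t%s", marker_id, .fmt_time(timestamp)))
}

#' @rdname log_record
#' @param forward,sideways,rotation input-device axis values.
#' @export
input_record <- function(time, object_id, forward, sideways, rotation) {
  .new_records(time, object_id, "INPUT",
               sprintf("%s\t%s\t%s", .fmt_time(forward), .fmt_time(sideways),
                       .fmt_time(rotation)))
}

#' @rdname log_record
#' @param x,y,z engine Cartesian coordinates (engine units).
#' @param rotation yaw in degrees.
#' @param azimuth,elevation optional dome angular coordinates (degrees),
#'   logged alongside the Cartesian position for dome-relative objects.
#' @export
position_record <- function(time, object_id, x, y, z, rotation,
                            azimuth = NULL, elevation = NULL) {
  p <- sprintf("%s\t%s\t%s\t%s", .fmt_time(x), .fmt_time(y), .fmt_time(z),
               .fmt_time(rotation))
  if (!is.null(azimuth)) {
    stopifnot(!is.null(elevation))
    p <- sprintf("%s\t%s\t%s", p, .fmt_time(azimuth), .fmt_time(elevation))
  }
  .new_records(time, object_id, "POSITION", p)
}

#' @rdname log_record
#' @param frame_index integer index of the frame being prepared.
#' @param flip_timestamp high-resolution clock time (seconds) at which the
#'   frame currently being *displayed* was flipped by the graphics card.
#' @export
frame_record <- function(time, object_id, frame_index, flip_timestamp) {
  .new_records(time, object_id, "FRAME",
               sprintf("%d\t%s", as.integer(frame_index),
                       .fmt_time(flip_timestamp)))
}

#' @rdname log_record
#' @param state_name name of the state being entered or exited.
#' @param enter logical; `TRUE` for STATE_ENTER, `FALSE` for STATE_EXIT.
#' @export
state_record <- function(time, object_id, state_name, enter = TRUE) {
  if (any(!nzchar(state_name))) stop("state_name must be non-empty")
  .new_records(time, object_id,
               ifelse(enter, "STATE_ENTER", "STATE_EXIT"), state_name)
}

#' @rdname log_record
#' @param settings a [stimulus_settings()] object (serialized into the
#'   payload), or an already-serialized settings string.
#' @param location character location text, conventionally
#'   `"x y z"` or `"az el"`, recorded with the stimulus.
#' @param create logical; `TRUE` for STIMULUS_CREATE, `FALSE` for
#'   STIMULUS_DESTROY.
#' @export
stimulus_record <- function(time, object_id, settings, location,
                            create = TRUE) {
  if (inherits(settings, "stimulus_settings"))
    settings <- format(settings)
  .new_records(time, object_id,
               ifelse(create, "STIMULUS_CREATE", "STIMULUS_DESTROY"),
               sprintf("%s\t%s", settings, location))
}

#' @rdname log_record
#' @param text free text for a CUSTOM line (must not contain newlines).
#' @export
custom_record <- function(time, object_id, text) {
  if (any(grepl("\n", text))) stop("custom text must not contain newlines")
  .new_records(time, object_id, "CUSTOM", text)
}

#' Bind several record sets into one time-ordered log body
#'
#' @param ... `log_records` data frames.
#' @return a single `log_records` data frame sorted by time (stable order
#'   for ties, so records emitted at the same game time keep their relative
#'   order).
#' @export
bind_records <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  df <- df[order(df$time, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("log_records", "data.frame")
  df
}

# Stimulus settings ----------------------------------------------------------

#' Stimulus settings
#'
#' A single parameter struct shared by all stimulus classes: the stimulus
#' type selects the renderer, while `scale`, `height` and `hide` are common
#' to every type and `type_params` carries type-specific parameters (image
#' path, grating spatial frequency, spacing and count for MULTIPLE, ...).
#'
#' @param stimulus_type one of `"IMAGE"`, `"MOVIE"`, `"GRATING"`, `"MESH"`,
#'   `"MULTIPLE"`.
#' @param scale positive size multiplier.
#' @param height distance above the ground plane (engine units).
#' @param hide logical; a hidden stimulus exists but is not rendered.
#' @param type_params named list of type-specific parameters.
#' @return object of class `stimulus_settings`.
#' @export
stimulus_settings <- function(stimulus_type, scale = 1, height = 0,
                              hide = FALSE, type_params = list()) {
  types <- c("IMAGE", "MOVIE", "GRATING", "MESH", "MULTIPLE")
  stimulus_type <- match.arg(stimulus_type, types)
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  legal <- list(IMAGE = c("image_path"),
                MOVIE = c("movie_path", "loop"),
                GRATING = c("spatial_frequency", "orientation", "phase",
                            "contrast"),
                MESH = c("mesh_path"),
                MULTIPLE = c("spacing", "count", "element"))
  bad <- setdiff(names(type_params), legal[[stimulus_type]])
  if (length(bad))
    stop("illegal parameter(s) for ", stimulus_type, " stimulus: ",
         paste(bad, collapse = ", "))
  structure(list(stimulus_type = stimulus_type, scale = scale,
                 height = height, hide = isTRUE(hide),
                 type_params = type_params),
            class = "stimulus_settings")
}

#' @export
format.stimulus_settings <- function(x, ...) {
  tp <- if (length(x$type_params))
    paste(sprintf("%s=%s", names(x$type_params),
                  vapply(x$type_params, format, "")), collapse = ",")
  else ""
  sprintf("type=%s,scale=%s,height=%s,hide=%d%s%s",
          x$stimulus_type, format(x$scale), format(x$height),
          as.integer(x$hide), if (nzchar(tp)) "," else "", tp)
}

#' @export
print.stimulus_settings <- function(x, ...) {
  cat("<stimulus_settings> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Parse a serialized stimulus-settings string
#'
#' Inverse of `format()` on a [stimulus_settings()] object.
#'
#' @param text a `key=value,...` settings string as written to the log.
#' @return a `stimulus_settings` object.
#' @export
parse_stimulus_settings <- function(text) {
  kv <- strsplit(strsplit(text, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  named <- stats::setNames(as.list(vals), keys)
  tp <- named[setdiff(keys, c("type", "scale", "height", "hide"))]
  tp <- lapply(tp, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  stimulus_settings(named$type, as.numeric(named$scale),
                    as.numeric(named$height),
                    as.integer(named$hide) == 1L, tp)
}

# Serialization --------------------------------------------------------------

#' Serialize log records to text lines
#'
#' Produces one tab-separated line per record in the fixed column order
#' time / object id / line type / payload. Serialization and [parse_log()]
#' are exact inverses, and re-serializing a parsed log reproduces it
#' byte-for-byte.
#'
#' @param records a `log_records` data frame (see [log_record()]).
#' @return character vector of lines.
#' @export
serialize_records <- function(records) {
  bad <- setdiff(unique(records$line_type), LOG_LINE_TYPES)
  if (length(bad))
    stop("unknown line type: ", paste(bad, collapse = ", "))
  sprintf("%s\t%d\t%s\t%s", .fmt_time(records$time), records$object_id,
          records$line_type, records$payload)
}

#' Verbosity filtering of the abbreviated log
#'
#' Level 0 keeps only state transitions and event markers; 1 adds stimulus
#' lifecycle lines; 2 adds frame timing and input; 3 keeps everything
#' (identical to the continuous log).
#'
#' @param verbosity integer 0--3.
#' @return character vector of line types retained at that verbosity.
#' @export
verbosity_line_types <- function(verbosity) {
  verbosity <- as.integer(verbosity)
  if (is.na(verbosity) || verbosity < 0L)
    stop("verbosity must be a non-negative integer")
  lv <- list(c("STATE_ENTER", "STATE_EXIT", "EVENT_MARKER"),
             c("STIMULUS_CREATE", "STIMULUS_DESTROY"),
             c("FRAME", "INPUT"),
             c("POSITION", "CUSTOM"))
  unique(unlist(lv[seq_len(min(verbosity, 3L) + 1L)]))
}

#' Write a session log file
#'
#' @param records a `log_records` data frame, time-ordered.
#' @param header a [session_header()].
#' @param path output file path.
#' @param verbosity if smaller than 3, write the abbreviated log containing
#'   only the line types of [verbosity_line_types()]; the header's verbosity
#'   field is set to the written level.
#' @return `path`, invisibly.
#' @export
write_log <- function(records, header, path, verbosity = 3L) {
  header$verbosity <- as.integer(verbosity)
  keep <- records$line_type %in% verbosity_line_types(verbosity)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.serialize_header(header), con)
  writeLines(serialize_records(records[keep, , drop = FALSE]), con)
  invisible(path)
}

# Parsing --------------------------------------------------------------------

#' Parse a session log
#'
#' Streams a continuous or abbreviated session log from disk in fixed-size
#' chunks, so peak memory is bounded by a constant (the chunk buffers) plus
#' the size of the returned subset, never the whole file. Optional filters
#' select line types and/or object ids while streaming.
#'
#' When `convert = TRUE` (the default), the game-thread times of all
#' returned records are replaced by on-screen display times using the FRAME
#' records of the log (see [to_screen_time()]); irrespective of the filters,
#' FRAME and EVENT_MARKER lines are scanned during streaming to build the
#' frame table. Records logged before the first tabulated frame get the
#' approximate fallback conversion and are flagged `adjusted = FALSE`.
#'
#' @param path log file path (or a connection).
#' @param types optional character vector of line types to keep.
#' @param objects optional integer vector of object ids to keep.
#' @param convert logical; convert times to screen times.
#' @param config a [timing_config()] used for the conversion.
#' @param chunk_size number of lines per streamed chunk.
#' @return a `parsed_log` list with elements `header` (a `session_header`),
#'   `records` (a `log_records` data frame, with an extra logical column
#'   `adjusted` when `convert = TRUE`), `converted` (logical), and when
#'   converted also `frame_table`.
#' @export
parse_log <- function(path, types = NULL, objects = NULL, convert = TRUE,
                      config = timing_config(), chunk_size = 32768L) {
  if (!is.null(types)) {
    bad <- setdiff(types, LOG_LINE_TYPES)
    if (length(bad))
      stop("unknown line type in filter: ", paste(bad, collapse = ", "))
  }
  con <- if (inherits(path, "connection")) path else file(path, open = "rt")
  if (!inherits(path, "connection")) on.exit(close(con))

  # header block: leading lines starting with '#'
  header_lines <- character()
  line_no <- 0L
  first_body <- NULL
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l)) break
    line_no <- line_no + 1L
    if (startsWith(l, "#")) header_lines <- c(header_lines, l)
    else { first_body <- l; break }
  }
  if (!length(header_lines))
    stop("not a session log: missing '#' header block")
  header <- .parse_header(header_lines)

  keep_chunks <- list()
  frame_chunks <- list()
  marker_chunks <- list()
  carry <- first_body
  if (!is.null(first_body)) line_no <- line_no - 1L  # carried into chunk 1

  parse_chunk <- function(lines, first_line_no) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nc <- lengths(parts)
    if (any(nc < 4L)) {
      bad <- which(nc < 4L)[1L]
      stop("malformed log line ", first_line_no + bad - 1L,
           ": fewer than 4 columns")
    }
    time <- as.numeric(vapply(parts, `[`, "", 1L))
    if (anyNA(time)) {
      bad <- which(is.na(time))[1L]
      stop("malformed log line ", first_line_no + bad - 1L,
           ": unreadable time field")
    }
    oid <- as.integer(vapply(parts, `[`, "", 2L))
    typ <- vapply(parts, `[`, "", 3L)
    bad <- which(!typ %in% LOG_LINE_TYPES)
    if (length(bad))
      stop("malformed log line ", first_line_no + bad[1L] - 1L,
           ": unknown line type '", typ[bad[1L]], "'")
    payload <- vapply(parts, function(p) paste(p[-(1:3)], collapse = "\t"),
                      "")
    list(time = time, oid = oid, typ = typ, payload = payload)
  }

  repeat {
    lines <- c(carry, readLines(con, n = chunk_size))
    carry <- NULL
    if (!length(lines)) break
    ch <- parse_chunk(lines, line_no + 1L)
    line_no <- line_no + length(lines)

    if (convert) {
      isf <- ch$typ == "FRAME"
      if (any(isf))
        frame_chunks[[length(frame_chunks) + 1L]] <-
          data.frame(time = ch$time[isf], payload = ch$payload[isf])
      ism <- ch$typ == "EVENT_MARKER"
      if (any(ism))
        marker_chunks[[length(marker_chunks) + 1L]] <-
          data.frame(time = ch$time[ism], payload = ch$payload[ism])
    }

    keep <- rep(TRUE, length(ch$time))
    if (!is.null(types)) keep <- keep & ch$typ %in% types
    if (!is.null(objects)) keep <- keep & ch$oid %in% objects
    if (any(keep))
      keep_chunks[[length(keep_chunks) + 1L]] <-
        data.frame(time = ch$time[keep], object_id = ch$oid[keep],
                   line_type = ch$typ[keep], payload = ch$payload[keep],
                   stringsAsFactors = FALSE)
    if (length(lines) < chunk_size) break
  }

  records <- if (length(keep_chunks)) do.call(rbind, keep_chunks)
  else data.frame(time = numeric(), object_id = integer(),
                  line_type = character(), payload = character(),
                  stringsAsFactors = FALSE)
  rownames(records) <- NULL
  class(records) <- c("log_records", "data.frame")

  out <- list(header = header, records = records, converted = FALSE)
  if (convert) {
    frames <- if (length(frame_chunks)) do.call(rbind, frame_chunks)
    else data.frame(time = numeric(), payload = character())
    if (!nrow(frames))
      stop("screen-time conversion impossible: the log contains no FRAME ",
           "records (re-run with convert = FALSE, or use a continuous log)")
    markers <- if (length(marker_chunks)) do.call(rbind, marker_chunks)
    else data.frame(time = numeric(), payload = character())
    ft <- build_frame_table(frames, markers, config)
    st <- to_screen_time(records$time, ft, config)
    records$adjusted <- attr(st, "adjusted")
    records$time <- as.numeric(st)
    out$records <- records
    out$converted <- TRUE
    out$frame_table <- ft
  }
  class(out) <- "parsed_log"
  out
}

#' @export
print.parsed_log <- function(x, ...) {
  cat(sprintf("<parsed_log> %d records (%s times)\n", nrow(x$records),
              if (x$converted) "screen" else "game"))
  print(x$header)
  invisible(x)
}
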