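# Receptive-field mapping stimulus schedules in dome coordinates.
#
# All schedules are pure functions of their parameters and seed (base R's
# Mersenne-Twister, seeded explicitly and restored afterwards), so repeat
# calls are bit-identical; the generator name and seed are recorded in the
# schedule attributes. Frame indices are 0-based, as engine frame counters
# are.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

.schedule <- function(df, params, total_frames, seed = NULL) {
  rownames(df) <- NULL
  attr(df, "params") <- params
  attr(df, "total_frames") <- as.integer(total_frames)
  if (!is.null(seed)) {
    attr(df, "seed") <- as.integer(seed)
    attr(df, "rng") <- "Mersenne-Twister"
  }
  class(df) <- c("stimulus_schedule", "data.frame")
  df
}

#' Moving-bar (sphere-strip) mapping schedule
#'
#' A strip of a sphere of fixed angular width sweeps across the dome along
#' a great circle at constant angular speed, the dome analogue of a
#' moving-bar mapping paradigm. The strip center on each frame is part of
#' the schedule, as the paradigm's logging requires.
#'
#' @param orientation strip orientation in degrees (recorded with each
#'   event; the strip runs perpendicular to the sweep).
#' @param sweep_direction bearing of the sweep in degrees (0 = rightward,
#'   90 = upward), the great-circle direction through (0, 0).
#' @param speed degrees of visual angle per second (> 0).
#' @param strip_width angular width of the strip (degrees, > 0).
#' @param extent total sweep extent in degrees (at most 250, the dome
#'   coverage), centered on (0, 0).
#' @param frame_rate_hz display frame rate.
#' @return a `stimulus_schedule` data frame with one row per frame:
#'   `frame_index` (0-based), `sweep_offset_deg` (signed offset of the strip
#'   center along the sweep axis), `azimuth`, `elevation` (strip center in
#'   dome coordinates), `width_deg`, `orientation`.
#' @export
bar_sweep_schedule <- function(orientation = 0, sweep_direction = 0,
                               speed = 10, strip_width = 5, extent = 120,
                               frame_rate_hz = 60) {
  if (speed <= 0) stop("speed must be > 0")
  if (strip_width <= 0) stop("strip_width must be > 0")
  if (extent > 2 * DOME_MAX_POLAR_DEG)
    stop("extent exceeds the dome coverage (", 2 * DOME_MAX_POLAR_DEG,
         " degrees)")
  n <- as.integer(round(extent / speed * frame_rate_hz))
  if (n < 1L)
    stop("sweep of ", extent, " degrees at ", speed,
         " deg/s spans less than one frame")
  step <- speed / frame_rate_hz
  offs <- -extent / 2 + step * (seq_len(n) - 1L)
  b <- .deg2rad(sweep_direction)
  uo <- .deg2rad(offs)
  # great circle through (0,0) with bearing b: cos(u) forward + sin(u) m
  d <- cbind(cos(uo), sin(uo) * cos(b), sin(uo) * sin(b))
  dome <- cartesian_to_dome(d[, 1], d[, 2], d[, 3])
  .schedule(data.frame(frame_index = seq_len(n) - 1L,
                       sweep_offset_deg = offs,
                       azimuth = dome$azimuth, elevation = dome$elevation,
                       width_deg = strip_width, orientation = orientation),
            params = list(orientation = orientation,
                          sweep_direction = sweep_direction, speed = speed,
                          strip_width = strip_width, extent = extent,
                          frame_rate_hz = frame_rate_hz),
            total_frames = n)
}

#' Flashed Gaussian-blob mapping schedule
#'
#' Small Gaussian blobs flashed at grid locations across the dome, each
#' location exactly once per repetition in a seed-determined random order,
#' with fixed flash duration and inter-flash gap.
#'
#' @param azimuths,elevations degree vectors spanning the grid (all
#'   combinations are used; every grid point must lie on the dome, i.e.
#'   polar angle at most [DOME_MAX_POLAR_DEG]).
#' @param sigma_deg Gaussian blob sigma in degrees (profile truncated at 3
#'   sigma when rendered).
#' @param flash_frames frames each blob stays on.
#' @param gap_frames blank frames between flashes.
#' @param repetitions number of passes over the grid.
#' @param seed integer seed for the flash order.
#' @return a `stimulus_schedule` data frame with one row per visible frame:
#'   `frame_index` (0-based), `flash_index`, `azimuth`, `elevation`,
#'   `sigma_deg`, `value` (1 while on). Attribute `total_frames` counts
#'   on+gap frames.
#' @export
flash_grid_schedule <- function(azimuths, elevations, sigma_deg = 2,
                                flash_frames = 3L, gap_frames = 2L,
                                repetitions = 1L, seed = 1L) {
  if (!length(azimuths) || !length(elevations)) stop("empty grid")
  grid <- expand.grid(azimuth = azimuths, elevation = elevations)
  polar <- dome_polar_angle(grid$azimuth, grid$elevation)
  if (any(polar > DOME_MAX_POLAR_DEG))
    stop("grid point outside dome coverage (polar angle > ",
         DOME_MAX_POLAR_DEG, " degrees)")
  flash_frames <- as.integer(flash_frames)
  gap_frames <- as.integer(gap_frames)
  if (flash_frames < 1L) stop("flash_frames must be >= 1")
  ng <- nrow(grid)
  order_idx <- .with_seed(seed, unlist(lapply(seq_len(repetitions),
                                              function(r) sample.int(ng))))
  nf <- length(order_idx)
  cyc <- flash_frames + gap_frames
  rows <- data.frame(
    frame_index = rep((seq_len(nf) - 1L) * cyc, each = flash_frames) +
      rep(seq_len(flash_frames) - 1L, nf),
    flash_index = rep(seq_len(nf) - 1L, each = flash_frames),
    azimuth = rep(grid$azimuth[order_idx], each = flash_frames),
    elevation = rep(grid$elevation[order_idx], each = flash_frames),
    sigma_deg = sigma_deg, value = 1)
  .schedule(rows,
            params = list(azimuths = azimuths, elevations = elevations,
                          sigma_deg = sigma_deg,
                          flash_frames = flash_frames,
                          gap_frames = gap_frames,
                          repetitions = repetitions),
            total_frames = nf * cyc, seed = seed)
}

#' Sparse-noise mapping schedule
#'
#' Black and white squares of fixed size presented at random lattice
#' locations across the dome, a few per frame: positions are drawn
#' uniformly without replacement within each frame from a spacing lattice
#' anchored at (0, 0), polarities uniformly from the polarity set.
#'
#' @param square_size_deg square side in degrees.
#' @param spacing_deg lattice spacing in degrees.
#' @param squares_per_frame squares shown on each frame (at most the
#'   lattice size).
#' @param n_frames number of frames to generate.
#' @param polarities set of pixel values to draw from (default black -1 and
#'   white +1 on an intermediate gray background).
#' @param seed integer seed.
#' @return a `stimulus_schedule` data frame with `squares_per_frame` rows
#'   per frame: `frame_index` (0-based), `azimuth`, `elevation`,
#'   `size_deg`, `value`.
#' @export
sparse_noise_schedule <- function(square_size_deg = 4, spacing_deg = 5,
                                  squares_per_frame = 4L, n_frames = 100L,
                                  polarities = c(-1, 1), seed = 1L) {
  squares_per_frame <- as.integer(squares_per_frame)
  if (squares_per_frame < 1L) stop("squares_per_frame must be >= 1")
  k <- floor(DOME_MAX_POLAR_DEG / spacing_deg)
  g <- seq(-k, k) * spacing_deg
  lat <- expand.grid(azimuth = g, elevation = g)
  lat <- lat[dome_polar_angle(lat$azimuth, lat$elevation) <=
               DOME_MAX_POLAR_DEG, , drop = FALSE]
  nl <- nrow(lat)
  if (!nl) stop("empty lattice")
  if (squares_per_frame > nl)
    stop("squares_per_frame (", squares_per_frame,
         ") exceeds the lattice size (", nl, ")")
  draws <- .with_seed(seed, {
    pos <- replicate(n_frames, sample.int(nl, squares_per_frame))
    pol <- sample(polarities, n_frames * squares_per_frame, replace = TRUE)
    list(pos = as.integer(pos), pol = pol)
  })
  rows <- data.frame(
    frame_index = rep(seq_len(n_frames) - 1L, each = squares_per_frame),
    azimuth = lat$azimuth[draws$pos],
    elevation = lat$elevation[draws$pos],
    size_deg = square_size_deg,
    value = draws$pol)
  .schedule(rows,
            params = list(square_size_deg = square_size_deg,
                          spacing_deg = spacing_deg,
                          squares_per_frame = squares_per_frame,
                          polarities = polarities),
            total_frames = n_frames, seed = seed)
}

#' Brightness flicker sequence of the timing-verification object
#'
#' The brightness-switching object initializes at 0.5 and, once a state
#' machine is running, cycles through the 4-periodic pattern
#' 1, 0.3, 1, 0 -- one switch per frame, every switch accompanied by an
#' event marker.
#'
#' @param n_frames number of running frames.
#' @return numeric vector of length `n_frames + 1`: the initial 0.5
#'   followed by the pattern value of each running frame.
#' @export
flicker_sequence <- function(n_frames) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 0L) stop("n_frames must be >= 0")
  c(0.5, rep_len(c(1, 0.3, 1, 0), n_frames))
}

#' Serialize a stimulus schedule as log records
#'
#' Writes one CUSTOM record per schedule row (payload: the row's columns as
#' `key=value` pairs), preceded by a STIMULUS_CREATE record carrying the
#' generator parameters, so a schedule can be stored in and recovered from
#' a session log.
#'
#' @param schedule a `stimulus_schedule`.
#' @param object_id logging object id.
#' @param frame_period_s seconds per frame used to lay schedule frames onto
#'   log time.
#' @param t0 log time of frame 0.
#' @return a `log_records` data frame.
#' @export
schedule_records <- function(schedule, object_id = 100L,
                             frame_period_s = 1 / 60, t0 = 0) {
  p <- attr(schedule, "params")
  hdr <- paste(sprintf("%s=%s", names(p),
                       vapply(p, function(v) paste(format(v), collapse = ";"),
                              "")), collapse = ",")
  if (!is.null(attr(schedule, "seed")))
    hdr <- sprintf("%s,rng=%s,seed=%d", hdr, attr(schedule, "rng"),
                   attr(schedule, "seed"))
  cre <- stimulus_record(t0, object_id, sprintf("type=MULTIPLE,scale=1,%s",
                                                hdr), "0 0", create = TRUE)
  df <- as.data.frame(schedule)
  txt <- do.call(paste, c(lapply(names(df), function(nm)
    sprintf("%s=%s", nm, format(df[[nm]], trim = TRUE, digits = 10))),
    list(sep = ",")))
  evt <- custom_record(t0 + df$frame_index * frame_period_s, object_id, txt)
  bind_records(cre, evt)
}
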