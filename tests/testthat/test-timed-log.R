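# The session-log dialect: serialization, parsing, verbosity.

test_that("typed records serialize with the documented column counts", {
  m <- serialize_records(marker_record(1.5, 3L, 42L, 6.25))
  expect_length(strsplit(m, "\t")[[1]], 5L)   # id + accurate timestamp

  i <- serialize_records(input_record(1.5, 7L, 0.2, -0.1, 15))
  expect_length(strsplit(i, "\t")[[1]], 6L)   # forward, sideways, rotation

  expect_length(strsplit(serialize_records(
    position_record(0, 1L, 1, 2, 3, 90)), "\t")[[1]], 7L)
  expect_length(strsplit(serialize_records(
    position_record(0, 1L, 1, 2, 3, 90, 10, -5)), "\t")[[1]], 9L)

  # every line has at least four columns
  r <- random_records(200)
  ncols <- lengths(strsplit(serialize_records(r), "\t", fixed = TRUE))
  expect_true(all(ncols >= 4L))
})

test_that("unknown line types and bad payloads are rejected by name", {
  df <- data.frame(time = 0, object_id = 1L, line_type = "BOGUS",
                   payload = "x")
  expect_error(serialize_records(df), "BOGUS")
  expect_error(log_record(0, 1L, "BOGUS", "x"), "BOGUS")
  expect_error(log_record(0, 1L, "EVENT_MARKER", "onlyone"),
               "at least 2")
  expect_error(marker_record(0, 1L, 70000L, 0), "16 bits")
})

test_that("parse(serialize(.)) is the identity and re-serialization is
           byte-identical", {
  recs <- random_records(500, seed = 42L)
  f <- tempfile(fileext = ".log")
  write_log(recs, make_header(), f)
  pl <- parse_log(f, convert = FALSE)
  expect_equal(nrow(pl$records), nrow(recs))
  expect_identical(pl$records$time, recs$time)
  expect_identical(pl$records$object_id, recs$object_id)
  expect_identical(pl$records$line_type, recs$line_type)
  expect_identical(pl$records$payload, recs$payload)
  expect_identical(serialize_records(pl$records), serialize_records(recs))
  # and the bytes on disk round-trip too
  f2 <- tempfile(fileext = ".log")
  write_log(pl$records, pl$header, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("header fields survive a write/parse cycle and validate", {
  h <- session_header("2026-02-03T10:00:00Z", "m123", "KS", "rfmap",
                      "GrassField", 2L)
  f <- tempfile(fileext = ".log")
  write_log(random_records(10), h, f)
  h2 <- parse_log(f, convert = FALSE)$header
  expect_identical(h2$subject, "m123")
  expect_identical(h2$experiment, "rfmap")
  expect_identical(h2$level_name, "GrassField")
  expect_error(session_header("", "s", "e", "x", "l"), "non-empty")
})

test_that("type and object filters select exactly the matching records", {
  recs <- make_mixed_records()
  f <- tempfile(fileext = ".log")
  write_log(recs, make_header(), f)
  pl <- parse_log(f, types = "EVENT_MARKER", convert = FALSE)
  expect_true(all(pl$records$line_type == "EVENT_MARKER"))
  expect_equal(nrow(pl$records), sum(recs$line_type == "EVENT_MARKER"))
  pl2 <- parse_log(f, objects = 11L, convert = FALSE)
  expect_true(all(pl2$records$object_id == 11L))
  expect_equal(nrow(pl2$records), sum(recs$object_id == 11L))
  pl3 <- parse_log(f, types = c("POSITION"), objects = 10L,
                   convert = FALSE)
  expect_equal(nrow(pl3$records),
               sum(recs$line_type == "POSITION" & recs$object_id == 10L))
  expect_error(parse_log(f, types = "NOPE"), "NOPE")
})

test_that("malformed lines are reported with their line number", {
  f <- tempfile(fileext = ".log")
  lines <- c("# timed session log v1", "# subject: s",
             serialize_records(random_records(5)))
  lines[5] <- "1.0\t2"                     # line 5: too few columns
  writeLines(lines, f)
  expect_error(parse_log(f, convert = FALSE), "line 5")
})

test_that("conversion requires FRAME records", {
  recs <- make_mixed_records()   # no FRAME lines
  f <- tempfile(fileext = ".log")
  write_log(recs, make_header(), f)
  expect_error(parse_log(f, convert = TRUE), "no FRAME")
})

test_that("abbreviated logs: identical at max verbosity, a STATE-complete
           subset at min verbosity", {
  recs <- make_mixed_records()
  h <- make_header()
  f3 <- tempfile(); f0 <- tempfile(); fc <- tempfile()
  write_log(recs, h, fc)
  write_log(recs, h, f3, verbosity = 3L)
  write_log(recs, h, f0, verbosity = 0L)
  expect_identical(readLines(f3), readLines(fc))
  l0 <- parse_log(f0, convert = FALSE)$records
  lc <- parse_log(fc, convert = FALSE)$records
  # subset of the continuous log ...
  expect_true(all(serialize_records(l0) %in% serialize_records(lc)))
  # ... containing every STATE_* line
  states <- lc$line_type %in% c("STATE_ENTER", "STATE_EXIT")
  expect_true(all(serialize_records(lc[states, ]) %in%
                    serialize_records(l0)))
})

test_that("stimulus settings validate and round-trip through their text
           form", {
  s <- stimulus_settings("GRATING", scale = 2, height = 1.5,
                         type_params = list(spatial_frequency = 0.1))
  s2 <- parse_stimulus_settings(format(s))
  expect_equal(s2$stimulus_type, "GRATING")
  expect_equal(s2$scale, 2)
  expect_equal(s2$type_params$spatial_frequency, 0.1)
  expect_error(stimulus_settings("GRATING", scale = 0), "scale")
  expect_error(stimulus_settings("IMAGE",
                                 type_params = list(spatial_frequency = 1)),
               "illegal")
})
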