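# Shared helpers: small sessions and record sets built in code.

# a tiny mixed record set with two moving objects and a state machine
make_mixed_records <- function() {
  f1 <- seq(0, 0.49, by = 0.01)
  bind_records(
    state_record(0.0, 1L, "Trial", TRUE),
    position_record(f1, 10L, f1 * 100, 0, 0, 0),
    position_record(f1 + 0.001, 11L, 5, 5, 0, 90),
    input_record(f1, 10L, 1, 0, 0),
    marker_record(c(0.1, 0.3), 3L, c(2100L, 2000L), c(0.1, 0.3)),
    state_record(0.5, 1L, "Trial", FALSE))
}

make_header <- function(verbosity = 3L) {
  session_header("2026-01-01T00:00:00Z", "subj", "expr", "test", "Level",
                 verbosity)
}

# write a session's continuous log to a tempfile, return the path
write_temp_session <- function(session) {
  f <- tempfile(fileext = ".log")
  write_log(session$records, session$header, f)
  f
}

# random valid records of every type, for round-trip properties
random_records <- function(n, seed = 1L) {
  set.seed(seed)
  t <- sort(round(runif(n, 0, 1000), 7))
  oid <- sample.int(50L, n, replace = TRUE)
  type_of <- sample(1:7, n, replace = TRUE)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    recs[[i]] <- switch(
      type_of[i],
      marker_record(t[i], oid[i], sample.int(65535L, 1) - 1L,
                    t[i] + runif(1)),
      input_record(t[i], oid[i], runif(1, -1, 1), runif(1, -1, 1),
                   runif(1, -180, 180)),
      position_record(t[i], oid[i], runif(1, -1e4, 1e4),
                      runif(1, -1e4, 1e4), runif(1, 0, 100),
                      runif(1, 0, 360)),
      state_record(t[i], oid[i], sample(c("A", "B", "Trial", "Correct"), 1),
                   runif(1) < 0.5),
      frame_record(t[i], oid[i], i, t[i] + 0.05),
      custom_record(t[i], oid[i], paste0("note ", i)),
      stimulus_record(t[i], oid[i],
                      stimulus_settings("GRATING", scale = runif(1, 0.1, 5),
                                        type_params = list(
                                          spatial_frequency = runif(1))),
                      "10 0 0", create = runif(1) < 0.5))
  }
  do.call(bind_records, recs)
}
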