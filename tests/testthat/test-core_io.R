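test_that("spike trains enforce ordering and span invariants", {
  expect_error(spike_train(c(1, 1, 2), c(0, 10)), "strictly increasing")
  expect_error(spike_train(c(3, 2), c(0, 10)), "strictly increasing")
  expect_error(spike_train(c(0.5, 11), c(0, 10)), "outside")
  expect_error(spike_train(1, c(5, 5)), "t1 > t0")
  st <- spike_train(numeric(0), c(0, 10))
  expect_length(st$times, 0)
})

test_that("tracking traces require regular sampling", {
  t <- seq(0, 1, by = 0.04)
  xy <- cbind(seq_along(t), seq_along(t))
  expect_s3_class(tracking_trace(t, xy, xy), "tracking_trace")
  t_bad <- t; t_bad[5] <- t_bad[5] + 0.02
  expect_error(tracking_trace(t_bad, xy, xy), "constant")
  expect_error(tracking_trace(t[1], xy[1, , drop = FALSE],
                              xy[1, , drop = FALSE]), "two samples")
})

test_that("light pulse trains validate power and ordering", {
  expect_error(light_pulse_train(c(0, 0), 1, 1, 1), "strictly increasing")
  expect_error(light_pulse_train(c(0, 1), 1, 0, 1), "positive")
  lp <- light_pulse_train(0:4, 1, 0.5, 1)
  expect_equal(length(lp), 5L)
})

test_that("session records check component overlap and arena containment", {
  st <- spike_train(c(1, 2), c(0, 100))
  t <- seq(0, 10, by = 0.04)
  xy <- cbind(rep(35, length(t)), rep(25, length(t)))
  tr <- tracking_trace(t, xy, xy)
  s <- session_record("s1", st, tracking = tr, arena = maze_geometry())
  expect_s3_class(s, "session_record")
  # pulses outside the span are rejected
  lp <- light_pulse_train(c(50, 150), 1, 1, 1)
  expect_error(session_record("s1", st, pulses = lp), "outside")
  # out-of-arena tracking is rejected
  xy_bad <- xy; xy_bad[3, 1] <- 90
  tr_bad <- tracking_trace(t, xy_bad, xy)
  expect_error(session_record("s1", st, tracking = tr_bad, arena =
                                maze_geometry()), "bounding box")
})

test_that("sessions round-trip through disk within tolerance", {
  dir <- withr::local_tempdir()
  st <- spike_train(c(0.123456789123, 4.5, 9.999), c(0, 60.5))
  t <- seq(0, 10, by = 0.04)
  xy1 <- cbind(30 + sin(t), 20 + cos(t))
  xy2 <- cbind(31 + sin(t), 21 + cos(t))
  xy1[7, ] <- NA  # dropped video frame
  tr <- tracking_trace(t, xy1, xy2)
  lp <- light_pulse_train(c(20, 20.5, 21), c(1, 5, 1), c(0.5, 1, 6),
                          c(1, 1, 1))
  s <- session_record("roundtrip", st, tracking = tr, pulses = lp,
                      arena = maze_geometry(),
                      annotations = list(histology_calb1 = "positive",
                                         waveform_ms = 0.9))
  man <- write_session(s, dir)
  s2 <- read_session(man)
  expect_equal(s2$spikes$times, s$spikes$times, tolerance = 1e-9)
  expect_equal(s2$spikes$recording_span, s$spikes$recording_span)
  expect_equal(s2$tracking$led1_xy, s$tracking$led1_xy, tolerance = 1e-6)
  expect_true(all(is.na(s2$tracking$led1_xy[7, ])))
  expect_equal(s2$pulses$power_mW, s$pulses$power_mW, tolerance = 1e-6)
  expect_identical(s2$annotations$histology_calb1, "positive")
  expect_equal(s2$annotations$waveform_ms, 0.9)
  expect_equal(s2$arena$midline$perimeter, s$arena$midline$perimeter,
               tolerance = 1e-9)
})

test_that("a spikes-only session reads back with optional parts absent", {
  dir <- withr::local_tempdir()
  s <- session_record("minimal", spike_train(c(1, 2, 3), c(0, 10)))
  man <- write_session(s, dir)
  s2 <- read_session(man)
  expect_null(s2$tracking)
  expect_null(s2$pulses)
  expect_equal(s2$spikes$times, c(1, 2, 3))
})

test_that("malformed tables and violated invariants raise named errors", {
  dir <- withr::local_tempdir()
  s <- session_record("bad", spike_train(c(1, 2, 3), c(0, 10)))
  man <- write_session(s, dir)
  # corrupt the spike table: non-monotonic times
  spk_path <- file.path(dirname(man), "spikes.csv")
  writeLines(c("time_s", "3.0", "1.0"), spk_path)
  expect_error(read_session(man), "strictly increasing")
  writeLines(c("wrong_col", "1.0"), spk_path)
  expect_error(read_session(man), "time_s")
  expect_error(read_session(file.path(dir, "nope.yaml")), "not found")
})

test_that("a generated cohort survives a write/read round trip", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(opto_bench_cohort_spec(4, 3, 3, rng_seed = 11))
  expect_length(co$sessions, 10)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_length(back$sessions, 10)
  expect_equal(sort(names(back$sessions)),
               sort(co$ground_truth$session_id))
  expect_equal(back$ground_truth$responder_class,
               co$ground_truth$responder_class)
  for (s in co$sessions) {
    s2 <- back$sessions[[s$session_id]]
    expect_equal(s2$spikes$times, s$spikes$times, tolerance = 1e-9)
    expect_equal(s2$pulses$onsets, s$pulses$onsets, tolerance = 1e-9)
  }
})

test_that("config files mirror analysis_config fields exactly", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- analysis_config(pixel_size_cm = 2, rng_seed = 42L)
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$pixel_size_cm, 2)
  expect_equal(cfg2$rng_seed, 42L)
  expect_equal(cfg2$direct_latency_threshold_ms, 4)
  writeLines("not_a_field: 1", path)
  expect_error(read_config(path), "unknown field")
})
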