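test_that("simulated trajectories stay on the path and are deterministic", {
  mz <- maze_geometry()
  tr <- simulate_trajectory(mz, duration_s = 600, tracking_rate_hz = 25,
                            seed = 4)
  expect_equal(nrow(tr$led1_xy), 15000L)
  pos <- midpoint_position(tr)
  # containment: distance from the midline (dense polyline) within half the
  # path width, plus a small clipping margin
  th <- seq(0, 2 * pi, length.out = 720)
  ring <- ellipse_point(mz$midline, th)
  sub <- pos[seq(1, nrow(pos), by = 7), ]
  dmin <- vapply(seq_len(nrow(sub)), function(i) {
    sqrt(min((ring[, 1] - sub$x[i])^2 + (ring[, 2] - sub$y[i])^2))
  }, numeric(1))
  expect_lt(max(dmin), mz$path_width / 2 + 0.2)
  # determinism
  tr2 <- simulate_trajectory(mz, duration_s = 600, tracking_rate_hz = 25,
                             seed = 4)
  expect_identical(tr$led1_xy, tr2$led1_xy)
  tr3 <- simulate_trajectory(mz, duration_s = 600, tracking_rate_hz = 25,
                             seed = 5)
  expect_false(identical(tr$led1_xy, tr3$led1_xy))
})

test_that("recomputed movement fraction matches the configured run fraction", {
  mz <- maze_geometry()
  fr <- vapply(1:4, function(s) {
    tr <- simulate_trajectory(mz, duration_s = 600, seed = s)
    pos <- midpoint_position(tr)
    mean(compute_speed(pos, tr$dt) > 1)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.7), 0.05)
})

test_that("trajectory parameter errors are raised", {
  expect_error(simulate_trajectory(maze_geometry(), 60, tracking_rate_hz = 0),
               "tracking_rate_hz")
  expect_error(simulate_trajectory(maze_geometry(), -1), "duration")
})

test_that("place-cell spike counts follow the Poisson expectation", {
  mz <- maze_geometry()
  tr <- simulate_trajectory(mz, duration_s = 600, seed = 10)
  s <- attr(tr, "linear_s")
  # zero rate -> empty train
  spec0 <- place_field_spec(baseline_rate_hz = 0, field_gain_hz = 0,
                            field_center_cm = 10)
  st0 <- simulate_place_cell(spec0, tr, s, mz$midline$perimeter, seed = 1)
  expect_length(st0$times, 0)
  # pure baseline 2 Hz, no bursts: count within 3 SD of 1200
  spec2 <- place_field_spec(baseline_rate_hz = 2, field_gain_hz = 0,
                            field_center_cm = 10, burst_probability = 0)
  st2 <- simulate_place_cell(spec2, tr, s, mz$midline$perimeter, seed = 2)
  expect_gt(length(st2$times), 1200 - 3 * sqrt(1200))
  expect_lt(length(st2$times), 1200 + 3 * sqrt(1200))
  expect_true(all(diff(st2$times) > 0))
  expect_true(all(diff(st2$times) >= 0.002 - 1e-12))
})

test_that("burst promotion yields the expected burst index", {
  mz <- maze_geometry()
  tr <- simulate_trajectory(mz, duration_s = 600, seed = 20)
  s <- attr(tr, "linear_s")
  spec <- place_field_spec(baseline_rate_hz = 2, field_gain_hz = 0,
                           field_center_cm = 10, burst_probability = 0.3,
                           burst_size = 2)
  bi <- vapply(1:10, function(sd) {
    st <- simulate_place_cell(spec, tr, s, mz$midline$perimeter, seed = sd)
    burst_index(st)
  }, numeric(1))
  expect_lt(abs(mean(bi) - 0.3 / 1.3), 0.05)
})

test_that("opto responses reproduce the requested latency structure", {
  span <- c(0, 120)
  quiet <- spike_train(numeric(0), span)
  pulses <- light_pulse_train(seq(10, 59.5, by = 1), 1, 0.5, 1)
  # none class leaves the baseline untouched
  base <- simulate_homogeneous_train(2, span, seed = 3)
  expect_identical(
    simulate_opto_response(opto_response_spec("none"), base, pulses, 1)$times,
    base$times)
  expect_error(opto_response_spec("none", facilitation_increment = 0.1),
               "facilitate")
  # direct, probability 1: one evoked spike per pulse at 2.5 +/- 0.3 ms
  spec <- opto_response_spec("direct", latency_mean_ms = 2.5,
                             latency_sd_ms = 0.3, response_probability = 1)
  out <- simulate_opto_response(spec, quiet, pulses, seed = 7)
  expect_length(out$times, 50)
  lat <- (out$times - pulses$onsets) * 1000
  expect_true(all(lat > 0 & lat < 20))
  expect_lt(abs(mean(lat) - 2.5), 0.15)
})

test_that("facilitation raises late-train response rates", {
  span <- c(0, 10)
  quiet <- spike_train(numeric(0), span)
  train <- light_pulse_train(1 + (0:9) * 0.04, 5, 1, 25)
  spec <- opto_response_spec("indirect", response_probability = 0.2,
                             facilitation_increment = 0.1)
  early <- 0; late <- 0
  for (sd in 1:100) {
    out <- simulate_opto_response(spec, quiet, train, seed = sd)
    hits <- vapply(train$onsets, function(on)
      any(out$times > on & out$times <= on + 0.02), logical(1))
    early <- early + sum(hits[1:5])
    late <- late + sum(hits[6:10])
  }
  expect_gt(late, early)
})

test_that("cohorts are reproducible and carry matching ground truth", {
  spec <- opto_bench_cohort_spec(3, 2, 2, rng_seed = 5)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_length(co1$sessions, 7)
  expect_equal(table(co1$ground_truth$responder_class),
               table(c(rep("direct", 3), rep("indirect", 2),
                       rep("none", 2))))
  for (k in seq_along(co1$sessions))
    expect_identical(co1$sessions[[k]]$spikes$times,
                     co2$sessions[[k]]$spikes$times)
  # byte-identical after writing
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(co1, d1); write_cohort(co2, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  # empty cohort is allowed
  expect_length(generate_cohort(opto_bench_cohort_spec(0, 0, 0))$sessions, 0)
})

test_that("default pyramidal specs keep mean rates below 10 Hz", {
  mz <- maze_geometry()
  tr <- simulate_trajectory(mz, duration_s = 600, seed = 42)
  s <- attr(tr, "linear_s")
  spec <- place_field_spec()
  rates <- vapply(1:100, function(sd) {
    spec$field_center_cm <- (sd * 13) %% mz$midline$perimeter
    mean_firing_rate(simulate_place_cell(spec, tr, s, mz$midline$perimeter,
                                         seed = sd))
  }, numeric(1))
  expect_gte(mean(rates < 10), 0.99)
})
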