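test_that("pulse filtering applies interval, power, and train rules", {
  lp <- light_pulse_train(c(0.0, 0.1, 0.4), 1, 1, 1)
  kept <- filter_pulses(lp, min_interpulse_ms = 200)
  expect_equal(kept$onsets, c(0.0, 0.4))
  # 1 Hz low-power train survives intact
  lp2 <- light_pulse_train(0:9, 1, 1, 1)
  expect_equal(length(filter_pulses(lp2)), 10L)
  # >5 mW pulses are removed
  lp3 <- light_pulse_train(c(0, 1, 2), 1, c(1, 6, 5), 1)
  expect_equal(filter_pulses(lp3)$power_mW, c(1, 5))
  # 40 Hz trains are excluded outright
  lp4 <- light_pulse_train(c(0, 1), 1, 1, c(40, 1))
  expect_equal(filter_pulses(lp4)$train_hz, 1)
  expect_length(filter_pulses(light_pulse_train(numeric(0), numeric(0),
                                                numeric(0), numeric(0))), 0)
})

test_that("pulse filtering is monotone in its thresholds", {
  for (sd in 1:20) {
    set.seed(sd)
    n <- 30
    lp <- light_pulse_train(cumsum(runif(n, 0.05, 1)),
                            sample(c(1, 5), n, TRUE),
                            runif(n, 0.1, 8),
                            sample(c(1, 3, 40), n, TRUE))
    a <- filter_pulses(lp, min_interpulse_ms = 200, max_power_mW = 3)
    b <- filter_pulses(lp, min_interpulse_ms = 200, max_power_mW = 6)
    expect_true(all(a$onsets %in% b$onsets))
    c_ <- filter_pulses(lp, min_interpulse_ms = 100, max_power_mW = 3)
    expect_true(all(a$onsets %in% c_$onsets))
  }
})

test_that("PSTH bins spikes correctly and conserves counts", {
  span <- c(0, 100)
  # a spike 2.15 ms after a pulse lands in bin [2.1, 2.2)
  st <- spike_train(1.00215, span)
  lp <- light_pulse_train(1.0, 1, 1, 1)
  ps <- compute_psth(st, lp, window_ms = 20, bin_ms = 0.1)
  expect_length(ps$counts, 200L)
  expect_equal(sum(ps$counts), 1L)
  expect_equal(which(ps$counts == 1), 22L)  # bin starting at 2.1 ms
  expect_equal(ps$bin_edges_ms[22], 2.1)
  # no spikes -> all-zero counts
  ps0 <- compute_psth(spike_train(numeric(0), span), lp, 20, 0.1)
  expect_true(all(ps0$counts == 0))
  expect_error(compute_psth(st, light_pulse_train(numeric(0), numeric(0),
                                                  numeric(0), numeric(0))),
               "empty")
  expect_error(compute_psth(st, lp, window_ms = 20, bin_ms = 0.3), "divide")
  # conservation across many pulses against per-pulse window counts
  set.seed(9)
  st2 <- spike_train(sort(runif(400, 0, 100)), span)
  lp2 <- light_pulse_train(seq(5, 90, by = 0.5), 1, 1, 2)
  ps2 <- compute_psth(st2, lp2, 20, 0.1)
  manual <- sum(vapply(lp2$onsets, function(on)
    sum(st2$times >= on & st2$times < on + 0.02), numeric(1)))
  expect_equal(sum(ps2$counts), manual)
})

test_that("first-spike latencies follow the first-spike-in-window rule", {
  span <- c(0, 100)
  lp <- light_pulse_train(c(10, 20, 30), 1, 1, 1)
  # first of two in-window spikes wins
  st <- spike_train(c(10.002, 10.003, 20.025, 30.020), span)
  tl <- first_spike_latencies(st, lp, window_ms = 20)
  expect_equal(tl$latency_ms[1], 2.0)
  expect_true(is.na(tl$latency_ms[2]))   # 25 ms is outside the window
  expect_equal(tl$latency_ms[3], 20)     # edge spike is included
  # a spike exactly at onset does not count
  tl2 <- first_spike_latencies(spike_train(10, span), lp, 20)
  expect_true(all(is.na(tl2$latency_ms)))
  # empty train -> all failures
  tl3 <- first_spike_latencies(spike_train(numeric(0), span), lp, 20)
  expect_true(all(is.na(tl3$latency_ms)))
  # overlapping windows indicate unfiltered pulses
  lp_bad <- light_pulse_train(c(1, 1.01), 1, 1, 1)
  expect_error(first_spike_latencies(st, lp_bad, 20), "overlap")
})

test_that("latency summaries average over non-failure trials only", {
  mk <- function(lat) structure(list(latency_ms = lat, window_ms = 20),
                                class = "trial_latencies")
  s1 <- summarize_latency(mk(c(2, 2, 2)))
  expect_equal(s1$mean_ms, 2)
  expect_equal(s1$sd_ms, 0)
  expect_equal(s1$response_probability, 1)
  s2 <- summarize_latency(mk(c(2, 4, NA)))
  expect_equal(s2$mean_ms, 3)
  expect_equal(s2$response_probability, 2 / 3)
  s3 <- summarize_latency(mk(rep(NA_real_, 50)))
  expect_true(is.na(s3$mean_ms))
  expect_equal(s3$response_probability, 0)
})

test_that("evoked spikes per pulse averages window counts", {
  span <- c(0, 100)
  lp <- light_pulse_train(c(10, 20, 30, 40), 1, 1, 1)
  st <- spike_train(c(10.005, 20.004, 20.008, 30.019), span)
  expect_equal(evoked_spikes_per_pulse(st, lp, 20), 1.0)  # (1+2+1+0)/4
  lp10 <- light_pulse_train(seq(10, 19, 1), 1, 1, 1)
  st10 <- spike_train(seq(10, 19, 1) + 0.005, span)
  expect_equal(evoked_spikes_per_pulse(st10, lp10, 20), 1.0)
})

test_that("opto classification combines latency and reliability", {
  cfg <- analysis_config()
  mk <- function(mean, p) structure(
    list(mean_ms = mean, sd_ms = 0.3, response_probability = p,
         n_trials = 50, n_responses = round(50 * p)),
    class = "latency_summary")
  expect_equal(classify_optotag(mk(2.1, 0.95), cfg)$label, "direct")
  expect_equal(classify_optotag(mk(7.4, 0.6), cfg)$label, "indirect")
  expect_equal(classify_optotag(mk(NA, 0), cfg)$label, "nonresponsive")
  expect_equal(classify_optotag(mk(2.0, 0.3), cfg)$label, "nonresponsive")
  expect_equal(classify_optotag(mk(4.0, 0.9), cfg)$label, "indirect")
})
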