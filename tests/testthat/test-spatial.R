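test_that("midpoint positions drop incomplete frames", {
  t <- seq(0, 1, by = 0.04)
  n <- length(t)
  l1 <- cbind(rep(0, n), rep(0, n))
  l2 <- cbind(rep(2, n), rep(2, n))
  l1[3, ] <- NA
  tr <- tracking_trace(t, l1, l2)
  pos <- midpoint_position(tr)
  expect_equal(nrow(pos), n - 1)
  expect_true(all(pos$x == 1 & pos$y == 1))
  # coincident LEDs give the shared point
  tr2 <- tracking_trace(t, l2, l2)
  expect_true(all(midpoint_position(tr2)$x == 2))
  # all-missing tracking errors
  l1[] <- NA
  expect_error(midpoint_position(tracking_trace(t, l1, l2)), "no frame")
})

test_that("speed computation matches hand arithmetic", {
  t <- seq(0, 2, by = 0.04)
  pos <- data.frame(t = t, x = 2 * seq_along(t), y = 0)  # 2 cm per frame
  v <- compute_speed(pos, 0.04, smooth_s = 0.04)  # single-sample window
  expect_equal(v, rep(50, length(t)))
  # stationary -> zeros
  pos0 <- data.frame(t = t, x = 1, y = 1)
  expect_true(all(compute_speed(pos0, 0.04) == 0))
  expect_error(compute_speed(pos0[1, ], 0.04), "two samples")
})

test_that("occupancy maps conserve tracking time and use the right grid", {
  mz <- maze_geometry()
  cfg <- analysis_config()
  # single frame: total mass equals one frame interval
  one <- data.frame(t = 0, x = 35, y = 25)
  occ1 <- compute_occupancy(one, 0.04, mz, cfg)
  expect_equal(dim(occ1$z), c(28L, 20L))
  expect_equal(sum(occ1$z), 0.04, tolerance = 1e-12)
  # mask: pixels below 20 ms occupancy are invalid
  expect_true(all(occ1$z[occ1$valid] >= 0.02))
  tr <- simulate_trajectory(mz, 120, seed = 2)
  pos <- midpoint_position(tr)
  occ <- compute_occupancy(pos, tr$dt, mz, cfg)
  expect_equal(sum(occ$z), nrow(pos) * tr$dt, tolerance = 1e-9)
  expect_error(compute_occupancy(pos[0, ], tr$dt, mz, cfg), "no position")
})

test_that("rate maps integrate to the observed mean rate", {
  mz <- maze_geometry()
  cfg <- analysis_config()
  tr <- simulate_trajectory(mz, 600, seed = 6)
  pos <- midpoint_position(tr)
  occ <- compute_occupancy(pos, tr$dt, mz, cfg)
  # homogeneous 2 Hz spikes at random tracked positions
  set.seed(1)
  idx <- sample(nrow(pos), round(2 * 600))
  rmap <- compute_ratemap(cbind(pos$x[idx], pos$y[idx]), occ)
  v <- rmap$valid
  wmean <- sum(occ$z[v] * rmap$r[v]) / sum(occ$z[v])
  expect_equal(wmean, 2, tolerance = 0.1)
  # zero spikes give a zero map
  rmap0 <- compute_ratemap(cbind(numeric(0), numeric(0)), occ)
  expect_true(all(rmap0$r[rmap0$valid] == 0))
})

test_that("spatial information and sparsity reproduce closed forms", {
  occ4 <- occupancy_map(matrix(1, 2, 2))
  runi <- rate_map(matrix(2, 2, 2), occ4$valid)
  expect_equal(spatial_information(runi, occ4), 0, tolerance = 1e-12)
  expect_equal(sparsity(runi, occ4), 1, tolerance = 1e-12)
  rone <- rate_map(matrix(c(4, 0, 0, 0), 2, 2), occ4$valid)
  expect_equal(spatial_information(rone, occ4), 2, tolerance = 1e-12)
  expect_equal(sparsity(rone, occ4), 0.25, tolerance = 1e-12)
  # direct evaluation of the printed formulas on a 3-pixel map
  occ3 <- occupancy_map(matrix(c(2, 1, 1), 1, 3))
  r3 <- rate_map(matrix(c(2, 1, 1), 1, 3), occ3$valid)
  expect_equal(spatial_information(r3, occ3),
               0.5 * (4 / 3) * log2(4 / 3) + 0.5 * (2 / 3) * log2(2 / 3),
               tolerance = 1e-12)
  expect_equal(sparsity(r3, occ3), 2.25 / 2.5, tolerance = 1e-12)
  # zero spikes are undefined
  r0 <- rate_map(matrix(0, 2, 2), occ4$valid)
  expect_error(spatial_information(r0, occ4), "zero spikes")
  expect_error(sparsity(r0, occ4), "zero spikes")
})

test_that("metrics match a naive double-loop oracle on random maps", {
  set.seed(33)
  for (k in 1:25) {
    mp <- random_map_pair()
    if (sum(mp$lam) == 0) next
    expect_equal(spatial_information(mp$rmap, mp$occ),
                 naive_information(mp$p, mp$lam), tolerance = 1e-12)
    expect_equal(sparsity(mp$rmap, mp$occ),
                 naive_sparsity(mp$p, mp$lam), tolerance = 1e-12)
  }
})

test_that("masked pixels never contribute to the peak rate", {
  occ <- occupancy_map(matrix(c(1, 1, 0.001, 1), 2, 2))
  r <- matrix(c(2, 3, 99, 1), 2, 2)
  r[!occ$valid] <- 99
  rm_ <- rate_map(r, occ$valid)
  expect_equal(peak_firing_rate(rm_), 3)
  rm_none <- rate_map(matrix(1, 2, 2), matrix(FALSE, 2, 2))
  expect_error(peak_firing_rate(rm_none), "no valid")
})

test_that("synthetic field peaks fall in the expected envelope", {
  mz <- maze_geometry()
  cfg <- analysis_config()
  peaks <- vapply(1:10, function(sd) {
    tr <- simulate_trajectory(mz, 400, seed = sd)
    spec <- place_field_spec(baseline_rate_hz = 1, field_gain_hz = 8,
                             field_width_cm = 10, burst_probability = 0,
                             field_center_cm = 40)
    st <- simulate_place_cell(spec, tr, attr(tr, "linear_s"),
                              mz$midline$perimeter, seed = sd + 100)
    pos <- midpoint_position(tr)
    sp <- compute_speed(pos, tr$dt)
    mov <- sp > cfg$speed_threshold_cm_s
    occ <- compute_occupancy(pos[mov, ], tr$dt, mz, cfg)
    idx <- findInterval(st$times, pos$t, all.inside = TRUE)
    keep <- mov[idx]
    rmap <- compute_ratemap(cbind(pos$x[idx[keep]], pos$y[idx[keep]]), occ)
    peak_firing_rate(rmap)
  }, numeric(1))
  expect_true(all(peaks > 5 & peaks < 13))
})
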