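# deterministic session: constant-speed circular running with spikes fired
# at a fixed track phase every lap (identical first and second halves when
# `laps` is even)
make_circle_session <- function(duration_s = 240, laps = 4, radius = 20,
                                center = c(35, 25), rate_hz = 25,
                                spike_phase = 0.5) {
  omega <- laps * 2 * pi / duration_s
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  theta <- omega * t
  pos <- cbind(center[1] + radius * cos(theta),
               center[2] + radius * sin(theta))
  tr <- tracking_trace(t, pos, pos)
  spike_t <- (spike_phase + 2 * pi * (0:(laps - 1))) / omega
  spike_t <- spike_t[spike_t < duration_s]
  st <- spike_train(spike_t, recording_span = c(0, duration_s))
  session_record("circle", st, tracking = tr, arena = maze_geometry())
}

# naive double-loop evaluation of the printed spatial-information formula
naive_information <- function(p, lam) {
  lambda <- 0
  for (i in seq_along(p)) lambda <- lambda + p[i] * lam[i]
  acc <- 0
  for (i in seq_along(p)) {
    if (lam[i] > 0) {
      ratio <- lam[i] / lambda
      acc <- acc + p[i] * ratio * log2(ratio)
    }
  }
  acc
}

# naive double-loop evaluation of the sparsity formula
naive_sparsity <- function(p, lam) {
  num <- 0; den <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * lam[i]
    den <- den + p[i] * lam[i]^2
  }
  num^2 / den
}

# random occupancy/rate map pair on an nx-by-ny grid, all pixels valid
random_map_pair <- function(nx = 6, ny = 5, zero_rate_frac = 0.2) {
  z <- matrix(stats::runif(nx * ny, 0.05, 2), nx, ny)
  r <- matrix(stats::rexp(nx * ny, 1 / 2), nx, ny)
  r[stats::runif(nx * ny) < zero_rate_frac] <- 0
  occ <- occupancy_map(z, mask_s = 0)
  list(occ = occ, rmap = rate_map(r, occ$valid),
       p = as.vector(z) / sum(z), lam = as.vector(r))
}

# brute-force exact two-sided rank-sum p-value by full enumeration
enumerate_rank_sum_p <- function(a, b) {
  n <- length(a); N <- n + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)])
  sets <- utils::combn(N, n)
  W <- apply(sets, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(W <= w_obs + 1e-9), mean(W >= w_obs - 1e-9)))
}
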