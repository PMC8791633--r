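#' Simulate O-maze exploration
#'
#' Generates a two-LED head-tracking trace of a mouse running on the maze's
#' elliptical midline. Behavior alternates run bouts and pauses (a two-state
#' semi-Markov process with exponential dwell times); forward speed during a
#' run follows an Ornstein-Uhlenbeck process around a per-bout target, with
#' occasional direction reversals after pauses. Lateral displacement from
#' the midline is an Ornstein-Uhlenbeck excursion driven per centimeter
#' traveled (so a paused mouse does not drift), bounded inside the path.
#' The two LEDs are placed half a head-vector ahead of and behind the
#' position, along the heading.
#'
#' @param maze A [maze_geometry()].
#' @param duration_s Trace duration (s).
#' @param tracking_rate_hz Camera frame rate (Hz).
#' @param speed_params Named list overriding any of: `run_fraction` (target
#'   fraction of time in run bouts, 0.7), `run_mean_s` (mean run-bout
#'   length, 8 s), `run_speed_range` (c(5, 30) cm/s), `run_speed_log_mean`
#'   (log 12), `run_speed_log_sd` (0.35), `speed_tau_s` (OU time constant,
#'   2 s), `speed_sd` (OU SD, 2 cm/s), `pause_speed_cm_s` (0.2),
#'   `reversal_prob` (0.15), `lateral_sd_cm` (1.3), `lateral_tau_cm` (60),
#'   `head_distance_cm` (3).
#' @param seed Integer seed; the trace is a deterministic function of
#'   (arguments, seed).
#' @return A [tracking_trace()]; the ground-truth arc-length coordinate of
#'   each frame (cm along the midline) is attached as attribute
#'   `"linear_s"`, and the configured run fraction as `"run_fraction"`.
#' @examples
#' mz <- maze_geometry()
#' tr <- simulate_trajectory(mz, duration_s = 60, seed = 1)
#' range(tr$led1_xy[, 1])
#' @export
simulate_trajectory <- function(maze, duration_s, tracking_rate_hz = 25,
                                speed_params = list(), seed = 1) {
  stopifnot(inherits(maze, "maze_geometry"))
  if (duration_s <= 0)
    stop("simulate_trajectory: duration_s must be positive", call. = FALSE)
  if (tracking_rate_hz <= 0)
    stop("simulate_trajectory: tracking_rate_hz must be positive",
         call. = FALSE)
  p <- utils::modifyList(list(
    run_fraction = 0.7, run_mean_s = 8,
    run_speed_range = c(5, 30), run_speed_log_mean = log(12),
    run_speed_log_sd = 0.35, speed_tau_s = 2, speed_sd = 2,
    pause_speed_cm_s = 0.15, reversal_prob = 0.15,
    lateral_sd_cm = 1.3, lateral_tau_cm = 60, head_distance_cm = 3),
    speed_params)
  set.seed(seed)

  dt <- 1 / tracking_rate_hz
  n <- max(2L, round(duration_s * tracking_rate_hz))
  t <- (seq_len(n) - 1L) * dt
  pause_mean_s <- p$run_mean_s * (1 - p$run_fraction) / p$run_fraction

  # state sequence: TRUE = run
  state <- logical(n)
  i <- 1L
  running <- stats::runif(1) < p$run_fraction
  direction <- sample(c(-1, 1), 1)
  dir_vec <- numeric(n)
  while (i <= n) {
    # gamma bout durations (shape 4): realistic spread without the excess
    # of near-zero bouts an exponential would produce
    mean_dwell <- if (running) p$run_mean_s else pause_mean_s
    dwell <- stats::rgamma(1, shape = 4, rate = 4 / mean_dwell)
    j <- min(n, i + max(1L, round(dwell / dt)) - 1L)
    state[i:j] <- running
    if (!running && stats::runif(1) < p$reversal_prob)
      direction <- -direction
    dir_vec[i:j] <- direction
    running <- !running
    i <- j + 1L
  }

  # forward speed: OU around per-bout targets during runs, crawl in pauses
  bout_id <- cumsum(c(TRUE, diff(state) != 0))
  bout_first <- !duplicated(bout_id)
  n_bouts <- sum(bout_first)
  bout_target <- ifelse(
    state[bout_first],
    pmin(pmax(stats::rlnorm(n_bouts, p$run_speed_log_mean,
                            p$run_speed_log_sd),
              p$run_speed_range[1]), p$run_speed_range[2]),
    p$pause_speed_cm_s)
  target <- bout_target[bout_id]
  alpha <- dt / p$speed_tau_s
  noise <- stats::rnorm(n, 0, p$speed_sd * sqrt(2 * alpha))
  # OU recursion v[k] = (1 - alpha) v[k-1] + alpha target[k] + noise[k]
  drive <- alpha * target + noise
  drive[1] <- target[1]
  v <- as.numeric(stats::filter(drive, 1 - alpha, method = "recursive"))
  # pauses stay clearly below the 1 cm/s movement threshold even after the
  # lateral jitter and finite-difference speed estimation add their share
  v <- ifelse(state, pmax(v, 2), pmin(pmax(v, 0), 2 * p$pause_speed_cm_s))

  # arc-length position on the midline
  s <- cumsum(c(0, (dir_vec * v)[-n] * dt))
  mid <- maze$midline
  theta <- ellipse_theta_at(mid, s)

  # lateral offset, driven per cm traveled so pauses freeze it
  ds_abs <- abs(c(0, diff(s)))
  lat <- numeric(n)
  lmax <- maze$path_width / 2 - 0.5
  lat_noise <- stats::rnorm(n)
  for (k in 2:n) {
    lat[k] <- lat[k - 1] - lat[k - 1] / p$lateral_tau_cm * ds_abs[k] +
      p$lateral_sd_cm * sqrt(2 * ds_abs[k] / p$lateral_tau_cm) * lat_noise[k]
    lat[k] <- min(max(lat[k], -lmax), lmax)
  }

  base <- ellipse_point(mid, theta)
  co <- cos(mid$rotation); si <- sin(mid$rotation)
  # outward unit normal of the ellipse at parameter theta (world frame)
  nxr <- mid$b * cos(theta); nyr <- mid$a * sin(theta)
  nrm <- sqrt(nxr^2 + nyr^2)
  nx <- (co * nxr - si * nyr) / nrm
  ny <- (si * nxr + co * nyr) / nrm
  pos <- cbind(base[, 1] + lat * nx, base[, 2] + lat * ny)

  # heading along the direction of travel; LEDs fore and aft of the midpoint
  txr <- -mid$a * sin(theta); tyr <- mid$b * cos(theta)
  tn <- sqrt(txr^2 + tyr^2)
  hx <- dir_vec * (co * txr - si * tyr) / tn
  hy <- dir_vec * (si * txr + co * tyr) / tn
  half <- p$head_distance_cm / 2
  led1 <- cbind(pos[, 1] + half * hx, pos[, 2] + half * hy)
  led2 <- cbind(pos[, 1] - half * hx, pos[, 2] - half * hy)

  bb <- maze$bounding_box
  clip <- function(m) cbind(pmin(pmax(m[, 1], 0), bb[1]),
                            pmin(pmax(m[, 2], 0), bb[2]))
  tr <- tracking_trace(t, clip(led1), clip(led2))
  attr(tr, "linear_s") <- s %% mid$perimeter
  attr(tr, "linear_s_unwrapped") <- s
  attr(tr, "run_fraction") <- p$run_fraction
  tr
}
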