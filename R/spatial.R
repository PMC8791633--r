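#' Animal position from two-LED tracking
#'
#' The position is the midpoint of the two head-mounted LEDs. Frames where
#' either LED is missing are dropped, never interpolated.
#'
#' @param tracking A [tracking_trace()].
#' @return A data frame with columns `t`, `x`, `y` (one row per retained
#'   frame).
#' @export
midpoint_position <- function(tracking) {
  stopifnot(inherits(tracking, "tracking_trace"))
  ok <- stats::complete.cases(tracking$led1_xy) &
    stats::complete.cases(tracking$led2_xy)
  if (!any(ok))
    stop("midpoint_position: no frame has both LEDs", call. = FALSE)
  mid <- (tracking$led1_xy[ok, , drop = FALSE] +
            tracking$led2_xy[ok, , drop = FALSE]) / 2
  data.frame(t = tracking$t[ok], x = mid[, 1], y = mid[, 2])
}

# running mean with a centered window that shrinks at the edges
boxcar_smooth <- function(x, width) {
  n <- length(x)
  width <- max(1L, as.integer(width))
  if (width == 1L || n < 2) return(x)
  half <- (width - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Instantaneous running speed
#'
#' Central-difference speed from a position series (one-sided at the
#' edges), boxcar-smoothed over the configured window. Gaps from dropped
#' frames use the actual elapsed time.
#'
#' @param positions Data frame from [midpoint_position()].
#' @param dt Nominal frame interval (s), used to size the smoothing window.
#' @param smooth_s Boxcar window length (s); a window of one sample returns
#'   the raw finite differences.
#' @return Speed (cm/s), one value per position sample.
#' @export
compute_speed <- function(positions, dt, smooth_s = 0.25) {
  n <- nrow(positions)
  if (n < 2)
    stop("compute_speed: need at least two samples", call. = FALSE)
  x <- positions$x; y <- positions$y; t <- positions$t
  i_next <- c(2:n, n)
  i_prev <- c(1, 1:(n - 1))
  disp <- sqrt((x[i_next] - x[i_prev])^2 + (y[i_next] - y[i_prev])^2)
  v <- disp / (t[i_next] - t[i_prev])
  boxcar_smooth(v, round(smooth_s / dt))
}

# Gaussian-kernel mass spreading onto the pixel grid.
# Each sample's kernel is evaluated at the true sample-to-pixel-center
# distance, truncated at 4 sigma, and normalized over the in-grid pixels it
# reaches, so total deposited mass equals sum(weights) exactly.
kernel_accumulate <- function(x, y, weights, nx, ny, pixel_cm, sigma_px) {
  if (length(x) == 0) return(matrix(0, nrow = nx, ncol = ny))
  .kernel_accumulate_cpp(as.numeric(x), as.numeric(y), as.numeric(weights),
                         as.integer(nx), as.integer(ny), pixel_cm, sigma_px)
}

#' Construct an occupancy map directly
#'
#' Low-level constructor wrapping an existing occupancy matrix; used by
#' [compute_occupancy()] and useful for building small maps in closed-form
#' tests.
#'
#' @param z Matrix of seconds per pixel.
#' @param pixel_cm Pixel edge length (cm).
#' @param sigma_px Smoothing SD used (pixels).
#' @param mask_s Occupancy threshold (s) defining the valid mask.
#' @return An object of class `occupancy_map`: `z`, `valid` (logical
#'   matrix), `pixel_cm`, `sigma_px`, `total_time`.
#' @export
occupancy_map <- function(z, pixel_cm = 2.5, sigma_px = 1, mask_s = 0.020) {
  z <- as.matrix(z)
  if (any(z < 0)) stop("occupancy_map: z must be non-negative", call. = FALSE)
  structure(list(z = z, valid = z >= mask_s, pixel_cm = pixel_cm,
                 sigma_px = sigma_px, total_time = sum(z)),
            class = "occupancy_map")
}

#' Kernel-smoothed occupancy map
#'
#' Discretizes the arena into square pixels and deposits each tracking
#' frame's duration `dt` as a Gaussian kernel (SD `kernel_sigma_px` pixels,
#' truncated at 4 SD, normalized to unit mass over the grid) centered on
#' the animal's position, so the map totals the included tracking time
#' exactly. Pixels occupied for less than `occupancy_mask_s` are flagged
#' invalid.
#'
#' @param positions Data frame (`t`, `x`, `y`) of included (speed-filtered)
#'   samples.
#' @param dt Frame interval (s).
#' @param arena A [maze_geometry()] (defines the grid extent).
#' @param config An [analysis_config()].
#' @return An `occupancy_map` (see [occupancy_map()]).
#' @export
compute_occupancy <- function(positions, dt, arena,
                              config = analysis_config()) {
  if (is.null(positions) || nrow(positions) == 0)
    stop("compute_occupancy: no position samples", call. = FALSE)
  stopifnot(inherits(arena, "maze_geometry"),
            inherits(config, "analysis_config"))
  px <- config$pixel_size_cm
  nx <- as.integer(ceiling(arena$bounding_box[1] / px - 1e-9))
  ny <- as.integer(ceiling(arena$bounding_box[2] / px - 1e-9))
  z <- kernel_accumulate(positions$x, positions$y,
                         rep(dt, nrow(positions)), nx, ny, px,
                         config$kernel_sigma_px)
  occupancy_map(z, pixel_cm = px, sigma_px = config$kernel_sigma_px,
                mask_s = config$occupancy_mask_s)
}

#' Construct a rate map directly
#'
#' Low-level constructor for a firing-rate map on an existing grid.
#'
#' @param r Matrix of rates (Hz); masked pixels should be `NA`.
#' @param valid Logical matrix of valid pixels.
#' @return An object of class `rate_map`: `r`, `valid`, `n_spikes`.
#' @param n_spikes Number of spikes that built the map.
#' @export
rate_map <- function(r, valid, n_spikes = NA_integer_) {
  r <- as.matrix(r)
  stopifnot(identical(dim(r), dim(valid)))
  structure(list(r = r, valid = valid, n_spikes = n_spikes),
            class = "rate_map")
}

#' Kernel-smoothed firing-rate map
#'
#' Smooths the spike positions with the identical Gaussian kernel used for
#' the occupancy map and divides by occupancy: `r(x) = spike mass / z(x)`.
#' Rates are defined only on the occupancy map's valid pixels.
#'
#' @param spike_positions Two-column matrix (or data frame with `x`, `y`)
#'   of the animal's position at each included spike.
#' @param occupancy An `occupancy_map` from [compute_occupancy()].
#' @return A `rate_map` (see [rate_map()]).
#' @export
compute_ratemap <- function(spike_positions, occupancy) {
  stopifnot(inherits(occupancy, "occupancy_map"))
  if (is.null(occupancy$valid))
    stop("compute_ratemap: occupancy map lacks a valid mask", call. = FALSE)
  sp <- as.matrix(as.data.frame(spike_positions))
  nx <- nrow(occupancy$z); ny <- ncol(occupancy$z)
  num <- kernel_accumulate(sp[, 1], sp[, 2], rep(1, nrow(sp)), nx, ny,
                           occupancy$pixel_cm, occupancy$sigma_px)
  r <- matrix(NA_real_, nx, ny)
  v <- occupancy$valid
  r[v] <- num[v] / occupancy$z[v]
  rate_map(r, v, n_spikes = nrow(sp))
}

# shared extraction of (p_n, lambda_n, lambda) over valid pixels
map_distributions <- function(ratemap, occupancy) {
  stopifnot(inherits(ratemap, "rate_map"), inherits(occupancy, "occupancy_map"))
  v <- ratemap$valid & occupancy$valid & is.finite(ratemap$r)
  z <- occupancy$z[v]
  if (sum(z) <= 0)
    stop("map_distributions: no valid occupancy", call. = FALSE)
  p <- z / sum(z)
  lam_n <- ratemap$r[v]
  list(p = p, lam_n = lam_n, lambda = sum(p * lam_n))
}

#' Skaggs spatial information
#'
#' Information per spike,
#' `I = sum_n p_n (lambda_n / lambda) log2(lambda_n / lambda)`, where `p_n`
#' is the occupancy probability of pixel `n` (renormalized over valid
#' pixels), `lambda_n` the pixel firing rate, and `lambda = sum p_n
#' lambda_n` the overall mean rate. Pixels with zero rate contribute zero
#' (`0 log 0 := 0`).
#'
#' @param ratemap A `rate_map`.
#' @param occupancy The matching `occupancy_map`.
#' @return Information in bits per spike.
#' @examples
#' occ <- occupancy_map(matrix(1, 2, 2))
#' rm1 <- rate_map(matrix(c(4, 0, 0, 0), 2, 2), occ$valid)
#' spatial_information(rm1, occ)  # 2 bits/spike
#' @export
spatial_information <- function(ratemap, occupancy) {
  md <- map_distributions(ratemap, occupancy)
  if (md$lambda <= 0)
    stop("spatial_information: undefined with zero spikes", call. = FALSE)
  ratio <- md$lam_n / md$lambda
  pos <- ratio > 0
  sum(md$p[pos] * ratio[pos] * log2(ratio[pos]))
}

#' Sparsity index
#'
#' Occupancy-weighted compactness of firing,
#' `sparsity = (sum_n p_n lambda_n)^2 / sum_n p_n lambda_n^2`, lying in
#' (0, 1]: low values indicate a compact place field, values near 1 a
#' diffuse, spatially uniform pattern.
#'
#' @inheritParams spatial_information
#' @return Sparsity index in (0, 1].
#' @export
sparsity <- function(ratemap, occupancy) {
  md <- map_distributions(ratemap, occupancy)
  denom <- sum(md$p * md$lam_n^2)
  if (denom <= 0)
    stop("sparsity: undefined with zero spikes", call. = FALSE)
  md$lambda^2 / denom
}

#' Peak firing rate
#'
#' Maximum rate over the valid pixels of a (2D, non-linearized) rate map.
#'
#' @param ratemap A `rate_map`.
#' @return Peak rate (Hz).
#' @export
peak_firing_rate <- function(ratemap) {
  stopifnot(inherits(ratemap, "rate_map"))
  vals <- ratemap$r[ratemap$valid & is.finite(ratemap$r)]
  if (length(vals) == 0)
    stop("peak_firing_rate: no valid pixels", call. = FALSE)
  max(vals)
}

# nearest-in-time position lookup for spike times
spike_positions_lookup <- function(spike_times, positions) {
  if (nrow(positions) == 0 || length(spike_times) == 0)
    return(cbind(x = numeric(0), y = numeric(0)))
  idx <- findInterval(spike_times, positions$t, all.inside = TRUE)
  # choose the nearer of the bracketing samples
  use_next <- (positions$t[pmin(idx + 1L, nrow(positions))] - spike_times) <
    (spike_times - positions$t[idx])
  idx <- ifelse(use_next, pmin(idx + 1L, nrow(positions)), idx)
  cbind(x = positions$x[idx], y = positions$y[idx])
}
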