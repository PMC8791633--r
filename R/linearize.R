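# unwrap a circular phase series (radians) into a continuous one
unwrap_phase <- function(phase) {
  if (length(phase) < 2) return(phase)
  d <- diff(phase)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phase[1], d))
}

#' Fit an ellipse to a trajectory
#'
#' Direct least-squares conic fit constrained to ellipses (eigensystem of
#' the scatter matrices under the `4AC - B^2 = 1` constraint), with the
#' perimeter evaluated by quadrature. Data are centered before fitting for
#' numerical conditioning.
#'
#' @param positions Two-column matrix or data frame (`x`, `y`) of at least
#'   6 non-collinear points (cm).
#' @return An [ellipse_model()].
#' @examples
#' th <- seq(0, 2 * pi, length.out = 40)
#' fit_ellipse(cbind(25 * cos(th), 25 * sin(th)))$a
#' @export
fit_ellipse <- function(positions) {
  xy <- as.matrix(as.data.frame(positions)[, 1:2])
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 6)
    stop("fit_ellipse: need at least 6 points", call. = FALSE)
  mx <- mean(xy[, 1]); my <- mean(xy[, 2])
  x <- xy[, 1] - mx; y <- xy[, 2] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T <- tryCatch(-solve(S3, t(S2)),
                error = function(e)
                  stop("fit_ellipse: degenerate input", call. = FALSE))
  M <- S1 + S2 %*% T
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 1e-12)
  if (length(ok) == 0)
    stop("fit_ellipse: no elliptical solution (degenerate or collinear ",
         "input)", call. = FALSE)
  v <- V[, ok[1]]
  coef <- c(v, T %*% v)  # A B C D E F in the centered frame
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- 4 * A * C - B^2
  x0 <- (B * E - 2 * C * D) / den
  y0 <- (B * D - 2 * A * E) / den
  # constant term after translating to the center
  Fc <- F + A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0
  m <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  lam <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (any(lam * (-Fc) <= 0))
    stop("fit_ellipse: no elliptical solution", call. = FALSE)
  axes <- sqrt(-Fc / lam)
  a <- max(axes); b <- min(axes)
  # the major axis lies along the eigenvector of the smaller eigenvalue
  evec <- eigen(m, symmetric = TRUE)$vectors
  major <- evec[, which.min(lam)]
  rotation <- atan2(major[2], major[1])
  ellipse_model(c(x0 + mx, y0 + my), a, b, rotation)
}

#' Project positions onto an ellipse and linearize
#'
#' Each point is projected radially (along the ray from the ellipse center)
#' onto the ellipse, giving the ellipse parameter of its projection, and
#' then mapped to arc length along the ellipse. The result is a circular
#' coordinate in `[0, perimeter)` cm. Radial projection is an approximation
#' to the true closest-point projection; for points near the track of a
#' low-eccentricity ellipse the discrepancy is far below the map bin width.
#'
#' @param positions Two-column matrix or data frame of positions (cm).
#' @param ellipse An [ellipse_model()].
#' @return Numeric vector of arc-length coordinates (cm).
#' @export
linearize <- function(positions, ellipse) {
  stopifnot(inherits(ellipse, "ellipse_model"))
  xy <- as.matrix(as.data.frame(positions)[, 1:2])
  xr <- xy[, 1] - ellipse$center[1]
  yr <- xy[, 2] - ellipse$center[2]
  co <- cos(-ellipse$rotation); si <- sin(-ellipse$rotation)
  xe <- co * xr - si * yr
  ye <- si * xr + co * yr
  if (any(xe^2 + ye^2 < 1e-12))
    stop("linearize: point at the ellipse center has no projection",
         call. = FALSE)
  theta <- atan2(ellipse$a * ye, ellipse$b * xe)
  ellipse_arc_at(ellipse, theta)
}

#' Count laps from a linearized trajectory
#'
#' Converts the circular arc-length coordinate to a phase, unwraps it, and
#' counts how many full perimeters the unwrapped excursion (maximum minus
#' minimum) spans. Back-and-forth running below a full circuit contributes
#' no lap; alternating full circuits in either direction all count.
#'
#' @param linear_s Arc-length coordinates (cm) of consecutive samples.
#' @param perimeter Track perimeter (cm).
#' @return Integer lap count.
#' @export
count_laps <- function(linear_s, perimeter) {
  if (length(linear_s) < 2) return(0L)
  phase <- unwrap_phase(linear_s * 2 * pi / perimeter)
  as.integer(floor((max(phase) - min(phase)) / (2 * pi) + 1e-9))
}

# circular Gaussian smoothing of a histogram (sigma in bins, truncated 4 sd)
circular_smooth <- function(h, sigma_bins) {
  n <- length(h)
  if (sigma_bins <= 0 || n < 2) return(h)
  R <- min(n %/% 2, as.integer(ceiling(4 * sigma_bins)))
  off <- -R:R
  k <- exp(-off^2 / (2 * sigma_bins^2))
  k <- k / sum(k)
  out <- numeric(n)
  for (j in seq_along(off))
    out <- out + k[j] * h[((seq_len(n) - 1 + off[j]) %% n) + 1]
  out
}

#' Linearized firing-rate map
#'
#' Bins the circular arc-length coordinate, accumulates occupancy time and
#' spike counts per bin, smooths both histograms with a circular Gaussian
#' kernel (SD one bin), and divides. Bins with zero smoothed occupancy are
#' masked. Optionally max-normalized for display stacks.
#'
#' @param spike_s Arc-length coordinate (cm) at each included spike.
#' @param occupancy_s Arc-length coordinate (cm) of each included tracking
#'   frame.
#' @param perimeter Track perimeter (cm).
#' @param dt Frame interval (s).
#' @param bin_cm Nominal bin width (cm); the actual width divides the
#'   perimeter evenly.
#' @param sigma_bins Smoothing SD in bins.
#' @param normalize If `TRUE`, scale the rate profile to a maximum of 1.
#' @return An object of class `linearized_map`: `bin_start_cm`, `rate_hz`,
#'   `occupancy_s`, `valid`, `perimeter`, `normalized`.
#' @export
linearized_ratemap <- function(spike_s, occupancy_s, perimeter, dt,
                               bin_cm = 2.5, sigma_bins = 1,
                               normalize = FALSE) {
  stopifnot(perimeter > 0, dt > 0)
  n_bins <- max(2L, as.integer(round(perimeter / bin_cm)))
  width <- perimeter / n_bins
  to_bin <- function(s) floor((s %% perimeter) / width) %% n_bins + 1
  occ <- tabulate(to_bin(occupancy_s), nbins = n_bins) * dt
  spk <- tabulate(to_bin(spike_s), nbins = n_bins)
  occ_s <- circular_smooth(occ, sigma_bins)
  spk_s <- circular_smooth(spk, sigma_bins)
  valid <- occ_s > 0
  rate <- rep(NA_real_, n_bins)
  rate[valid] <- spk_s[valid] / occ_s[valid]
  if (normalize) {
    mx <- max(rate[valid], 0)
    if (mx > 0) rate <- rate / mx
  }
  structure(list(bin_start_cm = (seq_len(n_bins) - 1) * width,
                 rate_hz = rate, occupancy_s = occ_s, valid = valid,
                 perimeter = perimeter, normalized = normalize),
            class = "linearized_map")
}

#' Split-half spatial stability
#'
#' Splits a session at the temporal midpoint of its tracking, computes a
#' linearized rate map independently for each half (sharing the ellipse
#' fitted to the whole trajectory), and returns the Pearson correlation of
#' the two maps over bins valid in both halves.
#'
#' @param session A [session_record()] with tracking (internally, a
#'   precomputed spatial frame is also accepted).
#' @param config An [analysis_config()].
#' @return Pearson correlation coefficient.
#' @export
split_half_stability <- function(session, config = analysis_config()) {
  fr <- if (inherits(session, "session_spatial_frame")) session
        else session_spatial_frame(session, config)
  t_mid <- (fr$positions$t[1] + fr$positions$t[nrow(fr$positions)]) / 2
  half_map <- function(first) {
    fsel <- if (first) fr$positions$t <= t_mid else fr$positions$t > t_mid
    ssel <- if (first) fr$spike_t <= t_mid else fr$spike_t > t_mid
    inc_f <- fsel & fr$moving
    inc_s <- ssel & fr$spike_included
    if (sum(inc_f) < 2)
      stop("split_half_stability: a half has no occupancy", call. = FALSE)
    linearized_ratemap(fr$spike_s[inc_s], fr$linear_s[inc_f], fr$perimeter,
                       fr$dt, bin_cm = config$linear_bin_cm)
  }
  m1 <- half_map(TRUE)
  m2 <- half_map(FALSE)
  both <- m1$valid & m2$valid
  if (sum(both) < 2)
    stop("split_half_stability: fewer than 2 jointly valid bins",
         call. = FALSE)
  stats::cor(m1$rate_hz[both], m2$rate_hz[both])
}
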