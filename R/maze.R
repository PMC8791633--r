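#' Elliptical track model
#'
#' Parametric ellipse used both as the midline of the O-shaped maze and as
#' the linearization target fitted to a recorded trajectory. The perimeter
#' and the arc-length table are computed by trapezoidal quadrature on a fine
#' parameter grid (4096 nodes, relative error well below 1e-6).
#'
#' @param center Numeric length-2, ellipse center (cm).
#' @param a,b Semi-axes (cm); internally ordered so `a >= b`.
#' @param rotation Rotation of the major axis, radians counterclockwise.
#' @return An object of class `ellipse_model` with fields `center`, `a`,
#'   `b`, `rotation`, `perimeter`, and an internal arc-length lookup.
#' @examples
#' e <- ellipse_model(c(0, 0), 25, 25)
#' e$perimeter / (2 * pi)  # radius of a circle
#' @export
ellipse_model <- function(center, a, b, rotation = 0) {
  stopifnot(length(center) == 2, is.finite(center), is.finite(a),
            is.finite(b), is.finite(rotation))
  if (a <= 0 || b <= 0)
    stop("ellipse_model: semi-axes must be positive", call. = FALSE)
  if (b > a) {  # keep a as the major axis; rotate frame by 90 degrees
    tmp <- a; a <- b; b <- tmp
    rotation <- rotation + pi / 2
  }
  rotation <- atan2(sin(rotation), cos(rotation))
  n <- 4096L
  theta <- seq(0, 2 * pi, length.out = n + 1L)
  speed <- sqrt(a^2 * sin(theta)^2 + b^2 * cos(theta)^2)
  seg <- (speed[-1] + speed[-(n + 1L)]) / 2 * diff(theta)
  arc <- c(0, cumsum(seg))
  structure(list(center = as.numeric(center), a = a, b = b,
                 rotation = rotation, perimeter = arc[n + 1L],
                 .theta = theta, .arc = arc),
            class = "ellipse_model")
}

#' @export
print.ellipse_model <- function(x, ...) {
  cat(sprintf(
    "Ellipse: center (%.2f, %.2f) cm, semi-axes %.2f x %.2f cm, rotation %.3f rad, perimeter %.2f cm\n",
    x$center[1], x$center[2], x$a, x$b, x$rotation, x$perimeter))
  invisible(x)
}

# arc length s(theta) and its inverse, both vectorized, via the lookup table
ellipse_arc_at <- function(ellipse, theta) {
  th <- theta %% (2 * pi)
  stats::approx(ellipse$.theta, ellipse$.arc, xout = th, rule = 2)$y
}

ellipse_theta_at <- function(ellipse, s) {
  sm <- s %% ellipse$perimeter
  stats::approx(ellipse$.arc, ellipse$.theta, xout = sm, rule = 2)$y
}

# point on the ellipse (world frame) at parameter theta
ellipse_point <- function(ellipse, theta) {
  xr <- ellipse$a * cos(theta)
  yr <- ellipse$b * sin(theta)
  co <- cos(ellipse$rotation); si <- sin(ellipse$rotation)
  cbind(ellipse$center[1] + co * xr - si * yr,
        ellipse$center[2] + si * xr + co * yr)
}

#' O-shaped maze geometry
#'
#' The arena is a rectangle with an elliptical running path: the maze midline
#' is an ellipse centered in the bounding box, and the walkable annulus
#' extends half the path width to either side of it. Defaults describe the
#' 70 x 50 cm maze with a 9 cm wide path.
#'
#' @param bounding_box Numeric length-2: arena width and height (cm); the
#'   coordinate origin is the arena's lower-left corner.
#' @param path_width Walkable path width (cm).
#' @param center Midline ellipse center; default is the box center.
#' @param semi_axes Midline semi-axes; default is the largest midline that
#'   keeps the outer edge of the path inside the box.
#' @return An object of class `maze_geometry` with fields `bounding_box`,
#'   `path_width`, and `midline` (an [ellipse_model()]).
#' @examples
#' mz <- maze_geometry()
#' mz$midline$perimeter
#' @export
maze_geometry <- function(bounding_box = c(70, 50), path_width = 9,
                          center = bounding_box / 2,
                          semi_axes = bounding_box / 2 - path_width / 2) {
  stopifnot(length(bounding_box) == 2, bounding_box > 0, path_width > 0,
            length(semi_axes) == 2, semi_axes > 0)
  if (any(abs(center) + semi_axes + path_width / 2 >
          bounding_box + 1e-9) ||
      any(center - semi_axes - path_width / 2 < -1e-9))
    stop("maze_geometry: midline plus half path width must fit inside ",
         "the bounding box", call. = FALSE)
  structure(list(bounding_box = as.numeric(bounding_box),
                 path_width = path_width,
                 midline = ellipse_model(center, semi_axes[1], semi_axes[2])),
            class = "maze_geometry")
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat(sprintf("O-maze: %.0f x %.0f cm box, %.1f cm path, midline perimeter %.1f cm\n",
              x$bounding_box[1], x$bounding_box[2], x$path_width,
              x$midline$perimeter))
  invisible(x)
}
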