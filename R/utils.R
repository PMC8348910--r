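# Small numeric helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
lin_interp <- function(x, y, xout) {
  # piecewise-linear interpolation with linear extrapolation from end slopes
  stopifnot(length(x) == length(y), length(x) >= 2)
  o <- order(x)
  x <- x[o]; y <- y[o]
  out <- stats::approx(x, y, xout = xout, rule = 2)$y
  n <- length(x)
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed report tables in this
#' package use the conventional half-up rule instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# elementary rotation matrices, angles in radians, right-hand rule
rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# intrinsic x-y-z Euler composition (degrees)
euler_xyz <- function(rx, ry, rz) rot_x(deg2rad(rx)) %*% rot_y(deg2rad(ry)) %*% rot_z(deg2rad(rz))

# inverse of the skew operator, symmetrizing numerical noise
unskew <- function(m) {
  a <- (m - t(m)) / 2
  c(a[3, 2], a[1, 3], a[2, 1])
}

vec_norm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# standard gravity used to convert between SI and kilogram-force units
GRAVITY <- 9.81
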