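# Small geometric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero-length vector")
  v / n
}

#' Angle between two directions
#'
#' Returns the angle in degrees, in \[0, 180\], between two 3-D direction
#' vectors.
#'
#' @param u,v Numeric length-3 vectors (need not be unit length).
#' @return Angle in degrees.
#' @export
angle_between <- function(u, v) {
  u <- unit_vector(u)
  v <- unit_vector(v)
  d <- max(-1, min(1, sum(u * v)))
  acos(d) * 180 / pi
}

# Rotation matrix for a right-handed rotation by `angle_deg` degrees about
# the (not necessarily unit) axis.
rotation_about_axis <- function(axis, angle_deg) {
  a <- unit_vector(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation matrix from a rotation vector (axis * angle in radians).
rodrigues <- function(omega) {
  th <- sqrt(sum(omega^2))
  if (th < 1e-300) return(diag(3))
  rotation_about_axis(omega / th, th * 180 / pi)
}

# Cubic smoothstep on [0, 1].
smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# Uniformly random rotation matrix (axis uniform on the sphere, angle
# uniform up to max_deg). Uses the current RNG stream.
random_rotation <- function(max_deg) {
  ax <- rnorm(3)
  while (sum(ax^2) < 1e-12) ax <- rnorm(3)
  rotation_about_axis(ax, runif(1, -max_deg, max_deg))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
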