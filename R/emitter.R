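#' A single fluorescent dipole emitter
#'
#' Describes one molecule for the forward simulator: its sample-plane
#' position, the orientation of its emission dipole moment, the half angle
#' of the cone it wobbles in during a frame, and the expected number of
#' signal photons arriving at the camera's analyzer plane (before the
#' micropolarizers, which absorb on average half of them).
#'
#' Coordinates follow the image convention: x to the right (columns), y
#' down (rows), both in nanometres with pixel `(0, 0)` centred at
#' `(0, 0)` nm. `phi` is the in-plane azimuth of the dipole measured from
#' the +x axis; `theta` is the polar angle from the optical axis, so
#' `theta = 90` degrees lies in the sample plane.
#'
#' @param x_nm,y_nm Sample-plane position, nanometres.
#' @param z_nm Height of the emitter above the coverglass interface,
#'   nanometres (non-negative).
#' @param phi_deg In-plane azimuth in `(-90, 90]` degrees.
#' @param theta_deg Polar angle in `[0, 90]` degrees.
#' @param cone_deg Half angle of the wobble cone, degrees; `0` is perfectly
#'   immobilized, `90` is an isotropic (freely rotating) emitter.
#' @param photons Expected signal photons incident on the analyzer plane.
#'
#' @return An object of class `dipole_emitter`.
#' @export
dipole_emitter <- function(x_nm = 0, y_nm = 0, z_nm = 0,
                           phi_deg = 0, theta_deg = 90,
                           cone_deg = 0, photons = 1000) {
  if (z_nm < 0) stop("z_nm must be non-negative (emitter above the interface)")
  if (phi_deg <= -90 || phi_deg > 90)
    stop("phi_deg must lie in (-90, 90]")
  if (theta_deg < 0 || theta_deg > 90)
    stop("theta_deg must lie in [0, 90]")
  if (cone_deg < 0 || cone_deg > 90)
    stop("cone_deg must lie in [0, 90]")
  if (photons <= 0) stop("photons must be positive")
  x <- list(x_nm = x_nm, y_nm = y_nm, z_nm = z_nm,
            phi_deg = phi_deg, theta_deg = theta_deg,
            cone_deg = cone_deg, photons = photons)
  class(x) <- "dipole_emitter"
  x
}

#' @export
print.dipole_emitter <- function(x, ...) {
  cat(sprintf(
    "Dipole emitter at (%.1f, %.1f, %.1f) nm: phi %.1f deg, theta %.1f deg, cone %.1f deg, %g photons\n",
    x$x_nm, x$y_nm, x$z_nm, x$phi_deg, x$theta_deg, x$cone_deg, x$photons))
  invisible(x)
}

#' Near-uniform directions in a cone (Fibonacci lattice)
#'
#' Deterministic, near-uniform sampling of unit vectors within a cone of
#' half angle `cone_deg` about the +z axis, by a Fibonacci spiral in
#' `cos(beta)`.
#'
#' @param cone_deg Cone half angle, degrees.
#' @param n Number of directions.
#' @return An `n x 3` matrix of unit vectors.
#' @export
fibonacci_cone <- function(cone_deg, n = 512) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  cmin <- cos(cone_deg * pi / 180)
  cb <- 1 - (1 - cmin) * i / n  # uniform in cos(beta) over [cmin, 1]
  sb <- sqrt(pmax(0, 1 - cb^2))
  golden <- pi * (3 - sqrt(5))
  az <- golden * (seq_len(n) - 1)
  cbind(sb * cos(az), sb * sin(az), cb)
}

# Rotation taking +z to the direction (phi, theta).
rotation_to_axis <- function(phi_deg, theta_deg) {
  p <- phi_deg * pi / 180; t <- theta_deg * pi / 180
  Rz <- matrix(c(cos(p), sin(p), 0, -sin(p), cos(p), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  Rz %*% Ry
}

#' Second moments of the dipole orientation over a wobble cone
#'
#' The detected intensity is quadratic in the dipole unit vector, so the
#' time-averaged image of a wobbling molecule depends on its orientation
#' distribution only through the 3 x 3 second-moment matrix
#' `M = <mu mu^T>`. For a cone of half angle `delta` uniform in solid
#' angle around its axis the moments are available in closed form: in the
#' cone frame `M = diag(a, a, b)` with `b = (1 + c + c^2) / 3`,
#' `a = (1 - b) / 2`, `c = cos(delta)`; the matrix is then rotated to the
#' mean orientation `(phi_deg, theta_deg)`. For `cone_deg = 0` it is the
#' rank-one matrix `mu mu^T`. A numeric average over sampled cone
#' directions (see [fibonacci_cone()]) converges to the same matrix and
#' serves as its cross-check.
#'
#' @param phi_deg,theta_deg Mean dipole orientation, degrees.
#' @param cone_deg Wobble-cone half angle, degrees.
#' @return A symmetric 3 x 3 matrix with unit trace.
#' @export
cone_second_moments <- function(phi_deg, theta_deg, cone_deg = 0) {
  R <- rotation_to_axis(phi_deg, theta_deg)
  if (cone_deg <= 0) {
    mu <- R %*% c(0, 0, 1)
    return(tcrossprod(mu))
  }
  cd <- cos(cone_deg * pi / 180)
  b <- (1 + cd + cd^2) / 3
  a <- (1 - b) / 2
  R %*% diag(c(a, a, b)) %*% t(R)
}

#' Rotational-constraint parameter of a wobble cone
#'
#' The scalar rotational mobility parameter reported alongside cone-model
#' fits, defined through the second moment of the cone distribution:
#' `gamma = (3 <cos^2 beta> - 1) / 2`, where `beta` is the angle between an
#' orientation sample and the cone axis. Equals 1 for an immobilized
#' molecule and 0 for free rotation; for a uniform cone of half angle
#' `delta`, `<cos^2 beta> = (1 + cos d + cos^2 d) / 3` and therefore
#' `gamma = cos(d) (1 + cos(d)) / 2`.
#'
#' @param cone_deg Cone half angle, degrees.
#' @return `gamma` in `[0, 1]`.
#' @export
wobble_gamma <- function(cone_deg) {
  cd <- cos(pmin(pmax(cone_deg, 0), 90) * pi / 180)
  cd * (1 + cd) / 2
}
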