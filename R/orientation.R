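#' Orientation and mobility estimates from a Stokes region of interest
#'
#' The intensity-only orientation estimator. Over a small region of
#' interest covering one molecule's image: the unweighted means
#' `<S0>, <S1>, <S2>` give the in-plane angle
#' `phi = atan2(<S2>, <S1>) / 2`, the net degree of linear polarization
#' `netDoLP = sqrt(<S1>^2 + <S2>^2) / <S0>`, and through
#' [theta_from_netdolp()] the polar angle `theta` (flagged invalid when the
#' inversion argument leaves `[0, 1]`, e.g. under noise, wobble or index
#' mismatch). The rotational-mobility proxy `avgDoLP` is the mean over ROI
#' pixels of the per-pixel degree of linear polarization.
#'
#' The `avgDoLP` mean runs over the pixels inside the spot's half-maximum
#' support (`S0 > support_fraction * max(S0)`): outside it the per-pixel
#' ratio is a quotient of near-zero quantities and reflects noise rather
#' than rotational mobility. Per-pixel values are clipped to `[0, 1]` so
#' the proxy remains a degree of polarization under noise.
#'
#' @param roi_stokes A list with matrices `S0`, `S1`, `S2` restricted to
#'   the ROI. `S0` should be background-corrected; `S1` and `S2` need no
#'   correction because an unpolarized background cancels in them.
#' @param constants A [fourkas_constants()] object.
#' @param support_fraction Fraction of the ROI peak `S0` defining the
#'   pixels entering the `avgDoLP` mean.
#' @return A one-row data.frame with `phi_deg` in `(-90, 90]`,
#'   `theta_deg`, `theta_valid`, `netdolp`, `avgdolp`; `NULL` if
#'   `<S0> <= 0` (rejected localization).
#' @export
estimate_orientation <- function(roi_stokes, constants,
                                 support_fraction = 0.5) {
  s0 <- mean(roi_stokes$S0)
  if (!is.finite(s0) || s0 <= 0) return(NULL)
  s1 <- mean(roi_stokes$S1)
  s2 <- mean(roi_stokes$S2)
  phi <- 0.5 * atan2(s2, s1) * 180 / pi
  if (phi <= -90 + 1e-12) phi <- 90
  net <- sqrt(s1^2 + s2^2) / s0
  th <- theta_from_netdolp(net, constants)
  keep <- roi_stokes$S0 > support_fraction * max(roi_stokes$S0) &
    roi_stokes$S0 > 0
  avg <- if (any(keep)) {
    dolp <- sqrt(roi_stokes$S1^2 + roi_stokes$S2^2) / roi_stokes$S0
    mean(pmin(dolp[keep], 1))
  } else NA_real_
  data.frame(phi_deg = phi, theta_deg = th$theta_deg,
             theta_valid = th$theta_valid, netdolp = net, avgdolp = avg)
}

#' Circular mean of 180-degree-periodic angles
#'
#' In-plane dipole angles are axial (period 180 degrees); means and spreads
#' are computed with the angle-doubling method to avoid wrap bias near the
#' +/-90 degree boundary.
#'
#' @param phi_deg Angles in degrees.
#' @return Mean angle in `(-90, 90]` degrees.
#' @export
phi_mean <- function(phi_deg) {
  a <- 2 * phi_deg * pi / 180
  m <- atan2(mean(sin(a)), mean(cos(a))) / 2 * 180 / pi
  if (m <= -90 + 1e-12) m <- 90
  m
}

#' Circular standard deviation of 180-degree-periodic angles
#'
#' Angle-doubling circular standard deviation,
#' `sd = sqrt(-2 log R) / 2` in degrees, where `R` is the resultant length
#' of the doubled angles. For tightly concentrated samples this approaches
#' the ordinary standard deviation.
#'
#' @param phi_deg Angles in degrees.
#' @return Standard deviation in degrees.
#' @export
phi_sd <- function(phi_deg) {
  a <- 2 * phi_deg * pi / 180
  r <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
  r <- min(max(r, 1e-12), 1)
  sqrt(-2 * log(r)) / 2 * 180 / pi
}

#' Smallest signed difference between axial angles
#'
#' @param a,b Angles in degrees (180-degree period).
#' @return Signed difference `a - b` wrapped to `(-90, 90]`.
#' @export
phi_diff <- function(a, b) {
  d <- (a - b) %% 180
  d[d > 90] <- d[d > 90] - 180
  d
}
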