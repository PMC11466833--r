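#' Optical configuration of a polarization-camera microscope
#'
#' Bundles the objective, tube lens, sample medium and camera geometry used
#' by the dipole-spread-function (DSF) simulator and the pixel-size design
#' tool. The half-maximum collection angle of the objective is
#' `alpha = asin(NA / n_immersion)` and the sample-plane ("virtual") pixel
#' pitch is `camera_pixel_um * 1000 / magnification` nanometres.
#'
#' @param numerical_aperture Objective numerical aperture (must be smaller
#'   than `n_immersion`).
#' @param n_immersion Refractive index of the immersion medium (and of the
#'   coverglass, assumed index matched to it).
#' @param n_sample Refractive index of the sample medium. `1.33` for aqueous
#'   samples; set equal to `n_immersion` for an index-matched mountant.
#' @param wavelength_nm Emission wavelength in vacuum, nanometres.
#' @param magnification Total system magnification onto the camera.
#' @param tube_focal_length_mm Focal length of the tube lens actually used,
#'   millimetres. When it differs from `tube_design_focal_length_mm` the
#'   effective magnification is rescaled by their ratio (e.g. an objective
#'   designed for a 180 mm tube lens mounted on a 200 mm body).
#' @param tube_design_focal_length_mm Tube-lens focal length the objective
#'   was designed for, millimetres.
#' @param camera_pixel_um Physical pixel pitch of the camera, micrometres.
#' @param defocus_nm Axial offset of the focal plane from the emitter plane,
#'   nanometres.
#'
#' @return An object of class `optical_config`.
#' @examples
#' opt <- optical_config() # the 1.4-NA oil / x60 / 3.45 um configuration
#' sample_pitch_nm(opt)    # 57.5 nm
#' @export
optical_config <- function(numerical_aperture = 1.4,
                           n_immersion = 1.518,
                           n_sample = 1.33,
                           wavelength_nm = 630,
                           magnification = 60,
                           tube_focal_length_mm = 200,
                           tube_design_focal_length_mm = 200,
                           camera_pixel_um = 3.45,
                           defocus_nm = 0) {
  stopifnot(numerical_aperture > 0, n_immersion > 0, n_sample > 0,
            wavelength_nm > 0, magnification > 0, camera_pixel_um > 0,
            tube_focal_length_mm > 0, tube_design_focal_length_mm > 0)
  if (numerical_aperture >= n_immersion)
    stop("numerical_aperture must be smaller than n_immersion")
  x <- list(numerical_aperture = numerical_aperture,
            n_immersion = n_immersion,
            n_sample = n_sample,
            wavelength_nm = wavelength_nm,
            magnification = magnification,
            tube_focal_length_mm = tube_focal_length_mm,
            tube_design_focal_length_mm = tube_design_focal_length_mm,
            camera_pixel_um = camera_pixel_um,
            defocus_nm = defocus_nm)
  class(x) <- "optical_config"
  x
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  NA %.3g, n_immersion %.4g, n_sample %.4g\n",
              x$numerical_aperture, x$n_immersion, x$n_sample))
  cat(sprintf("  wavelength %g nm, magnification x%g (effective x%.4g)\n",
              x$wavelength_nm, x$magnification, effective_magnification(x)))
  cat(sprintf("  camera pixel %g um -> sample-plane pitch %.4g nm\n",
              x$camera_pixel_um, sample_pitch_nm(x)))
  cat(sprintf("  half collection angle alpha = %.4f rad\n",
              collection_half_angle(x)))
  invisible(x)
}

#' Half-maximum collection angle of the objective
#'
#' @param optics An [optical_config()].
#' @return `asin(NA / n_immersion)` in radians.
#' @export
collection_half_angle <- function(optics) {
  asin(optics$numerical_aperture / optics$n_immersion)
}

#' Effective magnification including a tube-lens mismatch
#'
#' @param optics An [optical_config()].
#' @return Nominal magnification scaled by the ratio of the actual to the
#'   design tube-lens focal length.
#' @export
effective_magnification <- function(optics) {
  optics$magnification *
    optics$tube_focal_length_mm / optics$tube_design_focal_length_mm
}

#' Sample-plane (virtual) pixel pitch
#'
#' @param optics An [optical_config()].
#' @return Pixel pitch referred to the sample plane, nanometres.
#' @export
sample_pitch_nm <- function(optics) {
  optics$camera_pixel_um * 1000 / effective_magnification(optics)
}

#' Angular integration constants for four-channel polarized detection
#'
#' Closed-form constants `A`, `B`, `C` describing the total intensity a
#' dipole emitter sends through an ideal linear analyzer at angle `eta`,
#' integrated over the collection cone of an aplanatic objective with half
#' angle `alpha`:
#' `I(eta) = K * (A + B sin^2(theta) + C sin^2(theta) cos(2 (phi - eta)))`,
#' where `(phi, theta)` are the azimuthal and polar orientation of the
#' emission dipole. They are obtained by integrating the dipole far field
#' over the cone after meridional collimation; `K` is an overall scale that
#' cancels in every estimator built from intensity ratios.
#'
#' @param alpha Half-maximum collection angle in radians, in `(0, pi/2)`.
#' @return A list of class `fourkas_constants` with elements `A`, `B`, `C`
#'   and `alpha`.
#' @seealso [theta_from_netdolp()], [netdolp_from_theta()]
#' @export
fourkas_constants <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= pi / 2)
    stop("alpha must be a single value in (0, pi/2)")
  ca <- cos(alpha)
  x <- list(A = 1 / 6 - ca / 4 + ca^3 / 12,
            B = ca / 8 - ca^3 / 8,
            C = 7 / 48 - ca / 16 - ca^2 / 16 - ca^3 / 48,
            alpha = alpha)
  class(x) <- "fourkas_constants"
  x
}

#' @export
print.fourkas_constants <- function(x, ...) {
  cat(sprintf("Angular constants (alpha = %.4f rad): A = %.6f, B = %.6f, C = %.6f\n",
              x$alpha, x$A, x$B, x$C))
  invisible(x)
}

#' Invert the net degree of linear polarization to a polar angle
#'
#' For a rotationally immobilized emitter in an index-matched medium the net
#' degree of linear polarization `p` measured over a region of interest
#' determines the polar angle of the emission dipole:
#' `theta = asin(sqrt(A p / (C - B p)))`, with `theta` measured from the
#' optical axis (`theta = 90` degrees is in the sample plane, `theta = 0`
#' is along the optical axis and gives `p = 0`).
#'
#' The argument of the square root is clamped to `[0, 1]`; values outside
#' that interval (from noise, rotational mobility or refractive index
#' mismatch) are flagged.
#'
#' @param netdolp Net degree of linear polarization, one value or a vector.
#' @param constants A [fourkas_constants()] object.
#' @return A data.frame with columns `theta_deg` and `theta_valid`.
#' @export
theta_from_netdolp <- function(netdolp, constants) {
  stopifnot(inherits(constants, "fourkas_constants"))
  arg <- constants$A * netdolp / (constants$C - constants$B * netdolp)
  valid <- is.finite(arg) & arg >= 0 & arg <= 1
  arg_cl <- pmin(pmax(arg, 0), 1)
  arg_cl[!is.finite(arg_cl)] <- 0
  data.frame(theta_deg = asin(sqrt(arg_cl)) * 180 / pi,
             theta_valid = valid)
}

#' Forward map from polar angle to net degree of linear polarization
#'
#' The noiseless net degree of linear polarization of an immobilized dipole
#' at polar angle `theta` (degrees) under the four-channel analyzer model:
#' `p = C sin^2(theta) / (A + B sin^2(theta))`.
#'
#' @param theta_deg Polar angle(s) from the optical axis, degrees.
#' @param constants A [fourkas_constants()] object.
#' @return Net degree of linear polarization, same length as `theta_deg`.
#' @export
netdolp_from_theta <- function(theta_deg, constants) {
  stopifnot(inherits(constants, "fourkas_constants"))
  s2 <- sin(theta_deg * pi / 180)^2
  constants$C * s2 / (constants$A + constants$B * s2)
}
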