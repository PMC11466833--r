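#' CMOS camera noise model
#'
#' Shot noise, quantum efficiency, Gaussian read noise and digitization for
#' a scientific CMOS detector. Per pixel, a frame in photons is converted
#' as: `electrons ~ Poisson(QE * (signal + background))` plus
#' `Normal(0, read_noise)` electrons, then
#' `ADU = round(gain * electrons + offset)` clamped to the bit depth.
#'
#' `background` is the expected background level per pixel per frame in
#' photons arriving at that pixel's detector (i.e. after the analyzer).
#'
#' @param quantum_efficiency Detection probability per photon, `(0, 1]`.
#' @param gain ADU per electron.
#' @param offset Dark level, ADU.
#' @param read_noise RMS read noise, electrons.
#' @param bit_depth Digitizer depth, bits.
#' @param background Background photons per pixel per frame.
#' @return An object of class `camera_noise_model`.
#' @export
camera_noise_model <- function(quantum_efficiency = 0.7,
                               gain = 1,
                               offset = 100,
                               read_noise = 2,
                               bit_depth = 16,
                               background = 10) {
  stopifnot(quantum_efficiency > 0, quantum_efficiency <= 1,
            gain > 0, offset >= 0, read_noise >= 0,
            bit_depth >= 1, background >= 0)
  structure(list(quantum_efficiency = quantum_efficiency, gain = gain,
                 offset = offset, read_noise = read_noise,
                 bit_depth = bit_depth, background = background),
            class = "camera_noise_model")
}

#' @export
print.camera_noise_model <- function(x, ...) {
  cat(sprintf(
    "CMOS noise model: QE %.2f, gain %g ADU/e-, offset %g ADU, read noise %g e-, %d bit, background %g photons/px\n",
    x$quantum_efficiency, x$gain, x$offset, x$read_noise,
    x$bit_depth, x$background))
  invisible(x)
}

# Evaluate fn with a private, seeded RNG stream, restoring the caller's.
with_local_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Add CMOS camera noise to a frame
#'
#' @param frame Matrix (or 3D array of frames) in photons per pixel.
#' @param noise A [camera_noise_model()].
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return Integer-valued numeric array in ADU, clamped to the bit depth,
#'   with attribute `n_saturated` counting clamped-high pixels.
#' @export
add_camera_noise <- function(frame, noise = camera_noise_model(), seed = 1) {
  stopifnot(inherits(noise, "camera_noise_model"))
  adu_max <- 2^noise$bit_depth - 1
  out <- with_local_seed(seed, function() {
    lambda <- noise$quantum_efficiency * (pmax(frame, 0) + noise$background)
    e <- stats::rpois(length(lambda), lambda) +
      stats::rnorm(length(lambda), 0, noise$read_noise)
    adu <- round(noise$gain * e + noise$offset)
    array(pmin(pmax(adu, 0), adu_max), dim = dim(frame))
  })
  attr(out, "n_saturated") <- sum(out == adu_max)
  out
}

#' Convert a raw ADU frame back to expected photons per pixel
#'
#' Inverts the mean of the camera model: photons =
#' `(ADU - offset) / (gain * QE)`. Background photons are not removed (see
#' [background_correct()]).
#'
#' @param frame Array in ADU.
#' @param noise The [camera_noise_model()] used for acquisition.
#' @return Array in photon units (may be negative where noise undershoots
#'   the offset).
#' @export
adu_to_photons <- function(frame, noise) {
  stopifnot(inherits(noise, "camera_noise_model"))
  (frame - noise$offset) / (noise$gain * noise$quantum_efficiency)
}
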