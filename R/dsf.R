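#' Image grid specification
#'
#' The pixel raster a simulated frame is rendered on. Pixels are indexed
#' 0-based with the pixel-centre convention: pixel `(row, col)` is centred
#' at `(x, y) = (col, row) * pitch_nm`, x to the right and y down.
#'
#' @param nx,ny Number of columns and rows.
#' @param pitch_nm Sample-plane pixel pitch, nanometres. Must match the
#'   optical configuration it is used with (see [sample_pitch_nm()]).
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(nx, ny = nx, pitch_nm) {
  stopifnot(nx >= 1, ny >= 1, pitch_nm > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pitch_nm = pitch_nm), class = "image_grid")
}

# Centre pixel (0-based) used as the FFT origin of a grid.
grid_centre_px <- function(n) floor((n - 1) / 2)

# Memo cache for pupil/image basis fields keyed by configuration.
.basis_cache <- new.env(parent = emptyenv())

#' Vectorial dipole-spread-function basis fields
#'
#' Computes the complex image-plane fields of the three Cartesian dipole
#' components (x, y, z) of an emitter near the coverglass interface, for
#' both camera-frame field polarizations, on the requested grid. The image
#' of any (possibly wobbling) dipole is a quadratic form in these six
#' fields, so they are cached and reused across orientations.
#'
#' Model: the back-focal-plane field of an oscillating dipole in the sample
#' medium is assembled from its s- and p-polarized far-field amplitudes,
#' Fresnel-transmitted through the sample/coverglass interface (with
#' complex-angle continuation above the critical angle, capturing
#' supercritical-angle fluorescence for emitters at the interface),
#' collimated aplanatically (apodization `1/sqrt(cos)`), and propagated to
#' the image plane by FFT. The pupil is sampled with at least
#' `min_pupil_samples` points across its diameter and the FFT grid is at
#' least `min_fft` points, giving generous zero padding.
#'
#' @param optics An [optical_config()].
#' @param grid An [image_grid()]; its pitch must equal
#'   `sample_pitch_nm(optics)` to within 1e-6 nm.
#' @param x_nm,y_nm Emitter position (see [image_grid()] coordinates).
#' @param z_nm Emitter height above the interface, nanometres.
#' @param min_pupil_samples,min_fft Numerical resolution controls.
#' @param cache Reuse previously computed fields for identical settings.
#' @return A list with the cropped complex basis fields `Ex`/`Ey` per
#'   dipole component, the 3 x 3 full-plane energy matrix `energy` used for
#'   photon normalization, and bookkeeping fields.
#' @export
dsf_basis <- function(optics, grid, x_nm = 0, y_nm = 0, z_nm = 0,
                      min_pupil_samples = 128, min_fft = 512, cache = TRUE) {
  stopifnot(inherits(optics, "optical_config"), inherits(grid, "image_grid"))
  pitch <- sample_pitch_nm(optics)
  if (abs(pitch - grid$pitch_nm) > 1e-6)
    stop(sprintf("grid pitch (%g nm) does not match the optics sample-plane pitch (%g nm)",
                 grid$pitch_nm, pitch))
  if (z_nm < 0) stop("z_nm must be non-negative")
  key <- paste(optics$numerical_aperture, optics$n_immersion, optics$n_sample,
               optics$wavelength_nm, optics$defocus_nm, pitch,
               grid$nx, grid$ny, x_nm, y_nm, z_nm,
               min_pupil_samples, min_fft, sep = "|")
  if (cache && !is.null(.basis_cache[[key]])) return(.basis_cache[[key]])

  na <- optics$numerical_aperture
  n1 <- optics$n_immersion
  ns <- optics$n_sample
  lam <- optics$wavelength_nm
  M <- 2^ceiling(log2(max(min_fft, min_pupil_samples * lam / (2 * na * pitch))))

  fr <- c(0:(M / 2 - 1), -(M / 2):-1) / (M * pitch) # cycles per nm
  nux <- matrix(fr, M, M, byrow = TRUE)             # varies along columns (x)
  nuy <- matrix(fr, M, M)                           # varies along rows (y)
  rho <- sqrt(nux^2 + nuy^2) * lam                  # = n1 sin(theta1)
  mask <- rho <= na
  st1 <- pmin(rho / n1, 1)
  ct1 <- sqrt(1 - st1^2)
  az <- atan2(nuy, nux)
  sts <- (n1 / ns) * st1
  cts <- sqrt(as.complex(1 - sts^2))                # +i sqrt(.) above critical
  tp <- 2 * ns * cts / (ns * ct1 + n1 * cts)
  ts <- 2 * ns * cts / (ns * cts + n1 * ct1)
  tp[!mask] <- 0; ts[!mask] <- 0

  k0 <- 2 * pi / lam
  phase <- exp(1i * k0 * (n1 * ct1 * optics$defocus_nm) + 1i * k0 * ns * cts * z_nm)
  # pupil tilt placing the emitter at (x_nm, y_nm) relative to the grid centre
  x0 <- x_nm - grid_centre_px(grid$nx) * pitch
  y0 <- y_nm - grid_centre_px(grid$ny) * pitch
  tilt <- exp(2i * pi * (nux * x0 + nuy * y0))
  apod <- ifelse(mask, 1 / sqrt(pmax(ct1, 1e-9)), 0)
  pre <- apod * phase * tilt * mask

  amp_p <- list(x = cts * cos(az), y = cts * sin(az), z = -sts + 0i)
  amp_s <- list(x = -sin(az) + 0i, y = cos(az) + 0i, z = 0i * az)
  fields <- list()
  for (d in c("x", "y", "z")) {
    er <- tp * amp_p[[d]]
    ea <- ts * amp_s[[d]]
    fields[[paste0("Ex", d)]] <- stats::fft((er * cos(az) - ea * sin(az)) * pre)
    fields[[paste0("Ey", d)]] <- stats::fft((er * sin(az) + ea * cos(az)) * pre)
  }

  ds <- c("x", "y", "z")
  energy <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    e <- sum(Re(fields[[paste0("Ex", ds[i])]] * Conj(fields[[paste0("Ex", ds[j])]]) +
                fields[[paste0("Ey", ds[i])]] * Conj(fields[[paste0("Ey", ds[j])]])))
    energy[i, j] <- e; energy[j, i] <- e
  }

  ix <- ((0:(grid$nx - 1)) - grid_centre_px(grid$nx)) %% M + 1
  iy <- ((0:(grid$ny - 1)) - grid_centre_px(grid$ny)) %% M + 1
  basis <- lapply(fields, function(z) z[iy, ix, drop = FALSE])

  out <- list(basis = basis, energy = energy, fft_size = M,
              grid = grid, pitch_nm = pitch)
  if (cache) .basis_cache[[key]] <- out
  out
}

#' Clear the cached dipole-spread-function basis fields
#'
#' @return Invisibly, the number of entries removed.
#' @export
clear_dsf_cache <- function() {
  n <- length(ls(.basis_cache))
  rm(list = ls(.basis_cache), envir = .basis_cache)
  invisible(n)
}

#' Simulate the four polarized channel images of a dipole emitter
#'
#' Renders the noiseless intensity images a single (possibly wobbling)
#' dipole emitter would produce behind ideal linear analyzers at 0, 45, 90
#' and 135 degrees, co-registered on the same grid, in photons per pixel.
#' Wobble is handled exactly through the orientation second moments of a
#' uniform cone (see [cone_second_moments()]): because intensity is
#' quadratic in the dipole vector, averaging intensities over the cone and
#' contracting with the averaged second moments are identical.
#'
#' Photon bookkeeping: `emitter$photons` is the expected number of signal
#' photons arriving at the analyzer plane over the whole (uncropped) image
#' plane; the returned channel images therefore sum to at most
#' `2 * photons` (each analyzer transmits half of an unpolarized field, and
#' the four-channel sum counts every photon twice via
#' `I0 + I90 = I45 + I135 = total`), less any energy falling outside the
#' requested grid.
#'
#' @param emitter A [dipole_emitter()].
#' @param optics An [optical_config()].
#' @param grid An [image_grid()] whose pitch matches the optics.
#' @param basis Optional precomputed [dsf_basis()] for this emitter
#'   position (overrides position-dependent caching).
#' @return A list of class `dipole_channels` with matrices `I0`, `I45`,
#'   `I90`, `I135` (rows = y), plus the grid.
#' @export
simulate_dipole_channels <- function(emitter, optics, grid, basis = NULL) {
  stopifnot(inherits(emitter, "dipole_emitter"))
  if (is.null(basis))
    basis <- dsf_basis(optics, grid, emitter$x_nm, emitter$y_nm, emitter$z_nm)
  mom <- cone_second_moments(emitter$phi_deg, emitter$theta_deg,
                             emitter$cone_deg)
  channels_from_moments(basis, mom, emitter$photons)
}

# Contract basis fields with an orientation second-moment matrix.
channels_from_moments <- function(basis, mom, photons) {
  ds <- c("x", "y", "z")
  norm <- sum(mom * basis$energy)
  sc <- photons / norm
  out <- list()
  for (eta in c(0, 45, 90, 135)) {
    e <- eta * pi / 180
    a <- lapply(ds, function(d) cos(e) * basis$basis[[paste0("Ex", d)]] +
                                sin(e) * basis$basis[[paste0("Ey", d)]])
    img <- 0
    for (i in 1:3) for (j in 1:3)
      img <- img + mom[i, j] * Re(a[[i]] * Conj(a[[j]]))
    out[[paste0("I", eta)]] <- img * sc
  }
  out$grid <- basis$grid
  class(out) <- "dipole_channels"
  out
}
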