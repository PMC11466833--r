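# Radius (cycles/pixel) enclosing a fraction of a map's spectral energy.
spectral_energy_radius <- function(img, fraction) {
  n1 <- nrow(img); n2 <- ncol(img)
  P <- abs(stats::fft(img))^2
  f1 <- c(0:(ceiling(n1 / 2) - 1), -(floor(n1 / 2)):-1) / n1
  f2 <- c(0:(ceiling(n2 / 2) - 1), -(floor(n2 / 2)):-1) / n2
  r <- sqrt(outer(f1^2, f2^2, "+"))
  o <- order(as.vector(r))
  cs <- cumsum(as.vector(P)[o])
  as.vector(r)[o][which(cs >= fraction * cs[length(cs)])[1]]
}

# Worst-case emitter orientation set spanning the S1/S2 modulation extremes.
sampling_orientation_set <- function() {
  list(list(phi = 0,    theta = 90, cone = 0),
       list(phi = 22.5, theta = 90, cone = 0),
       list(phi = 45,   theta = 90, cone = 0),
       list(phi = 0,    theta = 0,  cone = 0),
       list(phi = 0,    theta = 90, cone = 90))
}

#' Spectral overlap margin of the Stokes carriers at a given pixel size
#'
#' The 2 x 2 analyzer mosaic places `S0` at baseband and modulates `S1`
#' and `S2` onto the Nyquist carriers, so the raw frame can only be
#' demodulated artifact-free if the `S0` band and the carrier bands do not
#' overlap. This simulates noiseless single-dipole images at pitch
#' `pixel_nm` over a worst-case orientation set, measures the spectral
#' support of each Stokes component as the radius enclosing
#' `energy_fraction` of its energy (dipole images are not strictly
#' band-limited after sampling, so supports are measured, not assumed),
#' and returns the signed gap
#' `0.5 - r(S0) - max r(S1, S2)` in cycles per pixel. Negative values mean
#' the bands overlap.
#'
#' @param optics An [optical_config()]; only its NA, indices and wavelength
#'   matter (the camera geometry is overridden by `pixel_nm`).
#' @param pixel_nm Candidate sample-plane pixel size, nanometres.
#' @param energy_fraction Encircled-energy fraction defining band support.
#' @param grid_px Simulation grid side (pixels).
#' @return Signed margin in cycles per pixel.
#' @export
stokes_spectral_overlap <- function(optics, pixel_nm,
                                    energy_fraction = 0.999, grid_px = 64) {
  stopifnot(pixel_nm > 0)
  opt <- optics
  opt$magnification <- 1
  opt$tube_focal_length_mm <- opt$tube_design_focal_length_mm <- 200
  opt$camera_pixel_um <- pixel_nm / 1000
  grid <- image_grid(grid_px, grid_px, pixel_nm)
  r0 <- 0; r12 <- 0
  for (o in sampling_orientation_set()) {
    em <- dipole_emitter(x_nm = grid_centre_px(grid_px) * pixel_nm,
                         y_nm = grid_centre_px(grid_px) * pixel_nm,
                         phi_deg = o$phi, theta_deg = o$theta,
                         cone_deg = o$cone, photons = 1)
    ch <- simulate_dipole_channels(em, opt, grid)
    st <- stokes_from_channels(ch$I0, ch$I45, ch$I90, ch$I135)
    r0 <- max(r0, spectral_energy_radius(st$S0, energy_fraction))
    if (max(abs(st$S1)) > 1e-9 * max(st$S0))
      r12 <- max(r12, spectral_energy_radius(st$S1, energy_fraction))
    if (max(abs(st$S2)) > 1e-9 * max(st$S0))
      r12 <- max(r12, spectral_energy_radius(st$S2, energy_fraction))
  }
  0.5 - r0 - r12
}

#' Largest pixel size with artifact-free Stokes recovery
#'
#' Sweeps candidate sample-plane pixel sizes, evaluates
#' [stokes_spectral_overlap()] at each, and reports the largest size whose
#' margin is non-negative (located by linear interpolation of the margin's
#' zero crossing between sweep points; the margin decreases with pixel
#' size).
#'
#' @param optics An [optical_config()].
#' @param pixel_range_nm Sweep range `c(min, max)`, nanometres.
#' @param step_nm Sweep step, nanometres.
#' @param ... Passed to [stokes_spectral_overlap()].
#' @return A list of class `sampling_report`: `optimal_nm` and `sweep`
#'   (data.frame `pixel_nm`, `margin`).
#' @export
optimal_pixel_size <- function(optics, pixel_range_nm = c(35, 95),
                               step_nm = 2.5, ...) {
  px <- seq(pixel_range_nm[1], pixel_range_nm[2], by = step_nm)
  margin <- vapply(px, function(p) stokes_spectral_overlap(optics, p, ...),
                   numeric(1))
  sweep <- data.frame(pixel_nm = px, margin = margin)
  if (all(margin >= 0)) {
    opt <- max(px)
  } else if (all(margin < 0)) {
    opt <- NA_real_
  } else {
    i <- which(margin < 0)[1]
    opt <- px[i - 1] + (0 - margin[i - 1]) * step_nm / (margin[i] - margin[i - 1])
  }
  structure(list(optimal_nm = opt, sweep = sweep), class = "sampling_report")
}

#' @export
print.sampling_report <- function(x, ...) {
  cat(sprintf("Optimal sample-plane pixel size: %.1f nm\n", x$optimal_nm))
  print(x$sweep, digits = 3)
  invisible(x)
}
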