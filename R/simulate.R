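#' Simulate a raw polarization-camera image stack with ground truth
#'
#' Composes the vectorial channel simulator, the micropolarizer mosaic and
#' the CMOS noise model into a multi-frame acquisition. `scene` is a list
#' with one entry per frame, each a list of [dipole_emitter()]s (possibly
#' empty). Emitters closer than `overlap_nm` within a frame are allowed but
#' flagged in the ground truth.
#'
#' @param scene List of frames; each frame a list of [dipole_emitter()].
#' @param optics An [optical_config()].
#' @param grid An [image_grid()] (even dimensions recommended for
#'   downstream demosaicking).
#' @param mosaic A [mosaic_layout()].
#' @param noise A [camera_noise_model()]; `NULL` returns noiseless photon
#'   frames.
#' @param seed Seed controlling all noise draws.
#' @param overlap_nm Distance below which co-frame emitters are flagged.
#' @param tiff_path,csv_path Optional output paths: 16-bit multi-page TIFF
#'   of the raw stack and a CSV ground-truth table with header
#'   `frame,x_nm,y_nm,phi_deg,theta_deg,cone_deg,photons,overlaps`.
#' @return A list of class `mosaic_stack`: `stack` (array ny x nx x
#'   n_frames; ADU if noise was applied, else photons), `truth`
#'   (data.frame), plus the grid/mosaic/noise/optics used.
#' @export
simulate_stack <- function(scene, optics = optical_config(),
                           grid = image_grid(32, 32, sample_pitch_nm(optics)),
                           mosaic = mosaic_layout(),
                           noise = camera_noise_model(),
                           seed = 1, overlap_nm = 500,
                           tiff_path = NULL, csv_path = NULL) {
  nt <- length(scene)
  stopifnot(nt >= 1)
  stack <- array(0, dim = c(grid$ny, grid$nx, nt))
  rows <- list()
  for (f in seq_len(nt)) {
    frame <- matrix(0, grid$ny, grid$nx)
    ems <- scene[[f]]
    for (em in ems) {
      ch <- simulate_dipole_channels(em, optics, grid)
      frame <- frame + apply_mosaic(ch, mosaic)
    }
    stack[, , f] <- frame
    if (length(ems)) {
      xs <- vapply(ems, `[[`, numeric(1), "x_nm")
      ys <- vapply(ems, `[[`, numeric(1), "y_nm")
      for (k in seq_along(ems)) {
        em <- ems[[k]]
        d2 <- (xs - em$x_nm)^2 + (ys - em$y_nm)^2
        rows[[length(rows) + 1]] <- data.frame(
          frame = f, x_nm = em$x_nm, y_nm = em$y_nm,
          phi_deg = em$phi_deg, theta_deg = em$theta_deg,
          cone_deg = em$cone_deg, photons = em$photons,
          overlaps = sum(d2 < overlap_nm^2) > 1)
      }
    }
  }
  if (!is.null(noise)) {
    seeds <- with_local_seed(seed, function()
      sample.int(.Machine$integer.max, nt))
    for (f in seq_len(nt))
      stack[, , f] <- add_camera_noise(stack[, , f], noise, seeds[f])
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
               phi_deg = numeric(), theta_deg = numeric(),
               cone_deg = numeric(), photons = numeric(),
               overlaps = logical())
  out <- list(stack = stack, truth = truth, grid = grid, optics = optics,
              mosaic = mosaic, noise = noise, seed = seed)
  class(out) <- "mosaic_stack"
  if (!is.null(tiff_path)) write_stack(stack, tiff_path)
  if (!is.null(csv_path)) utils::write.csv(truth, csv_path, row.names = FALSE)
  out
}

#' Scene helper: the same emitter repeated over many frames
#'
#' Builds the benchmark geometry used for precision measurements: one
#' static molecule imaged for `n_frames` frames.
#'
#' @param emitter A [dipole_emitter()].
#' @param n_frames Number of frames.
#' @return A scene list for [simulate_stack()].
#' @export
scene_repeats <- function(emitter, n_frames) {
  rep(list(list(emitter)), n_frames)
}
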