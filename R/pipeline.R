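#' Localize and orient molecules in a raw mosaic stack
#'
#' The fast intensity-only single-molecule pipeline. Per frame: convert ADU
#' to photons, demosaic to full-resolution Stokes maps, detect candidate
#' molecules on the incident-intensity map `S0`, cut a region of interest
#' around each, localize (`centroid` or `rotated_gaussian`), and estimate
#' the in-plane angle, polar angle, net and average degree of linear
#' polarization from the ROI Stokes means.
#'
#' Background handling: the per-frame median of the `S0` map (the ambient
#' level of a sparse single-molecule field) is subtracted from `S0` before
#' detection and orientation estimation; `S1` and `S2` are left untouched
#' because an unpolarized background cancels in the channel differences and
#' subtracting an estimate there would only add noise. Slowly varying
#' structured background can additionally be removed beforehand with
#' `background_window`.
#'
#' @param stack 3D array (ADU) or a `mosaic_stack` from [simulate_stack()],
#'   or a TIFF path.
#' @param optics An [optical_config()].
#' @param mosaic A [mosaic_layout()].
#' @param noise The [camera_noise_model()] used in acquisition (for the
#'   ADU-to-photon conversion); `NULL` if the stack is already in photons.
#' @param method Localization method, see [localize_roi()].
#' @param demosaic `"fourier"` or `"spline"`.
#' @param roi_px ROI side length (odd pixels).
#' @param detect_sigma_px,detect_k Detection parameters, see
#'   [detect_candidates()].
#' @param background_window Temporal median window for [background_correct()];
#'   `NULL` skips stack-level background correction (ROI-level border
#'   subtraction is always applied).
#' @param csv_path Optional output CSV (see [write_localizations()]).
#' @return A list of class `smolm_result`: `table` (localization
#'   data.frame), `qc` (list with per-stage counts).
#' @export
pipeline_localize <- function(stack, optics = optical_config(),
                              mosaic = mosaic_layout(),
                              noise = camera_noise_model(),
                              method = "centroid",
                              demosaic = c("fourier", "spline"),
                              roi_px = 9,
                              detect_sigma_px = 2, detect_k = 5,
                              background_window = NULL,
                              csv_path = NULL) {
  demosaic <- match.arg(demosaic)
  if (is.character(stack)) stack <- read_stack(stack)
  if (inherits(stack, "mosaic_stack")) stack <- stack$stack
  if (length(dim(stack)) == 2) stack <- array(stack, dim = c(dim(stack), 1))
  pitch <- sample_pitch_nm(optics)
  const <- fourkas_constants(collection_half_angle(optics))
  ph <- if (is.null(noise)) stack else adu_to_photons(stack, noise)
  if (!is.null(background_window)) ph <- background_correct(ph, background_window)
  nt <- dim(ph)[3]
  rows <- list()
  n_candidates <- 0L
  for (f in seq_len(nt)) {
    frame <- ph[, , f]
    st <- if (demosaic == "fourier") demosaic_fourier(frame, mosaic)
          else demosaic_spline(frame, mosaic)
    s0 <- st$S0 - stats::median(st$S0)
    cand <- detect_candidates(s0, sigma_px = detect_sigma_px,
                              k = detect_k, min_distance_px = roi_px)
    n_candidates <- n_candidates + nrow(cand)
    for (i in seq_len(nrow(cand))) {
      roi0 <- extract_roi(s0, cand$row[i], cand$col[i], roi_px)
      if (is.null(roi0)) next
      roi1 <- extract_roi(st$S1, cand$row[i], cand$col[i], roi_px)
      roi2 <- extract_roi(st$S2, cand$row[i], cand$col[i], roi_px)
      loc <- localize_roi(roi0, method)
      ori <- estimate_orientation(list(S0 = roi0, S1 = roi1, S2 = roi2),
                                  const)
      if (is.null(ori)) next
      rows[[length(rows) + 1]] <- data.frame(
        frame = f,
        x_nm = (attr(roi0, "col0") + loc$x_px) * pitch,
        y_nm = (attr(roi0, "row0") + loc$y_px) * pitch,
        photons = loc$photons,
        phi_deg = ori$phi_deg, theta_deg = ori$theta_deg,
        theta_valid = ori$theta_valid,
        netdolp = ori$netdolp, avgdolp = ori$avgdolp,
        fit_method = loc$fit_method, residual = loc$residual)
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(loc_columns))),
                    loc_columns)
  qc <- list(n_frames = nt, n_candidates = n_candidates,
             n_localizations = nrow(table))
  if (!is.null(csv_path)) write_localizations(table, csv_path)
  structure(list(table = table, qc = qc), class = "smolm_result")
}

#' @export
print.smolm_result <- function(x, ...) {
  cat(sprintf("SMOLM result: %d localizations from %d frames (%d candidates)\n",
              x$qc$n_localizations, x$qc$n_frames, x$qc$n_candidates))
  invisible(x)
}

#' Diffraction-limited polarization processing of a stack
#'
#' The workflow without single-molecule localization: per frame (or
#' z-slice), demosaic the raw frame and derive the angle/degree of linear
#' polarization maps and an HSV composite. Slice count is preserved.
#'
#' @inheritParams pipeline_localize
#' @return A list of class `dl_result` with per-frame lists `stokes`,
#'   `maps`, and an array `hsv` `(ny, nx, 3, n_frames)`.
#' @export
pipeline_diffraction_limited <- function(stack, optics = optical_config(),
                                         mosaic = mosaic_layout(),
                                         noise = camera_noise_model(),
                                         demosaic = c("fourier", "spline")) {
  demosaic <- match.arg(demosaic)
  if (is.character(stack)) stack <- read_stack(stack)
  if (inherits(stack, "mosaic_stack")) stack <- stack$stack
  if (length(dim(stack)) == 2) stack <- array(stack, dim = c(dim(stack), 1))
  ph <- if (is.null(noise)) stack else adu_to_photons(stack, noise)
  nt <- dim(ph)[3]
  stokes <- vector("list", nt)
  maps <- vector("list", nt)
  hsv <- array(0, dim = c(dim(ph)[1], dim(ph)[2], 3, nt))
  for (f in seq_len(nt)) {
    st <- if (demosaic == "fourier") demosaic_fourier(ph[, , f], mosaic)
          else demosaic_spline(ph[, , f], mosaic)
    stokes[[f]] <- st
    maps[[f]] <- polarization_maps(st)
    hsv[, , , f] <- hsv_composite(st)
  }
  structure(list(stokes = stokes, maps = maps, hsv = hsv), class = "dl_result")
}
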