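#' HSV polarization composite
#'
#' Renders Stokes maps as an RGB image in HSV space: hue encodes the angle
#' of linear polarization cyclically over its 180-degree period, saturation
#' the degree of linear polarization (clipped to `[0, 1]`), and value the
#' total intensity `S0` normalized to a high percentile.
#'
#' @param stokes A `stokes_maps` list.
#' @param value_percentile Percentile of positive `S0` used as white level.
#' @param gamma Display gamma applied to the value channel.
#' @return An `ny x nx x 3` RGB array in `[0, 1]`.
#' @export
hsv_composite <- function(stokes, value_percentile = 0.999, gamma = 1) {
  maps <- polarization_maps(stokes)
  hue <- ((maps$aolp_deg + 90) %% 180) / 180
  sat <- pmin(pmax(maps$dolp, 0), 1)
  pos <- stokes$S0[stokes$S0 > 0]
  white <- if (length(pos)) stats::quantile(pos, value_percentile) else 1
  val <- pmin(pmax(stokes$S0 / white, 0), 1)^gamma
  hue[is.na(hue)] <- 0
  sat[is.na(sat)] <- 0
  cols <- grDevices::hsv(as.vector(hue), as.vector(sat), as.vector(val))
  rgb <- grDevices::col2rgb(cols) / 255
  array(c(matrix(rgb[1, ], nrow(val)), matrix(rgb[2, ], nrow(val)),
          matrix(rgb[3, ], nrow(val))), dim = c(dim(val), 3))
}

#' Render localizations as orientation-coded rods
#'
#' Draws each localization as a short rod centred on its position and
#' aligned with its estimated in-plane angle, rasterized onto a
#' super-resolution pixel grid. Rods are coloured by a cyclic in-plane
#' angle colour map; localizations whose rotational-mobility proxy falls
#' below `mobile_threshold` can instead be drawn white to mark molecules
#' too rotationally free for a meaningful in-plane angle.
#'
#' @param table Localization data.frame with columns `x_nm`, `y_nm`,
#'   `phi_deg` and (if `mobile_white`) `avgdolp`.
#' @param pitch_nm Render pixel pitch, nanometres.
#' @param rod_length_nm Rod length, nanometres.
#' @param mobile_white Draw rows with `avgdolp < mobile_threshold` white.
#' @param mobile_threshold Threshold on `avgdolp` (default 0.4).
#' @param xlim,ylim Optional `c(min, max)` nm ranges; defaults to the data
#'   extent padded by one rod length.
#' @return An RGB array `ny x nx x 3` in `[0, 1]`, with attribute
#'   `extent_nm` giving `(xmin, xmax, ymin, ymax)`.
#' @export
render_rods <- function(table, pitch_nm = 10, rod_length_nm = 40,
                        mobile_white = FALSE, mobile_threshold = 0.4,
                        xlim = NULL, ylim = NULL) {
  stopifnot(all(c("x_nm", "y_nm", "phi_deg") %in% names(table)))
  pad <- rod_length_nm
  if (is.null(xlim)) xlim <- range(table$x_nm) + c(-pad, pad)
  if (is.null(ylim)) ylim <- range(table$y_nm) + c(-pad, pad)
  nx <- max(2L, ceiling(diff(xlim) / pitch_nm))
  ny <- max(2L, ceiling(diff(ylim) / pitch_nm))
  img <- array(0, dim = c(ny, nx, 3))
  if (nrow(table) == 0) return(structure(img, extent_nm = c(xlim, ylim)))
  hue <- ((table$phi_deg + 90) %% 180) / 180
  cols <- grDevices::col2rgb(grDevices::hsv(hue, 1, 1)) / 255
  if (mobile_white && "avgdolp" %in% names(table)) {
    mob <- table$avgdolp < mobile_threshold
    cols[, mob] <- 1
  }
  half <- rod_length_nm / 2
  steps <- seq(-half, half, length.out = max(3L, ceiling(rod_length_nm / pitch_nm) * 2 + 1))
  for (i in seq_len(nrow(table))) {
    a <- table$phi_deg[i] * pi / 180
    # same angular frame as phi: from +x toward +y (y down)
    xs <- table$x_nm[i] + steps * cos(a)
    ys <- table$y_nm[i] + steps * sin(a)
    cx <- pmin(pmax(floor((xs - xlim[1]) / pitch_nm) + 1, 1), nx)
    cy <- pmin(pmax(floor((ys - ylim[1]) / pitch_nm) + 1, 1), ny)
    for (k in seq_along(cx)) {
      img[cy[k], cx[k], 1] <- cols[1, i]
      img[cy[k], cx[k], 2] <- cols[2, i]
      img[cy[k], cx[k], 3] <- cols[3, i]
    }
  }
  structure(img, extent_nm = c(xlim, ylim))
}
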