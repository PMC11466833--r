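#' Split a raw mosaic frame into its four analyzer channels
#'
#' Rearranges the pixels of a raw polarization-camera frame into four
#' quarter-resolution images, one per analyzer angle, recording the
#' half-pixel offset of each channel's sampling lattice on the full grid.
#'
#' @param frame Raw frame matrix (any linear unit).
#' @param mosaic A [mosaic_layout()].
#' @return A list of class `split_channels` with quarter-resolution
#'   matrices `I0`, `I45`, `I90`, `I135` and an `offsets` list giving each
#'   channel's `(row, col)` parity on the full-resolution grid. Frames with
#'   odd dimensions are trimmed by one row/column with a warning.
#' @export
split_channels <- function(frame, mosaic = mosaic_layout()) {
  stopifnot(is.matrix(frame), inherits(mosaic, "mosaic_layout"))
  ny <- nrow(frame); nx <- ncol(frame)
  if (ny %% 2L == 1L || nx %% 2L == 1L) {
    warning("odd frame dimensions; trimming to even size")
    frame <- frame[seq_len(ny - ny %% 2L), seq_len(nx - nx %% 2L), drop = FALSE]
    ny <- nrow(frame); nx <- ncol(frame)
  }
  out <- list()
  offsets <- list()
  for (r in 0:1) for (c in 0:1) {
    eta <- mosaic$layout[r + 1, c + 1]
    nm <- paste0("I", eta)
    out[[nm]] <- frame[seq(r + 1, ny, by = 2), seq(c + 1, nx, by = 2),
                       drop = FALSE]
    offsets[[nm]] <- c(row = r, col = c)
  }
  out <- out[c("I0", "I45", "I90", "I135")]
  out$offsets <- offsets[c("I0", "I45", "I90", "I135")]
  out$full_dim <- c(ny, nx)
  class(out) <- "split_channels"
  out
}

#' Re-interleave split channels into a raw mosaic frame
#'
#' Exact inverse of [split_channels()] (for ideal analyzers).
#'
#' @param channels A `split_channels` object.
#' @param mosaic The [mosaic_layout()] used to split.
#' @return The reconstructed full-resolution frame.
#' @export
interleave_channels <- function(channels, mosaic = mosaic_layout()) {
  stopifnot(inherits(channels, "split_channels"))
  ny <- channels$full_dim[1]; nx <- channels$full_dim[2]
  frame <- matrix(0, ny, nx)
  for (nm in c("I0", "I45", "I90", "I135")) {
    off <- channels$offsets[[nm]]
    frame[seq(off["row"] + 1, ny, by = 2), seq(off["col"] + 1, nx, by = 2)] <-
      channels[[nm]]
  }
  frame
}

# 1D cubic-spline resampling of the rows/cols of a matrix.
spline_resample <- function(mat, at_in, at_out, along = c("col", "row")) {
  along <- match.arg(along)
  if (along == "row") return(t(spline_resample(t(mat), at_in, at_out, "col")))
  t(apply(mat, 1, function(v)
    stats::spline(at_in, v, xout = at_out, method = "fmm")$y))
}

#' Interpolate split channels to full resolution
#'
#' Upsamples each quarter-resolution channel to the full sensor grid by
#' separable cubic-spline interpolation, honouring the half-pixel offset of
#' its sampling lattice so that all four channels are co-registered. At the
#' pixels a channel actually measured, the output reproduces the
#' measurement exactly.
#'
#' @param channels A `split_channels` object.
#' @return A list with full-resolution matrices `I0`, `I45`, `I90`, `I135`.
#' @export
interpolate_channels <- function(channels) {
  stopifnot(inherits(channels, "split_channels"))
  ny <- channels$full_dim[1]; nx <- channels$full_dim[2]
  out <- list()
  for (nm in c("I0", "I45", "I90", "I135")) {
    off <- channels$offsets[[nm]]
    rows_in <- seq(off["row"], ny - 1, by = 2)
    cols_in <- seq(off["col"], nx - 1, by = 2)
    m <- spline_resample(channels[[nm]], cols_in, 0:(nx - 1), "col")
    out[[nm]] <- spline_resample(m, rows_in, 0:(ny - 1), "row")
  }
  out
}

#' Stokes parameter maps from four co-registered channel images
#'
#' `S0 = (I0 + I45 + I90 + I135) / 2`, `S1 = I0 - I90`,
#' `S2 = I45 - I135`, pixel-wise. `S0` estimates the intensity incident on
#' the micropolarizer array.
#'
#' @param I0,I45,I90,I135 Co-registered full-resolution channel images, or
#'   a single list with those elements as the first argument.
#' @return A list of class `stokes_maps` with matrices `S0`, `S1`, `S2`.
#' @export
stokes_from_channels <- function(I0, I45 = NULL, I90 = NULL, I135 = NULL) {
  if (is.list(I0) && is.null(I45)) {
    ch <- I0
    I0 <- ch$I0; I45 <- ch$I45; I90 <- ch$I90; I135 <- ch$I135
  }
  if (!all(dim(I0) == dim(I45)) || !all(dim(I0) == dim(I90)) ||
      !all(dim(I0) == dim(I135)))
    stop("channel images must share dimensions")
  structure(list(S0 = (I0 + I45 + I90 + I135) / 2,
                 S1 = I0 - I90,
                 S2 = I45 - I135),
            class = "stokes_maps")
}

# Raised-cosine radial low-pass transfer function on the FFT grid.
raised_cosine_lp <- function(ny, nx, cutoff, transition = 0.02) {
  fy <- c(0:(ceiling(ny / 2) - 1), -(floor(ny / 2)):-1) / ny
  fx <- c(0:(ceiling(nx / 2) - 1), -(floor(nx / 2)):-1) / nx
  r <- sqrt(outer(fy^2, fx^2, "+"))
  h <- 0.5 * (1 + cos(pi * (r - (cutoff - transition)) / (2 * transition)))
  h[r <= cutoff - transition] <- 1
  h[r >= cutoff + transition] <- 0
  h
}

fft_lowpass <- function(mat, cutoff, transition = 0.02) {
  h <- raised_cosine_lp(nrow(mat), ncol(mat), cutoff, transition)
  Re(stats::fft(stats::fft(mat) * h, inverse = TRUE)) / length(mat)
}

#' Fourier-demodulation Stokes estimation from a raw mosaic frame
#'
#' The 2 x 2 analyzer pattern amplitude-modulates `S1` and `S2` onto the
#' Nyquist carriers of the sensor while `S0` stays at baseband:
#' `m(r, c) = (S0 + cos(2 eta(r, c)) S1 + sin(2 eta(r, c)) S2) / 2`. The
#' frame is demodulated against the four pixel-parity carriers
#' `1, (-1)^r, (-1)^c, (-1)^(r+c)`, each product low-passed with a
#' raised-cosine window, and the Stokes maps recovered from the resulting
#' basebands by least squares. On band-limited inputs this matches
#' [stokes_from_channels()] applied to perfectly recovered channels.
#'
#' @param frame Raw mosaic frame (photon-linear units), even dimensions.
#' @param mosaic A [mosaic_layout()].
#' @param cutoff Low-pass half-band, cycles per pixel (default 0.25, the
#'   no-overlap band edge for optimally sampled data).
#' @param transition Raised-cosine transition half-width, cycles per pixel;
#'   the filter passes fully below `cutoff - transition` and stops fully
#'   above `cutoff + transition`, matching the narrow spectral gap between
#'   the baseband and the carriers at the optimal pixel pitch.
#' @return A `stokes_maps` list with full-resolution `S0`, `S1`, `S2`.
#' @export
demosaic_fourier <- function(frame, mosaic = mosaic_layout(),
                             cutoff = 0.25, transition = 0.02) {
  stopifnot(is.matrix(frame), inherits(mosaic, "mosaic_layout"))
  ny <- nrow(frame); nx <- ncol(frame)
  if (ny %% 2L == 1L || nx %% 2L == 1L)
    stop("demosaic_fourier needs even frame dimensions")
  pr <- rep_len(c(1, -1), ny)        # (-1)^r, r 0-based
  pc <- rep_len(c(1, -1), nx)
  carriers <- list(matrix(1, ny, nx),
                   matrix(pr, ny, nx),
                   matrix(pc, ny, nx, byrow = TRUE),
                   outer(pr, pc))
  bases <- lapply(carriers, function(ch) fft_lowpass(frame * ch, cutoff, transition))
  # Linear model: baseband_k = sum over parity positions of
  # chi_k(pos)/4 * (S0 + cos2eta S1 + sin2eta S2)/2
  pos <- expand.grid(r = 0:1, c = 0:1)
  eta <- mapply(function(r, c) mosaic$layout[r + 1, c + 1], pos$r, pos$c)
  chi <- cbind(1, (-1)^pos$r, (-1)^pos$c, (-1)^(pos$r + pos$c))
  design <- t(chi / 4) %*% cbind(0.5, 0.5 * cos(2 * eta * pi / 180),
                                 0.5 * sin(2 * eta * pi / 180))
  B <- vapply(bases, as.vector, numeric(ny * nx))
  S <- t(qr.solve(design, t(B)))
  structure(list(S0 = matrix(S[, 1], ny, nx),
                 S1 = matrix(S[, 2], ny, nx),
                 S2 = matrix(S[, 3], ny, nx)),
            class = "stokes_maps")
}

#' Spline-interpolation Stokes estimation from a raw mosaic frame
#'
#' Convenience composition: [split_channels()], [interpolate_channels()],
#' [stokes_from_channels()].
#'
#' @inheritParams demosaic_fourier
#' @return A `stokes_maps` list.
#' @export
demosaic_spline <- function(frame, mosaic = mosaic_layout()) {
  stokes_from_channels(interpolate_channels(split_channels(frame, mosaic)))
}

#' Angle and degree of linear polarization maps
#'
#' `AoLP = atan2(S2, S1) / 2` mapped to `(-90, 90]` degrees (the `-90`
#' boundary is reported as `+90`), and `DoLP = sqrt(S1^2 + S2^2) / S0`.
#' Pixels with `S0 <= 0` are masked (`NA`) rather than raising an error;
#' under noise `DoLP` may exceed 1 and is returned as-is.
#'
#' @param stokes A `stokes_maps` list.
#' @return A list of class `polarization_maps` with matrices `aolp_deg`
#'   and `dolp`.
#' @export
polarization_maps <- function(stokes) {
  stopifnot(all(c("S0", "S1", "S2") %in% names(stokes)))
  aolp <- 0.5 * atan2(stokes$S2, stokes$S1) * 180 / pi
  aolp[aolp <= -90 + 1e-12] <- 90
  dolp <- sqrt(stokes$S1^2 + stokes$S2^2) / stokes$S0
  bad <- !(stokes$S0 > 0)
  aolp[bad] <- NA_real_
  dolp[bad] <- NA_real_
  structure(list(aolp_deg = aolp, dolp = dolp), class = "polarization_maps")
}
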