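#' Micropolarizer mosaic layout
#'
#' The 2 x 2 tile of analyzer transmission-axis angles printed on the
#' sensor, anchored at pixel `(0, 0)` (top-left). The default is the
#' common industrial convention with 90 degrees at the even-row/even-column
#' position:
#' \preformatted{  [ 90  45 ]
#'   [ 135  0 ]}
#' Angles of -45 and 135 degrees denote the same analyzer and are
#' normalized to 135.
#'
#' @param layout A 2 x 2 numeric matrix; must be a permutation of
#'   `c(0, 45, 90, 135)` after normalizing -45 to 135.
#' @param extinction_ratio Analyzer extinction ratio; `Inf` (default) is an
#'   ideal polarizer, a finite value mixes in `1/extinction_ratio` of the
#'   orthogonal channel.
#' @return An object of class `mosaic_layout`.
#' @export
mosaic_layout <- function(layout = matrix(c(90, 135, 45, 0), 2, 2),
                          extinction_ratio = Inf) {
  layout <- matrix(as.numeric(layout), 2, 2)
  layout[layout == -45] <- 135
  if (!setequal(as.vector(layout), c(0, 45, 90, 135)) ||
      anyDuplicated(as.vector(layout)))
    stop("layout must be a permutation of the analyzer angles 0, 45, 90, -45")
  if (!(is.numeric(extinction_ratio) && extinction_ratio > 1))
    stop("extinction_ratio must be > 1 (Inf for ideal analyzers)")
  structure(list(layout = layout, extinction_ratio = extinction_ratio),
            class = "mosaic_layout")
}

#' @export
print.mosaic_layout <- function(x, ...) {
  cat("Micropolarizer mosaic (anchored at pixel (0,0)):\n")
  print(x$layout)
  cat(sprintf("  extinction ratio: %s\n", format(x$extinction_ratio)))
  invisible(x)
}

# Full-frame map of analyzer angles for a frame of size ny x nx.
mosaic_angle_map <- function(mosaic, ny, nx) {
  r <- (seq_len(ny) - 1) %% 2
  c <- (seq_len(nx) - 1) %% 2
  matrix(mosaic$layout[cbind(rep(r + 1, times = nx), rep(c + 1, each = ny))],
         ny, nx)
}

#' Sample four analyzer channels onto the mosaic sensor
#'
#' Produces the raw polarization-camera frame: each pixel records the
#' channel whose analyzer angle occupies its mosaic position. With a finite
#' extinction ratio `ER` the orthogonal channel leaks in with weight
#' `1/ER` (values scaled by `ER/(ER + 1)` so that an unpolarized input is
#' unchanged in total).
#'
#' @param channels A `dipole_channels` list or any list with co-registered
#'   matrices `I0`, `I45`, `I90`, `I135` in photons per pixel.
#' @param mosaic A [mosaic_layout()].
#' @return A matrix (photons per pixel) of the same size as the channels.
#' @export
apply_mosaic <- function(channels, mosaic = mosaic_layout()) {
  stopifnot(inherits(mosaic, "mosaic_layout"))
  need <- c("I0", "I45", "I90", "I135")
  if (!all(need %in% names(channels)))
    stop("channels must contain matrices I0, I45, I90, I135")
  dims <- dim(channels$I0)
  ny <- dims[1]; nx <- dims[2]
  ang <- mosaic_angle_map(mosaic, ny, nx)
  er <- mosaic$extinction_ratio
  frame <- matrix(0, ny, nx)
  for (eta in c(0, 45, 90, 135)) {
    par <- channels[[paste0("I", eta)]]
    sel <- ang == eta
    if (is.finite(er)) {
      orth <- channels[[paste0("I", (eta + 90) %% 180)]]
      frame[sel] <- (er * par[sel] + orth[sel]) / (er + 1)
    } else {
      frame[sel] <- par[sel]
    }
  }
  frame
}
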