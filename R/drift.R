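#' Fiducial-based lateral drift correction
#'
#' Estimates per-frame lateral drift as the (smoothed) mean displacement of
#' fiducial markers from their first-frame positions and subtracts it from
#' every localization. Frames where no fiducial was localized are filled by
#' linear interpolation of the drift trace.
#'
#' @param table Localization data.frame with columns `frame`, `x_nm`,
#'   `y_nm`.
#' @param fiducial_tracks data.frame with columns `frame`, `id`, `x_nm`,
#'   `y_nm`: repeated localizations of one or more fiducial beads. Each
#'   fiducial should be present in most frames (>= 80 percent recommended).
#'   `NULL` or zero rows applies the identity with a warning.
#' @param smooth_window Odd running-median window (frames) applied to the
#'   raw drift trace; `1` disables smoothing.
#' @return The corrected table, with the drift trace (data.frame `frame`,
#'   `dx_nm`, `dy_nm`) attached as attribute `drift`.
#' @export
drift_correct <- function(table, fiducial_tracks, smooth_window = 11) {
  frames <- sort(unique(table$frame))
  if (is.null(fiducial_tracks) || nrow(fiducial_tracks) == 0) {
    warning("no fiducials supplied; drift correction is the identity")
    drift <- data.frame(frame = frames, dx_nm = 0, dy_nm = 0)
    attr(table, "drift") <- drift
    return(table)
  }
  stopifnot(all(c("frame", "id", "x_nm", "y_nm") %in% names(fiducial_tracks)))
  disp <- do.call(rbind, lapply(split(fiducial_tracks, fiducial_tracks$id),
    function(tr) {
      tr <- tr[order(tr$frame), ]
      data.frame(frame = tr$frame,
                 dx = tr$x_nm - tr$x_nm[1],
                 dy = tr$y_nm - tr$y_nm[1])
    }))
  agg <- stats::aggregate(cbind(dx, dy) ~ frame, disp, mean)
  all_frames <- seq(min(c(frames, agg$frame)), max(c(frames, agg$frame)))
  dx <- stats::approx(agg$frame, agg$dx, xout = all_frames, rule = 2)$y
  dy <- stats::approx(agg$frame, agg$dy, xout = all_frames, rule = 2)$y
  if (smooth_window > 1 && length(dx) > smooth_window) {
    w <- smooth_window + (1 - smooth_window %% 2)
    dx <- stats::runmed(dx, w, endrule = "median")
    dy <- stats::runmed(dy, w, endrule = "median")
  }
  drift <- data.frame(frame = all_frames, dx_nm = as.numeric(dx),
                      dy_nm = as.numeric(dy))
  idx <- match(table$frame, drift$frame)
  table$x_nm <- table$x_nm - drift$dx_nm[idx]
  table$y_nm <- table$y_nm - drift$dy_nm[idx]
  attr(table, "drift") <- drift
  table
}
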