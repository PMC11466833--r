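#' Quality filters for localization tables
#'
#' Default thresholds follow common practice for intensity-only
#' polarization-camera data: at least 500 detected photons for every
#' localization, and `avgDoLP > 0.4` when in-plane-angle-coded output is
#' rendered (molecules below it are too rotationally free for a meaningful
#' in-plane angle).
#'
#' @param min_photons Minimum detected photons (inclusive); `NULL` disables.
#' @param min_avgdolp Minimum rotational-mobility proxy (exclusive);
#'   `NULL` disables.
#' @param max_fit_residual Maximum relative fit residual; `NULL` disables.
#' @return An object of class `filter_settings`.
#' @export
filter_settings <- function(min_photons = 500, min_avgdolp = 0.4,
                            max_fit_residual = NULL) {
  structure(list(min_photons = min_photons, min_avgdolp = min_avgdolp,
                 max_fit_residual = max_fit_residual),
            class = "filter_settings")
}

#' Filter a localization table
#'
#' Keeps rows that satisfy every enabled threshold: photons at least
#' `min_photons` (inclusive, "at least N photons"), `avgdolp` strictly
#' above `min_avgdolp`, and `residual` at most `max_fit_residual`. The
#' numbers of rows in and out are attached as attribute `log`.
#'
#' @param table Localization data.frame.
#' @param settings A [filter_settings()].
#' @return The filtered data.frame with a `log` attribute
#'   `c(n_in, n_out)`.
#' @export
filter_localizations <- function(table, settings = filter_settings()) {
  stopifnot(inherits(settings, "filter_settings"))
  keep <- rep(TRUE, nrow(table))
  if (!is.null(settings$min_photons))
    keep <- keep & table$photons >= settings$min_photons
  if (!is.null(settings$min_avgdolp))
    keep <- keep & table$avgdolp > settings$min_avgdolp
  if (!is.null(settings$max_fit_residual) && "residual" %in% names(table))
    keep <- keep & (is.na(table$residual) |
                      table$residual <= settings$max_fit_residual)
  out <- table[which(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log") <- c(n_in = nrow(table), n_out = nrow(out))
  out
}
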