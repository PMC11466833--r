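#' Link repeated localizations of static emitters into groups
#'
#' Deterministic nearest-neighbour linking for benchmark data where the
#' same molecules are imaged over many frames: localizations are processed
#' in frame order and attached to the nearest existing group whose running
#' mean position lies within `radius_nm` (ties broken by group creation
#' order); otherwise they found a new group.
#'
#' @param table Localization data.frame with `frame`, `x_nm`, `y_nm`.
#' @param radius_nm Grouping radius, nanometres. `NULL` uses 3 times a
#'   median-based precision estimate (median absolute frame-to-frame step),
#'   with a floor of 50 nm.
#' @return The table with an added integer `group` column.
#' @export
link_localizations <- function(table, radius_nm = NULL) {
  tab <- table[order(table$frame), ]
  if (is.null(radius_nm)) {
    d <- sqrt(diff(tab$x_nm)^2 + diff(tab$y_nm)^2)
    radius_nm <- max(50, 3 * stats::median(d[d < 500], na.rm = TRUE))
    if (!is.finite(radius_nm)) radius_nm <- 100
  }
  gx <- numeric(0); gy <- numeric(0); gn <- integer(0)
  grp <- integer(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (length(gx)) {
      d2 <- (gx / gn - tab$x_nm[i])^2 + (gy / gn - tab$y_nm[i])^2
      j <- which.min(d2)
      if (d2[j] <= radius_nm^2) {
        grp[i] <- j
        gx[j] <- gx[j] + tab$x_nm[i]
        gy[j] <- gy[j] + tab$y_nm[i]
        gn[j] <- gn[j] + 1L
        next
      }
    }
    gx <- c(gx, tab$x_nm[i]); gy <- c(gy, tab$y_nm[i]); gn <- c(gn, 1L)
    grp[i] <- length(gx)
  }
  tab$group <- grp
  tab
}

#' Precision curve from repeated measurements of static emitters
#'
#' Groups repeated localizations (see [link_localizations()]), computes per
#' group the standard deviation of `x`, `y` and the circular standard
#' deviation of the in-plane angle, restricts each group to its first
#' `max_repeats` measurements and discards groups with fewer than
#' `min_repeats`, bins groups by their mean photon count, and fits a power
#' law `sigma = a * N^b` to the binned data by least squares on the log
#' scale.
#'
#' @param table Localization data.frame with `frame`, `x_nm`, `y_nm`,
#'   `photons` and (for the angle curve) `phi_deg`.
#' @param radius_nm Grouping radius passed to [link_localizations()].
#' @param breaks Photon-bin breaks; default covers 100 to 10000 photons in
#'   8 logarithmic bins.
#' @param min_repeats,max_repeats Repeat-count window per group.
#' @return A list of class `precision_curve`: `bins` (data.frame with bin
#'   centre `photons`, `sigma_x_nm`, `sigma_y_nm`, `sigma_xy_nm`,
#'   `sigma_phi_deg`, `n_groups`) and `power_law` (data.frame per
#'   quantity: amplitude, exponent). Errors if no group has enough
#'   repeats (e.g. single-frame data).
#' @export
precision_from_repeats <- function(table, radius_nm = NULL, breaks = NULL,
                                   min_repeats = 12, max_repeats = 40) {
  linked <- link_localizations(table, radius_nm)
  per <- lapply(split(linked, linked$group), function(g) {
    g <- g[order(g$frame), ]
    if (nrow(g) > max_repeats) g <- g[seq_len(max_repeats), ]
    if (nrow(g) < min_repeats) return(NULL)
    data.frame(photons = mean(g$photons),
               sigma_x_nm = stats::sd(g$x_nm),
               sigma_y_nm = stats::sd(g$y_nm),
               sigma_phi_deg = if ("phi_deg" %in% names(g))
                 phi_sd(g$phi_deg) else NA_real_,
               n = nrow(g))
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0)
    stop("no emitter was measured at least ", min_repeats,
         " times; repeated imaging of static emitters is required")
  if (is.null(breaks)) breaks <- 10^seq(2, 4, length.out = 9)
  bin <- cut(per$photons, breaks)
  agg <- lapply(split(per, bin), function(b) {
    if (nrow(b) == 0) return(NULL)
    data.frame(photons = mean(b$photons),
               sigma_x_nm = mean(b$sigma_x_nm),
               sigma_y_nm = mean(b$sigma_y_nm),
               sigma_xy_nm = mean(c(b$sigma_x_nm, b$sigma_y_nm)),
               sigma_phi_deg = mean(b$sigma_phi_deg),
               n_groups = nrow(b))
  })
  bins <- do.call(rbind, agg)
  rownames(bins) <- NULL
  fit_power <- function(x, y) {
    ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
    if (sum(ok) < 2) return(c(amplitude = NA_real_, exponent = NA_real_))
    co <- stats::coef(stats::lm(log(y[ok]) ~ log(x[ok])))
    c(amplitude = exp(unname(co[1])), exponent = unname(co[2]))
  }
  pl <- rbind(xy = fit_power(bins$photons, bins$sigma_xy_nm),
              phi = fit_power(bins$photons, bins$sigma_phi_deg))
  res <- list(bins = bins,
              power_law = data.frame(quantity = rownames(pl), pl,
                                     row.names = NULL),
              per_group = per)
  class(res) <- "precision_curve"
  res
}

#' @export
print.precision_curve <- function(x, ...) {
  cat("Precision from repeated measurements:\n")
  print(x$bins, digits = 3)
  cat("Power-law fits (sigma = a * N^b):\n")
  print(x$power_law, digits = 3)
  invisible(x)
}
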