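#' Read a multi-page grayscale TIFF stack
#'
#' @param path TIFF file path.
#' @return Array `(ny, nx, n_frames)` of integer pixel values, with
#'   attribute `bit_depth`. RGB input is rejected.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) > 2)
    stop("RGB/multichannel TIFF input is not supported; raw frames must be grayscale")
  bits <- attr(pages[[1]], "bits.per.sample")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  stack <- array(0, dim = c(ny, nx, length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- pages[[f]]
  attr(stack, "bit_depth") <- if (is.null(bits)) NA_integer_ else bits
  stack
}

#' Write a stack as a 16-bit multi-page grayscale TIFF
#'
#' @param stack Matrix or array `(ny, nx, n_frames)` of non-negative
#'   integer-valued data below 2^16.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (length(dim(stack)) == 2) stack <- array(stack, dim = c(dim(stack), 1))
  mx <- 2^16 - 1
  if (any(stack < 0) || any(stack > mx))
    stop("stack values must lie in [0, 65535] for 16-bit output")
  frames <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f] / mx)
  tiff::writeTIFF(frames, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Write Stokes maps as a 32-bit float TIFF
#'
#' One page per parameter, in the order `S0`, `S1`, `S2`.
#'
#' @param stokes A `stokes_maps` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stokes <- function(stokes, path) {
  tiff::writeTIFF(list(stokes$S0, stokes$S1, stokes$S2), path,
                  bits.per.sample = 32, compression = "none")
  invisible(path)
}

loc_columns <- c("frame", "x_nm", "y_nm", "photons", "phi_deg", "theta_deg",
                 "theta_valid", "netdolp", "avgdolp", "fit_method", "residual")

#' Write a localization table to CSV
#'
#' Fixed column order
#' `frame,x_nm,y_nm,photons,phi_deg,theta_deg,theta_valid,netdolp,avgdolp,fit_method,residual`;
#' units are nanometres and degrees throughout. A small `<path>.meta.json`
#' sidecar records the software version so outputs stay attributable.
#'
#' @param table Localization data.frame.
#' @param path Output path.
#' @param sidecar Write the metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, sidecar = TRUE) {
  miss <- setdiff(loc_columns, names(table))
  for (m in miss) table[[m]] <- NA
  utils::write.csv(table[, loc_columns], path, row.names = FALSE)
  if (sidecar) write_sidecar(path)
  invisible(path)
}

write_sidecar <- function(path) {
  ver <- as.character(utils::packageVersion("stokescam"))
  writeLines(sprintf('{"software": "stokescam %s"}', ver),
             paste0(path, ".meta.json"))
}

#' Read a localization table written by [write_localizations()]
#'
#' @param path CSV path.
#' @return Localization data.frame.
#' @export
read_localizations <- function(path) {
  utils::read.csv(path)
}

#' Read a structured run configuration
#'
#' YAML file with optional blocks `optics`, `mosaic`, `noise`, `detect`,
#' `filter` and a top-level `seed`; omitted fields fall back to the package
#' defaults of [optical_config()], [mosaic_layout()],
#' [camera_noise_model()] and [filter_settings()].
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with the resolved component
#'   objects and the raw parsed list as attribute `raw`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(fn, block) do.call(fn, if (is.null(block)) list() else block)
  mos <- raw$mosaic
  if (!is.null(mos$layout)) mos$layout <- matrix(unlist(mos$layout), 2, 2,
                                                 byrow = TRUE)
  cfg <- list(optics = build(optical_config, raw$optics),
              mosaic = build(mosaic_layout, mos),
              noise = build(camera_noise_model, raw$noise),
              filter = build(filter_settings, raw$filter),
              detect = if (is.null(raw$detect)) list() else raw$detect,
              seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
  attr(cfg, "raw") <- raw
  class(cfg) <- "run_config"
  cfg
}
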