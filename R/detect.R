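# Separable Gaussian blur with reflected edges.
gaussian_blur <- function(mat, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad <- function(v) c(v[half:1], v, v[length(v) + 1 - seq_len(half)])
  conv1 <- function(v) stats::convolve(pad(v), rev(k), type = "filter")
  m <- apply(mat, 2, conv1)
  t(apply(t(m), 2, conv1))
}

#' Detect single-molecule candidates on an intensity map
#'
#' Band-passes the incident-intensity map `S0` with a difference of
#' Gaussians at the dipole-spread-function scale, then keeps local maxima
#' exceeding `k` times a robust noise scale (median absolute deviation of
#' the filtered image). Candidates closer than `min_distance_px` are merged
#' into the brighter one, so a single emitter never yields duplicate
#' detections within one fitting region.
#'
#' @param s0 Intensity map in photon-linear units (matrix).
#' @param sigma_px DSF Gaussian scale in pixels (default 2, appropriate for
#'   a diffraction-limited spot sampled near the optimal pitch).
#' @param k Detection threshold in robust noise sigmas.
#' @param min_distance_px Minimum separation between candidates.
#' @return A data.frame with 0-based pixel positions `row`, `col` and the
#'   band-passed peak `response`; zero rows when nothing is found.
#' @export
detect_candidates <- function(s0, sigma_px = 2, k = 5, min_distance_px = 9) {
  stopifnot(is.matrix(s0))
  bp <- gaussian_blur(s0, sigma_px) - gaussian_blur(s0, 2 * sigma_px)
  sig <- stats::mad(bp)
  thr <- k * sig
  ny <- nrow(bp); nx <- ncol(bp)
  # strict local maxima over the 8-neighbourhood, excluding the border
  ok <- matrix(FALSE, ny, nx)
  ri <- 2:(ny - 1); ci <- 2:(nx - 1)
  ctr <- bp[ri, ci]
  ok[ri, ci] <- ctr > thr &
    ctr >= bp[ri - 1, ci] & ctr >= bp[ri + 1, ci] &
    ctr >= bp[ri, ci - 1] & ctr >= bp[ri, ci + 1] &
    ctr >= bp[ri - 1, ci - 1] & ctr >= bp[ri - 1, ci + 1] &
    ctr >= bp[ri + 1, ci - 1] & ctr >= bp[ri + 1, ci + 1]
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(row = integer(), col = integer(), response = numeric()))
  cand <- data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                     response = bp[idx])
  cand <- cand[order(-cand$response), ]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1):nrow(cand)
      d2 <- (cand$row[later] - cand$row[i])^2 + (cand$col[later] - cand$col[i])^2
      keep[later][d2 < min_distance_px^2] <- FALSE
    }
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}
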