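# Shared fixtures and independent oracles for the test suite.

default_optics <- optical_config()          # 1.4 NA oil, x60, 630 nm, water
matched_optics <- optical_config(n_sample = 1.518)
default_pitch <- sample_pitch_nm(default_optics)
default_grid <- image_grid(32, 32, default_pitch)
grid_centre_nm <- function(grid = default_grid) {
  floor((grid$nx - 1) / 2) * grid$pitch_nm
}

rel_rms <- function(a, b, mask = TRUE) {
  sqrt(mean((a - b)[mask]^2)) / sqrt(mean(b[mask]^2))
}

# Independent quadrature oracle for the angular constants: integrates the
# dipole far field through an x-analyzer over the collection cone
# (trapezoid rule on a polar grid), normalized by 4*pi. Solves A, B, C from
# three dipole orientations:
#   I0(z-dipole) = A; I0(x-dipole) = A + B + C; I0(y-dipole) = A + B - C.
quadrature_channel <- function(alpha, mu, n = 400) {
  th <- seq(0, alpha, length.out = n + 1)
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)
  thm <- matrix(th, n + 1, 2 * n + 1)
  phm <- matrix(ph, n + 1, 2 * n + 1, byrow = TRUE)
  ap <- mu[1] * cos(thm) * cos(phm) + mu[2] * cos(thm) * sin(phm) -
    mu[3] * sin(thm)
  as <- -mu[1] * sin(phm) + mu[2] * cos(phm)
  ex <- ap * cos(phm) - as * sin(phm)
  f <- ex^2 * sin(thm)
  simpson <- function(m) {           # m odd number of nodes
    w <- rep(c(2, 4), length.out = m); w[c(1, m)] <- 1
    w / 3
  }
  wt <- simpson(n + 1)
  wp <- simpson(2 * n + 1)
  sum(outer(wt, wp) * f) * (alpha / n) * (pi / n)
}

quadrature_constants <- function(alpha, n = 400) {
  iz <- quadrature_channel(alpha, c(0, 0, 1), n) / (4 * pi)
  ix <- quadrature_channel(alpha, c(1, 0, 0), n) / (4 * pi)
  iy <- quadrature_channel(alpha, c(0, 1, 0), n) / (4 * pi)
  list(A = iz, B = (ix + iy) / 2 - iz, C = (ix - iy) / 2)
}

# Seeded uniform draws inside a cone of half angle cone_deg around the
# axis (phi0, theta0), returned as (phi, theta) in degrees.
with_seed_draw_cone <- function(seed, cone_deg, theta0_deg, n,
                                phi0_deg = 30, stratified = FALSE) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cmin <- cos(cone_deg * pi / 180)
  if (stratified) {
    # jittered-grid stratification in (cos beta, azimuth): one uniform
    # draw per cell of a sqrt(n) x sqrt(n) grid
    m <- round(sqrt(n))
    stopifnot(m * m == n)
    i <- rep(seq_len(m), each = m); j <- rep(seq_len(m), times = m)
    cb <- cmin + (1 - cmin) * (i - stats::runif(n)) / m
    az <- 2 * pi * (j - stats::runif(n)) / m
  } else {
    cb <- stats::runif(n, cmin, 1)
    az <- stats::runif(n, 0, 2 * pi)
  }
  sb <- sqrt(1 - cb^2)
  dirs <- cbind(sb * cos(az), sb * sin(az), cb)
  p0 <- phi0_deg * pi / 180; t0 <- theta0_deg * pi / 180
  rz <- matrix(c(cos(p0), sin(p0), 0, -sin(p0), cos(p0), 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(t0), 0, -sin(t0), 0, 1, 0, sin(t0), 0, cos(t0)), 3, 3)
  dirs <- dirs %*% t(rz %*% ry)
  flip <- dirs[, 3] < 0
  dirs[flip, ] <- -dirs[flip, ]
  theta <- pmin(acos(pmin(dirs[, 3], 1)) * 180 / pi, 90)
  phi <- atan2(dirs[, 2], dirs[, 1]) * 180 / pi
  phi[phi <= -90] <- phi[phi <= -90] + 180
  phi[phi > 90] <- phi[phi > 90] - 180
  list(phi = phi, theta = theta)
}

# One noiseless frame of a single emitter on the default grid, cached per
# test session.
.noiseless_cache <- new.env()
noiseless_frame <- function(phi_deg = 0, theta_deg = 90, cone_deg = 0,
                            photons = 1000, optics = default_optics,
                            grid = default_grid) {
  key <- paste(phi_deg, theta_deg, cone_deg, photons,
               optics$n_sample, grid$nx, sep = "_")
  if (is.null(.noiseless_cache[[key]])) {
    ctr <- grid_centre_nm(grid)
    em <- dipole_emitter(ctr, ctr, phi_deg = phi_deg, theta_deg = theta_deg,
                         cone_deg = cone_deg, photons = photons)
    ch <- simulate_dipole_channels(em, optics, grid)
    .noiseless_cache[[key]] <- list(channels = ch,
                                    frame = apply_mosaic(ch),
                                    emitter = em)
  }
  .noiseless_cache[[key]]
}

# Repeated noisy measurements of one static emitter through the pipeline.
pipeline_repeats <- function(frame0, n, noise = camera_noise_model(),
                             optics = default_optics, seed_base = 0, ...) {
  tabs <- list()
  for (s in seq_len(n)) {
    nf <- add_camera_noise(frame0, noise, seed = seed_base + s)
    r <- pipeline_localize(array(nf, dim = c(dim(frame0), 1)), optics,
                           noise = noise, ...)
    if (nrow(r$table) >= 1) {
      t1 <- r$table[which.max(r$table$photons), ]
      t1$frame <- s
      tabs[[length(tabs) + 1]] <- t1
    }
  }
  do.call(rbind, tabs)
}
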