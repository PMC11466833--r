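test_that("splitting a 4x4 frame partitions all pixels by analyzer", {
  frame <- matrix(1:16, 4, 4)
  sp <- split_channels(frame)
  vals <- sort(unname(unlist(sp[c("I0", "I45", "I90", "I135")])))
  expect_equal(vals, 1:16)
  for (nm in c("I0", "I45", "I90", "I135"))
    expect_equal(dim(sp[[nm]]), c(2L, 2L))
})

test_that("split then re-interleave is the identity", {
  frame <- matrix(rnorm(12 * 16), 12, 16)
  expect_equal(interleave_channels(split_channels(frame)), frame)
})

test_that("a constant frame splits into constant channels", {
  sp <- split_channels(matrix(7, 6, 6))
  for (nm in c("I0", "I45", "I90", "I135"))
    expect_true(all(sp[[nm]] == 7))
})

test_that("odd dimensions are trimmed with a warning", {
  expect_warning(sp <- split_channels(matrix(0, 5, 6)), "odd")
  expect_equal(sp$full_dim, c(4, 6))
})

test_that("interpolation is exact at measured sites and for constants", {
  sp <- split_channels(matrix(3.5, 8, 8))
  up <- interpolate_channels(sp)
  for (nm in c("I0", "I45", "I90", "I135"))
    expect_equal(up[[nm]], matrix(3.5, 8, 8), tolerance = 1e-12)
  fr <- noiseless_frame(phi_deg = 20, theta_deg = 85)
  sp <- split_channels(fr$frame)
  up <- interpolate_channels(sp)
  for (nm in c("I0", "I45", "I90", "I135")) {
    off <- sp$offsets[[nm]]
    rows <- seq(off["row"] + 1, 32, by = 2)
    cols <- seq(off["col"] + 1, 32, by = 2)
    expect_lt(max(abs(up[[nm]][rows, cols] - sp[[nm]])), 1e-9)
  }
})

test_that("cubic-spline recovery beats nearest-neighbour and bilinear", {
  fr <- noiseless_frame(phi_deg = 30, theta_deg = 90, photons = 500)
  truth <- fr$channels
  sp <- split_channels(fr$frame)
  sup <- with(truth, (I0 + I45 + I90 + I135) / 2) > 0.01 * max(truth$I0)
  err_of <- function(up) mean(vapply(c("I0", "I45", "I90", "I135"),
    function(nm) rel_rms(up[[nm]], truth[[nm]], sup), numeric(1)))
  # comparison interpolators on the same split input
  up_nn <- lapply(sp[c("I0", "I45", "I90", "I135")], function(ch)
    ch[rep(seq_len(16), each = 2), rep(seq_len(16), each = 2)])
  lin1 <- function(v, at_in, at_out)
    stats::approx(at_in, v, xout = at_out, rule = 2)$y
  up_bl <- lapply(c("I0", "I45", "I90", "I135"), function(nm) {
    off <- sp$offsets[[nm]]
    m <- t(apply(sp[[nm]], 1, lin1,
                 at_in = seq(off["col"], by = 2, length.out = 16),
                 at_out = 0:31))
    apply(m, 2, lin1, at_in = seq(off["row"], by = 2, length.out = 16),
          at_out = 0:31)
  })
  names(up_bl) <- c("I0", "I45", "I90", "I135")
  err_spline <- err_of(interpolate_channels(sp))
  expect_lt(err_spline, err_of(up_nn))
  expect_lt(err_spline, err_of(up_bl))
})

test_that("Stokes parameters follow their defining arithmetic", {
  mk <- function(v) matrix(v, 2, 2)
  st <- stokes_from_channels(mk(3), mk(2), mk(1), mk(2))
  expect_equal(st$S0, mk(4)); expect_equal(st$S1, mk(2)); expect_equal(st$S2, mk(0))
  st <- stokes_from_channels(mk(1), mk(1), mk(1), mk(1))
  expect_equal(st$S0, mk(2)); expect_equal(st$S1, mk(0)); expect_equal(st$S2, mk(0))
  st <- stokes_from_channels(mk(1), mk(0.5), mk(0), mk(0.5))
  expect_equal(st$S0, mk(1)); expect_equal(st$S1, mk(1))
  expect_equal(polarization_maps(st)$dolp, mk(1))
  expect_error(stokes_from_channels(mk(1), mk(1), mk(1), matrix(1, 3, 3)),
               "dimensions")
})

test_that("Fourier demodulation is exact for uniform polarized fields", {
  ch <- list(I0 = matrix(1.5, 16, 16), I45 = matrix(1.25, 16, 16),
             I90 = matrix(0.5, 16, 16), I135 = matrix(0.75, 16, 16))
  # (S0, S1, S2) = (2, 1, 0.5)
  frame <- apply_mosaic(ch)
  st <- demosaic_fourier(frame)
  expect_lt(max(abs(st$S0 - 2)), 1e-6)
  expect_lt(max(abs(st$S1 - 1)), 1e-6)
  expect_lt(max(abs(st$S2 - 0.5)), 1e-6)
})

test_that("Fourier demodulation works for any mosaic tile order", {
  ch <- list(I0 = matrix(1.5, 16, 16), I45 = matrix(1.25, 16, 16),
             I90 = matrix(0.5, 16, 16), I135 = matrix(0.75, 16, 16))
  for (perm in list(c(0, 45, 90, 135), c(45, 0, 135, 90), c(0, 90, 45, 135))) {
    mos <- mosaic_layout(matrix(perm, 2, 2))
    st <- demosaic_fourier(apply_mosaic(ch, mos), mos)
    expect_lt(max(abs(st$S0 - 2)), 1e-6)
    expect_lt(max(abs(st$S1 - 1)), 1e-6)
    expect_lt(max(abs(st$S2 - 0.5)), 1e-6)
  }
})

test_that("demosaicked Stokes maps match the simulator ground truth", {
  fr <- noiseless_frame(phi_deg = 30, theta_deg = 90, photons = 1000)
  truth <- stokes_from_channels(fr$channels$I0, fr$channels$I45,
                                fr$channels$I90, fr$channels$I135)
  sup <- truth$S0 > 0.01 * max(truth$S0)
  st <- demosaic_fourier(fr$frame)
  for (nm in c("S0", "S1", "S2"))
    expect_lt(rel_rms(st[[nm]], truth[[nm]], sup), 0.02)
})

test_that("white-noise input keeps shape and a non-negative baseband", {
  set.seed(2)
  frame <- matrix(abs(rnorm(32 * 32, 100, 10)), 32, 32)
  st <- demosaic_fourier(frame)
  expect_equal(dim(st$S0), c(32L, 32L))
  expect_true(all(st$S0 > 0))
})

test_that("polarization maps implement the half-angle conventions", {
  mk <- function(v) matrix(v, 1, 1)
  st <- function(a, b, c) list(S0 = mk(a), S1 = mk(b), S2 = mk(c))
  expect_equal(polarization_maps(st(1, 1, 0))$aolp_deg[1], 0)
  expect_equal(polarization_maps(st(1, 0, 1))$aolp_deg[1], 45)
  expect_equal(polarization_maps(st(1, -1, 0))$aolp_deg[1], 90) # tie-break
  m <- polarization_maps(st(2, 0.6, 0.8))
  expect_equal(m$aolp_deg[1], 26.565, tolerance = 1e-4)
  expect_equal(m$dolp[1], 0.5)
  masked <- polarization_maps(st(0, 1, 0))
  expect_true(is.na(masked$aolp_deg[1]))
})

test_that("AoLP and DoLP are invariant to global intensity scaling", {
  fr <- noiseless_frame(phi_deg = -50, theta_deg = 80)
  st1 <- demosaic_fourier(fr$frame)
  st2 <- demosaic_fourier(fr$frame * 7.3)
  m1 <- polarization_maps(st1); m2 <- polarization_maps(st2)
  sup <- st1$S0 > 0.05 * max(st1$S0)
  expect_lt(max(abs(m1$dolp[sup] - m2$dolp[sup])), 1e-9)
  expect_lt(max(abs(phi_diff(m1$aolp_deg[sup], m2$aolp_deg[sup]))), 1e-9)
})

test_that("noiseless Stokes maps are physical: sqrt(S1^2+S2^2) <= S0", {
  for (case in list(c(0, 90, 0), c(40, 60, 0), c(0, 90, 90))) {
    fr <- noiseless_frame(phi_deg = case[1], theta_deg = case[2],
                          cone_deg = case[3])
    st <- stokes_from_channels(fr$channels$I0, fr$channels$I45,
                               fr$channels$I90, fr$channels$I135)
    expect_true(all(sqrt(st$S1^2 + st$S2^2) <= st$S0 * (1 + 1e-9)))
  }
})

test_that("rotating the dipole rotates the recovered AoLP equally", {
  recovered_phi <- function(phi) {
    fr <- noiseless_frame(phi_deg = phi, theta_deg = 90)
    st <- demosaic_fourier(fr$frame)
    i <- which(st$S0 == max(st$S0), arr.ind = TRUE)
    0.5 * atan2(st$S2[i], st$S1[i]) * 180 / pi
  }
  base <- recovered_phi(10)
  for (d in c(25, 60, 75)) {
    expect_lt(abs(phi_diff(recovered_phi(10 + d) - base, d)), 0.5)
  }
})

test_that("temporal-median background correction removes static background", {
  set.seed(9)
  ny <- 8; nx <- 8; nt <- 31
  bg <- matrix(runif(ny * nx, 50, 150), ny, nx)
  stack <- array(rep(bg, nt), dim = c(ny, nx, nt))
  # transient spikes on a few frames
  stack[4, 4, 15] <- stack[4, 4, 15] + 500
  stack[2, 6, 20] <- stack[2, 6, 20] + 300
  out <- background_correct(stack, window = 11)
  expect_lt(max(abs(out[, , 5])), 1e-9)           # static level removed
  expect_gt(out[4, 4, 15], 499)                   # spikes preserved
  expect_gt(out[2, 6, 20], 299)
  # constant stack -> zero everywhere
  zero <- background_correct(array(3, dim = c(4, 4, 21)), window = 7)
  expect_true(all(abs(zero) < 1e-12))
})

test_that("short stacks fall back to a global median with a warning", {
  stack <- array(5, dim = c(4, 4, 5))
  expect_warning(out <- background_correct(stack, window = 101), "global")
  expect_true(all(abs(out) < 1e-12))
})

test_that("the HSV composite follows the hue/saturation/value mapping", {
  mk <- function(v) matrix(v, 2, 2)
  grey <- hsv_composite(list(S0 = mk(1), S1 = mk(0), S2 = mk(0)))
  expect_equal(grey[, , 1], grey[, , 2])
  expect_equal(grey[, , 2], grey[, , 3])          # DoLP 0 -> greyscale
  dark <- hsv_composite(list(S0 = mk(0), S1 = mk(0), S2 = mk(0)))
  expect_true(all(dark == 0))                     # S0 = 0 -> black
  # AoLP 0 and 90 are opposite hues on the 180-degree wheel
  st <- list(S0 = matrix(1, 1, 2), S1 = matrix(c(1, -1), 1, 2),
             S2 = matrix(0, 1, 2))
  comp <- hsv_composite(st)
  rgb1 <- comp[1, 1, ]; rgb2 <- comp[1, 2, ]
  expect_gt(sum(abs(rgb1 - rgb2)), 1)             # well separated colours
})
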