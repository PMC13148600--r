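test_that("transfer function reduces to known closed forms", {
  g <- test_grid(32L)
  expect_equal(asm_transfer(g, 0), matrix(1 + 0i, 32, 32))
  d <- 5e-6
  k <- asm_transfer(g, d)
  # DC component is the plane-wave carrier
  expect_equal(k[1, 1], exp(2i * pi * g$n_med * d / g$wavelength))
  # in-medium wavelength shortens the carrier period
  g2 <- wavefield_grid(32, dx = 1e-8, wavelength = lambda_xray, n_med = 1.5)
  expect_equal(asm_transfer(g2, d)[1, 1],
               exp(2i * pi * 1.5 * d / lambda_xray))
  expect_error(wavefield_grid(32, dx = -1e-9, wavelength = 1e-10), "positive")
  expect_error(wavefield_grid(32, dx = 1e-9, wavelength = 0), "positive")
})

test_that("evanescent components are zeroed", {
  # long wavelength relative to the pixel pitch puts the grid corners
  # beyond the propagating circle
  g <- wavefield_grid(16, dx = 1e-6, wavelength = 1.5e-6)
  k <- asm_transfer(g, 1e-5)
  fx <- holofield:::fft_freq(16, 1e-6)
  rad <- 1 - outer((1.5e-6 * fx)^2, rep(1, 16)) -
    outer(rep(1, 16), (1.5e-6 * fx)^2)
  expect_true(all(k[rad < 0] == 0))
  expect_true(all(abs(Mod(k[rad >= 0]) - 1) < 1e-12))
})

test_that("propagation matches a brute-force DFT evaluation", {
  # independent oracle: explicit DFT matrices instead of the FFT
  L <- 16L
  g <- test_grid(L)
  set.seed(4)
  U <- matrix(complex(real = rnorm(L^2), imaginary = rnorm(L^2)), L, L)
  g$field <- U
  d <- 3e-6
  got <- propagate(g, d)$field
  j <- 0:(L - 1)
  F <- exp(-2i * pi * outer(j, j) / L)
  K <- asm_transfer(g, d)
  ref <- (Conj(F) %*% ((F %*% U %*% F) * K) %*% Conj(F)) / L^2
  expect_lt(max(Mod(got - ref)), 1e-10)
})

test_that("Gaussian beam diffracts at the analytic rate", {
  # closed-form oracle: beam waist w0 grows to w0*sqrt(2) after one
  # Rayleigh range
  L <- 32L
  dx <- 10e-9
  w0 <- 5 * dx
  g <- wavefield_grid(L, dx = dx, wavelength = lambda_xray)
  x <- (seq_len(L) - (L / 2 + 1)) * dx
  r2 <- outer(x^2, rep(1, L)) + outer(rep(1, L), x^2)
  g$field <- exp(-r2 / w0^2) + 0i
  zR <- pi * w0^2 / lambda_xray
  I <- Mod(propagate(g, zR)$field)^2
  # beam width from the intensity second moment (w = 2 sigma)
  w_meas <- 2 * sqrt(sum(I * outer(x^2, rep(1, L))) / sum(I))
  expect_lt(abs(w_meas / (w0 * sqrt(2)) - 1), 0.01)
})

test_that("propagation is unitary, invertible and composable", {
  g <- test_grid(32L)
  set.seed(11)
  ph <- matrix(0, 32, 32); ph[12:20, 12:20] <- -0.3
  g$field <- exp(1i * ph)
  p <- propagate(g, 7e-6)
  # power conservation on the (fully propagating) band
  expect_lt(abs(sum(Mod(p$field)^2) / sum(Mod(g$field)^2) - 1), 1e-10)
  # round trip
  back <- propagate(p, -7e-6)
  expect_lt(max(Mod(back$field - g$field)), 1e-10)
  # composition
  two <- propagate(propagate(g, 3e-6), 4e-6)
  expect_lt(max(Mod(two$field - p$field)), 1e-10)
  # uniform field only picks up a global phase
  u <- test_grid(16L)
  pu <- propagate(u, 1e-5)
  expect_lt(max(abs(Mod(pu$field) - 1)), 1e-12)
  expect_lt(max(Mod(pu$field - pu$field[1, 1])), 1e-12)
  # invalid input
  u$field[3, 3] <- NaN + 0i
  expect_error(propagate(u, 1e-6), "NaN")
})

test_that("multi-slice forward model has the correct limits", {
  L <- 32L
  g <- test_grid(L)
  dep <- depth_grid(25e-6, 20e-9, 9L)
  dims <- c(L, L, 9L)
  zero <- array(0, dims)
  # empty volume: unit intensity exactly
  I0 <- multislice_forward(object_volume(zero, zero, phi = -0.3, A = 0.03),
                           dep, g)
  expect_lt(max(abs(I0 - 1)), 1e-12)
  # uniform absorber in one slice: Beer-Lambert
  oA <- zero; oA[, , 5] <- 1
  IA <- multislice_forward(object_volume(zero, oA, phi = 0, A = 0.03), dep, g)
  expect_lt(max(abs(IA - exp(-2 * 0.03))), 1e-12)
  # shape/validation errors
  expect_error(object_volume(zero, zero[, , 1:5], phi = 0, A = 0), "shape")
  expect_error(object_volume(zero, zero, phi = 0, A = -1), "absorbance")
  expect_error(object_volume(zero + 2, zero, phi = 0, A = 0), "0, 1")
})

test_that("a single occupied slice equals the thin-object hologram", {
  L <- 48L
  g <- test_grid(L)
  ref <- render_phantom(disc_phantom(L, r = 8))
  H <- simulate_hologram(ref$phase, ref$absorbance, 25e-6, g)
  dep <- depth_grid(25e-6, 20e-9, 9L)
  dims <- c(L, L, 9L)
  op <- array(0, dims); oa <- array(0, dims)
  occ <- (ref$phase != 0) * 1
  op[, , 5] <- occ; oa[, , 5] <- occ
  I <- multislice_forward(object_volume(op, oa, phi = -0.3, A = 0.03), dep, g)
  expect_lt(max(abs(I - H$intensity) / H$intensity), 1e-8)
})

test_that("lateral object shifts shift the hologram circularly", {
  L <- 32L
  g <- test_grid(L)
  dep <- depth_grid(25e-6, 20e-9, 5L)
  dims <- c(L, L, 5L)
  occ <- matrix(0, L, L); occ[10:14, 12:17] <- 1
  mk <- function(o2d) {
    op <- array(0, dims); op[, , 3] <- o2d
    multislice_forward(object_volume(op, op, phi = -0.2, A = 0.02), dep, g)
  }
  I1 <- mk(occ)
  k <- 5L
  shifted <- occ[c((L - k + 1):L, 1:(L - k)), ]  # circular shift in x
  I2 <- mk(shifted)
  expect_lt(max(abs(I2 - I1[c((L - k + 1):L, 1:(L - k)), ])), 1e-8)
})

test_that("back-propagation refocuses a sharp object at its true depth", {
  L <- 64L
  g <- test_grid(L)
  ref <- render_phantom(disc_phantom(L))
  H <- simulate_hologram(ref$phase, ref$absorbance, 25e-6, g)
  sweep_d <- seq(10e-6, 40e-6, by = 1.5e-6)
  # edge-sharpness as gradient-energy concentration (kurtosis): at focus
  # the gradient collapses onto the object rim, off focus it spreads over
  # defocus fringes
  sharp <- vapply(sweep_d, function(d) {
    I <- Mod(backpropagate_to_object(H, d, g)$field)^2
    gm <- holofield:::sobel_magnitude(I)
    mean(gm^4) / mean(gm^2)^2
  }, numeric(1))
  # edge sharpness peaks within +/- 2 sweep steps of the true depth
  expect_lte(abs(sweep_d[which.max(sharp)] - 25e-6), 2 * 1.5e-6 + 1e-12)
  # trivial case and error path
  u <- backpropagate_to_object(matrix(1, 16, 16), 1e-5, test_grid(16L))
  expect_lt(max(abs(Mod(u$field)^2 - 1)), 1e-10)
  expect_error(backpropagate_to_object(matrix(-1, 16, 16), 1e-5,
                                       test_grid(16L)), "nonnegative")
})

test_that("depth grids implement the centred slice window", {
  dep <- depth_grid(100e-6, 20e-9, 81L)
  expect_equal(dep$n_slices, 81L)
  expect_equal(dep$z1, 100e-6 - 40 * 20e-9)
  expect_equal(dep$zN, 100e-6 + 40 * 20e-9)
  expect_equal(diff(dep$z), rep(20e-9, 80))
  expect_equal(dep$z[dep$i_prime], 100e-6)
  expect_error(depth_grid(100e-9, 20e-9, 81L), "z1 > 0")
  expect_error(depth_grid(1e-4, 2e-8, 80L), "odd")
})
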