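test_that("phantom rendering produces exact reference maps", {
  # empty spec
  empty <- render_phantom(phantom_spec(list(), L = 16, dx = 1e-8,
                                       z_prime = 1e-5))
  expect_true(all(empty$phase == 0) && all(empty$absorbance == 0))
  expect_true(all(empty$masks$background))
  # the three-letter reference phantom carries exactly the stated values
  ref <- render_phantom(default_phantom(128L))
  expect_setequal(unique(as.vector(ref$phase)), c(0, -0.1, -0.2, -0.3))
  expect_setequal(unique(as.vector(ref$absorbance)), c(0, 0.01, 0.02, 0.03))
  expect_named(ref$masks, c("alpha", "beta", "gamma", "background"))
  # object masks are disjoint and complement the background
  tot <- Reduce(`+`, ref$masks[c("alpha", "beta", "gamma")])
  expect_true(all(tot <= 1))
  expect_true(all((tot == 0) == ref$masks$background))
})

test_that("map sums follow the pixel count of the shape", {
  spec <- phantom_spec(
    list(list(shape = shape_disc(32, 32, 20), phase = -0.2,
              absorbance = 0.02, label = "d")),
    L = 64, dx = 1e-8, z_prime = 1e-5)
  ref <- render_phantom(spec)
  n_px <- sum(ref$masks$d)
  expect_equal(sum(ref$phase), -0.2 * n_px)
  expect_equal(sum(ref$absorbance), 0.02 * n_px)
  # direct pixel-count oracle
  px <- expand.grid(x = 1:64, y = 1:64)
  expect_equal(n_px, sum((px$x - 32)^2 + (px$y - 32)^2 <= 400))
})

test_that("overlapping phantom objects are rejected", {
  spec <- phantom_spec(
    list(list(shape = shape_disc(20, 20, 8), phase = -0.1,
              absorbance = 0.01, label = "a"),
         list(shape = shape_disc(24, 20, 8), phase = -0.2,
              absorbance = 0.02, label = "b")),
    L = 48, dx = 1e-8, z_prime = 1e-5)
  expect_error(render_phantom(spec), "overlap")
})

test_that("noise-free holograms obey limiting cases and power balance", {
  g <- test_grid(48L)
  z <- matrix(0, 48, 48)
  expect_equal(simulate_hologram(z, z, 1e-5, g)$intensity,
               matrix(1, 48, 48))
  a <- matrix(0.02, 48, 48)
  expect_lt(max(abs(simulate_hologram(z, a, 1e-5, g)$intensity -
                      exp(-0.04))), 1e-12)
  # free-space propagation conserves the transmitted power deficit
  ref <- render_phantom(default_phantom(64L, z_prime = 25e-6))
  g64 <- test_grid(64L)
  H <- simulate_hologram(ref$phase, ref$absorbance, 25e-6, g64)
  expect_lt(abs(sum(H$intensity - 1) -
                  sum(exp(-2 * ref$absorbance) - 1)) /
              abs(sum(exp(-2 * ref$absorbance) - 1)), 1e-6)
  expect_error(simulate_hologram(z * NaN, z, 1e-5, g), "NaN")
  expect_error(simulate_hologram(z, z, -1, g), "> 0")
})

test_that("shot noise follows the scaled Poisson law", {
  # uniform hologram: expected count is exactly mu at every pixel, and
  # Monte-Carlo moments over 1e5 pixels match within 3 standard errors
  n <- c(400L, 250L)  # 1e5 draws
  H <- hologram(matrix(1, n[1], n[2]))
  mu <- 300
  snl <- apply_shot_noise(H, mu, seed = 2024)
  counts <- snl$intensity * mu
  expect_true(all(counts >= 0))
  expect_lt(max(abs(counts - round(counts))), 1e-6)  # integer up to rescaling
  m <- mean(counts); v <- stats::var(as.vector(counts))
  se_mean <- sqrt(mu / prod(n))
  se_var <- sqrt((2 * mu^2 + mu) / prod(n))  # var of Poisson sample variance
  expect_lt(abs(m - mu), 3 * se_mean)
  expect_lt(abs(v - mu), 3 * se_var)
})

test_that("shot noise scales with the local intensity", {
  # E[H'] = H / Hbar elementwise: check on a two-level hologram
  I <- matrix(0.5, 100, 100); I[, 51:100] <- 1.5
  mu <- 200
  snl <- apply_shot_noise(hologram(I), mu, seed = 9)
  lam_lo <- mu * 0.5 / mean(I); lam_hi <- mu * 1.5 / mean(I)
  m_lo <- mean(snl$intensity[, 1:50] * mu)
  m_hi <- mean(snl$intensity[, 51:100] * mu)
  expect_lt(abs(m_lo - lam_lo), 3 * sqrt(lam_lo / 5000))
  expect_lt(abs(m_hi - lam_hi), 3 * sqrt(lam_hi / 5000))
})

test_that("shot noise is bit-reproducible and validates inputs", {
  H <- hologram(pm_image(3, 32L) + 0.5)
  a <- apply_shot_noise(H, 1000, seed = 7)
  b <- apply_shot_noise(H, 1000, seed = 7)
  expect_identical(a$intensity, b$intensity)
  expect_equal(a$mu, 1000)
  expect_equal(a$seed, 7)
  c1 <- apply_shot_noise(H, 1000, seed = 8)
  expect_false(identical(a$intensity, c1$intensity))
  expect_error(apply_shot_noise(H, 0, seed = 1), "positive")
  expect_error(hologram(matrix(-0.1, 4, 4)), "nonnegative")
})

test_that("noise application does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(apply_shot_noise(hologram(matrix(1, 8, 8)), 100, seed = 55))
  r2 <- runif(1)
  expect_identical(r1, r2)
})
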