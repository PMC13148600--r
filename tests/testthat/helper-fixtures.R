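# Shared fixtures: small grids and deterministic pseudo-random images.

lambda_xray <- xray_wavelength(9.344)

test_grid <- function(L = 32L, dx = 10e-9) {
  wavefield_grid(L, dx = dx, wavelength = lambda_xray)
}

# Park-Miller LCG in exact double arithmetic; reproducible across
# languages (used to freeze cross-implementation oracle values).
pm_lcg <- function(seed, n) {
  x <- seed
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (16807 * x) %% 2147483647
    out[i] <- x / 2147483647
  }
  out
}

pm_image <- function(seed, L = 32L) matrix(pm_lcg(seed, L * L), L, L)

# Single-disc phantom: the sharp-edged known-geometry oracle object.
disc_phantom <- function(L = 64L, dx = 10e-9, z_prime = 25e-6, r = L / 6,
                         phase = -0.3, absorbance = 0.03) {
  phantom_spec(
    list(list(shape = shape_disc(L / 2, L / 2, r), phase = phase,
              absorbance = absorbance, label = "disc")),
    L = L, dx = dx, z_prime = z_prime
  )
}
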