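test_that("Fourier-feature encoding has the stated structure", {
  net <- field_network(seed = 3)
  expect_equal(dim(net$B), c(64L, 3L))
  z <- matrix(0, 5, 3)
  enc <- encode_coords(z, net)
  expect_equal(dim(enc), c(5L, 128L))           # encoding width 128
  expect_equal(enc[, 1:64], matrix(0, 5, 64))   # sin block at origin
  expect_equal(enc[, 65:128], matrix(1, 5, 64)) # cos block at origin
  # the projection scale is sigma: same seed, sigma' = (25/15) sigma
  net25 <- field_network(sigma = 25, seed = 3)
  expect_equal(net25$B, net$B * 25 / 15)
  expect_equal(sqrt(mean(rowSums(net25$B^2))) /
                 sqrt(mean(rowSums(net$B^2))), 25 / 15)
})

test_that("the field is sigmoid-bounded and deterministic in its seed", {
  net <- field_network(n_freq = 16L, hidden = c(24L, 24L, 24L), seed = 5)
  set.seed(1)
  coords <- matrix(runif(3e4), ncol = 3)
  o <- field_forward(coords, net)
  expect_equal(dim(o), c(1e4L, 2L))
  expect_true(all(o > 0 & o < 1))
  net_b <- field_network(n_freq = 16L, hidden = c(24L, 24L, 24L), seed = 5)
  expect_identical(field_forward(coords, net_b), o)
  net_c <- field_network(n_freq = 16L, hidden = c(24L, 24L, 24L), seed = 6)
  expect_false(identical(field_forward(coords, net_c), o))
})

test_that("prior loss has its closed forms and matches a direct sum", {
  g <- test_grid(8L)
  dep <- depth_grid(25e-6, 20e-9, 13L)
  mask <- matrix(0L, 8, 8); mask[3:6, 3:6] <- 1L
  labels <- build_label_stack(mask, dep, 5L)
  # closed forms through crafted outputs
  lab_vec <- as.vector(labels$labels)
  o_exact <- cbind(lab_vec, lab_vec)
  expect_equal(holofield:::prior_loss_from_o(o_exact, labels, g, dep)$loss, 0)
  o_half <- matrix(0.5, length(lab_vec), 2)
  expect_equal(holofield:::prior_loss_from_o(o_half, labels, g, dep)$loss,
               0.25)
  # brute-force double sum with a real network
  net <- field_network(n_freq = 8L, hidden = c(12L, 12L, 12L), seed = 2)
  got <- loss_prior(net, labels, dep, g)
  o <- field_forward(lattice_coords(g, dep), net)
  acc <- 0
  idx <- 0
  for (i in seq_len(13)) for (m in seq_len(8)) for (l in seq_len(8)) {
    idx <- idx + 1
    acc <- acc + (o[idx, 1] - labels$labels[l, m, i])^2 +
      (o[idx, 2] - labels$labels[l, m, i])^2
  }
  expect_equal(got, acc / (2 * 8 * 8 * 13), tolerance = 1e-12)
})

test_that("boundary loss sums the three face pairs", {
  g <- test_grid(6L)
  dep <- depth_grid(25e-6, 20e-9, 5L)
  n_lat <- 6 * 6 * 5
  faces <- holofield:::boundary_face_indices(6L, 6L, 5L)
  o0 <- matrix(0, n_lat, 2)
  expect_equal(holofield:::boundary_loss_from_o(o0, g, dep)$loss, 0)
  o1 <- matrix(1, n_lat, 2)
  expect_equal(holofield:::boundary_loss_from_o(o1, g, dep)$loss, 3)
  # brute-force face enumeration with a real network
  net <- field_network(n_freq = 6L, hidden = c(8L, 8L, 8L), seed = 9)
  got <- loss_boundary(net, dep, g)
  o <- field_forward(lattice_coords(g, dep), net)
  l <- rep(1:6, times = 6 * 5); m <- rep(rep(1:6, each = 6), times = 5)
  i <- rep(1:5, each = 36)
  ref <- mean(o[l == 1 | l == 6, ]^2) + mean(o[m == 1 | m == 6, ]^2) +
    mean(o[i == 1 | i == 5, ]^2)
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("analytic gradients of the data loss match finite differences", {
  # small version of the end-to-end gradient check (the acceptance suite
  # runs the full 32 x 32, N = 9 case)
  L <- 16L
  g <- test_grid(L)
  dep <- depth_grid(25e-6, 20e-9, 5L)
  ref <- render_phantom(disc_phantom(L, r = 4))
  H <- simulate_hologram(ref$phase, ref$absorbance, 25e-6, g)
  net <- field_network(n_freq = 8L, hidden = c(10L, 10L, 10L), seed = 3)
  phi <- -0.3; A <- 0.03
  feats <- encode_coords(lattice_coords(g, dep), net)
  cache <- holofield:::mlp_forward(net, feats)
  dims <- c(L, L, 5L)
  vol <- object_volume(array(cache$out[, 1], dims),
                       array(cache$out[, 2], dims), phi = phi, A = A)
  fw <- holofield:::ms_forward(vol, dep, g)
  msb <- holofield:::ms_backward(fw, 2 * (fw$intensity - H$intensity) / L^2)
  gr <- holofield:::mlp_backward(
    net, cache, cbind(as.vector(msb$o_phi), as.vector(msb$o_A)))
  set.seed(42)
  for (k in 1:5) {
    li <- sample(4, 1)
    i <- sample(nrow(net$W[[li]]), 1); j <- sample(ncol(net$W[[li]]), 1)
    eps <- 1e-6
    perturbed <- function(s) {
      n2 <- net; n2$W[[li]][i, j] <- n2$W[[li]][i, j] + s
      loss_data(n2, H, dep, g, phi, A)
    }
    fd <- (perturbed(eps) - perturbed(-eps)) / (2 * eps)
    expect_equal(gr$W[[li]][i, j], fd, tolerance = 1e-4)
  }
})
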