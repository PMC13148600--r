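test_that("pre-training on zero labels drives the field to zero", {
  g <- test_grid(16L)
  dep <- depth_grid(25e-6, 20e-9, 11L)
  labels <- build_label_stack(matrix(0L, 16, 16), dep, 5L)
  net <- field_network(n_freq = 12L, hidden = c(16L, 16L, 16L), seed = 1)
  net <- pretrain_field(net, labels, dep, g, epochs = 120L, lr = 1e-2)
  o <- field_forward(lattice_coords(g, dep), net)
  expect_lt(mean(o), 0.05)
  expect_lt(loss_prior(net, labels, dep, g), 0.01)
})

test_that("pre-training separates labelled object columns from background", {
  g <- test_grid(16L)
  dep <- depth_grid(25e-6, 20e-9, 11L)
  mask <- matrix(0L, 16, 16)
  mask[5:12, 5:12] <- ifelse(
    (outer(5:12, 5:12, function(a, b) (a - 8.5)^2 + (b - 8.5)^2)) <= 12,
    1L, 0L)
  labels <- build_label_stack(mask, dep, 5L)
  net <- field_network(n_freq = 12L, hidden = c(16L, 16L, 16L), seed = 2)
  net <- pretrain_field(net, labels, dep, g, epochs = 400L, lr = 5e-3)
  # at z' the field distinguishes inside from outside
  coords <- lattice_coords(g, dep)
  at_zp <- abs(coords[, 3] - 0.5) < 1e-9
  o_zp <- matrix(field_forward(coords[at_zp, ], net)[, 1], 16, 16)
  expect_gt(mean(o_zp[mask == 1]) - mean(o_zp[mask == 0]), 0.5)
  # smoothed pre-training loss is non-increasing (up to optimizer jitter)
  h <- net$pretrain_history
  sm <- stats::filter(h, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 1e-3))
  expect_lt(tail(h, 1), 0.02)
})

test_that("map extraction collapses the window by slice summation", {
  g <- test_grid(8L)
  dep <- depth_grid(25e-6, 20e-9, 13L)
  dims <- c(8L, 8L, 13L)
  op <- array(0, dims); oa <- array(0, dims)
  op[3, 4, 7] <- 1; oa[3, 4, 7] <- 1  # one occupied voxel in the window
  vol <- object_volume(op, oa, phi = -0.3, A = 0.03)
  res <- extract_maps(vol, phi = -0.3, A = 0.03, depth = dep, grid = g,
                      window = 2:12)
  expect_equal(res$phase[3, 4], -0.3)
  expect_equal(res$absorbance[3, 4], 0.03)
  expect_equal(sum(res$phase != 0), 1L)
  # empty volume: zero maps
  vol0 <- object_volume(op * 0, oa * 0, phi = -0.3, A = 0.03)
  res0 <- extract_maps(vol0, phi = -0.3, A = 0.03, depth = dep, grid = g)
  expect_true(all(res0$phase == 0) && all(res0$absorbance == 0))
  # occupancy accumulates across slices
  op[3, 4, 8] <- 1
  vol2 <- object_volume(op, oa, phi = -0.3, A = 0.03)
  res2 <- extract_maps(vol2, phi = -0.3, A = 0.03, depth = dep, grid = g,
                       window = 2:12)
  expect_equal(res2$phase[3, 4], -0.6)
})

test_that("the data loss vanishes for self-consistent inputs", {
  L <- 24L
  g <- test_grid(L)
  dep <- depth_grid(25e-6, 20e-9, 11L)
  # a zero-pretrained field against a flat hologram
  labels <- build_label_stack(matrix(0L, L, L), dep, 5L)
  net <- field_network(n_freq = 10L, hidden = c(12L, 12L, 12L), seed = 4)
  net <- pretrain_field(net, labels, dep, g, epochs = 150L, lr = 1e-2)
  ld <- loss_data(net, hologram(matrix(1, L, L)), dep, g,
                  phi = -0.3, A = 0.03)
  expect_lt(ld, 1e-4)
  # ground-truth occupancy against its own hologram (via the multi-slice
  # model directly: exact self-consistency)
  ref <- render_phantom(disc_phantom(L, r = 5))
  H <- simulate_hologram(ref$phase, ref$absorbance, 25e-6, g)
  dims <- c(L, L, 11L)
  op <- array(0, dims); op[, , 6] <- (ref$phase != 0) * 1
  vol <- object_volume(op, op, phi = ref$phase, A = ref$absorbance)
  I <- multislice_forward(vol, dep, g)
  expect_lt(mean((I - H$intensity)^2), 1e-10)
})

test_that("training recovers a single-disc phantom end to end", {
  # compact parameter-recovery harness: one disc, mu = 1000
  L <- 32L
  g <- test_grid(L)
  dep <- depth_grid(25e-6, 20e-9, 13L)
  ref <- render_phantom(disc_phantom(L, r = 6))
  H0 <- simulate_hologram(ref$phase, ref$absorbance, 25e-6, g)
  Hs <- apply_shot_noise(H0, 1000, seed = 5)
  res <- neural_holo_reconstruct(
    Hs, g, dep, phi = ref$phase, A = ref$absorbance,
    sigma = 15, n_freq = 16L, hidden = c(32L, 32L, 32L), net_seed = 11,
    pretrain_epochs = 120L, pretrain_lr = 5e-3,
    epochs = 450L, lr = 2e-3, patience = NULL)
  m <- ref$masks$disc
  expect_lt(abs(mean(res$phase[m]) - (-0.3)) / 0.3, 0.15)
  expect_equal(res$method, "neural_field")
  expect_s3_class(res, "recon_result")
  # training history is recorded and finite
  expect_true(all(is.finite(res$details$history$l_data)))
})

test_that("training validates inputs and records early stopping", {
  g <- test_grid(16L)
  dep <- depth_grid(25e-6, 20e-9, 11L)
  net <- field_network(n_freq = 8L, hidden = c(8L, 8L, 8L), seed = 1)
  expect_error(train_field(net, hologram(matrix(1, 8, 8)), dep, g,
                           phi = -0.3, A = 0.03), "shape")
  expect_error(train_field(net, hologram(matrix(1, 16, 16)), dep, g,
                           phi = matrix(-0.3, 16, 16), A = 0.03,
                           trainable_coeffs = TRUE), "scalar")
  fit <- train_field(net, hologram(matrix(1, 16, 16)), dep, g,
                     phi = -0.3, A = 0.03, epochs = 30L, lr = 1e-3,
                     patience = 5L, min_epochs = 10L, warmup = NULL)
  expect_s3_class(fit, "field_fit")
  expect_lte(fit$epochs_run, 30L)
  expect_equal(nrow(fit$history), fit$epochs_run)
})
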