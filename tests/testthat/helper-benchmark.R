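# Desk-scale benchmark shared by the acceptance tests: computed once per
# test run and cached (several acceptance blocks read different aspects
# of the same grid of reconstructions).

.bench_env <- new.env(parent = emptyenv())

desk_benchmark <- function() {
  if (!is.null(.bench_env$results)) return(.bench_env$results)
  L <- 64L
  z_prime <- 25e-6
  grid <- wavefield_grid(L, dx = 10e-9, wavelength = lambda_xray)
  depth <- depth_grid(z_prime, 20e-9, 13L)
  ref <- render_phantom(default_phantom(L, 10e-9, z_prime))
  H0 <- simulate_hologram(ref$phase, ref$absorbance, z_prime, grid)
  phase_refs <- c(alpha = -0.3, beta = -0.2, gamma = -0.1)
  absorb_refs <- c(alpha = 0.03, beta = 0.02, gamma = 0.01)
  rows <- list()
  for (mu in c(1000, 300, 100)) {
    for (sd in 1:3) {
      snl <- apply_shot_noise(H0, mu, seed = sd)
      nf <- neural_holo_reconstruct(
        snl, grid, depth, phi = ref$phase, A = ref$absorbance,
        w_z = 5L, sigma = 15, n_freq = 20L, hidden = c(40L, 40L, 40L),
        net_seed = sd + 500000L, precision = "single",
        pretrain_epochs = 100L, pretrain_lr = 5e-3,
        epochs = 400L, lr = 2e-3, patience = NULL,
        warmup = 100L, restart_every = 100L)
      gs <- gs_reconstruct(snl, grid, z_prime)
      rows[[length(rows) + 1L]] <- data.frame(
        mu = mu, seed = sd,
        nf_phase = average_percentage_error(nf$phase, ref$masks,
                                            phase_refs)$average,
        nf_absorb = average_percentage_error(nf$absorbance, ref$masks,
                                             absorb_refs)$average,
        gs_phase = average_percentage_error(gs$phase, ref$masks,
                                            phase_refs)$average)
    }
  }
  .bench_env$results <- do.call(rbind, rows)
  .bench_env$results
}

bench_median <- function(results, col, mu) {
  stats::median(results[results$mu == mu, col])
}
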