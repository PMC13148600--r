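#' Pre-train the neural field on mask labels
#'
#' Full-batch Adam minimization of the prior loss ([loss_prior()]) over
#' the complete coordinate lattice, guiding the field toward the candidate
#' 3-D object region before the physics-based stage.  The defaults follow
#' the reference schedule: 300 epochs at learning rate 1e-3.
#'
#' @param net A [field_network()].
#' @param labels A `mask_label_stack` from [build_label_stack()].
#' @param depth A [depth_grid()].
#' @param grid A [wavefield_grid()].
#' @param epochs Number of epochs (each evaluates the full lattice once).
#' @param lr Adam learning rate.
#' @param verbose Print the loss every 50 epochs.
#' @return The trained `field_network`, with the per-epoch loss history in
#'   `$pretrain_history`.
#' @export
pretrain_field <- function(net, labels, depth, grid, epochs = 300L,
                           lr = 1e-3, verbose = FALSE) {
  stopifnot(epochs >= 1, lr > 0)
  feats <- encode_coords(lattice_coords(grid, depth), net)
  params <- net_params(net)
  state <- adam_init(params)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    cache <- mlp_forward(net, feats)
    pl <- prior_loss_from_o(cache$out, labels, grid, depth)
    if (!is.finite(pl$loss)) {
      stop(sprintf("pre-training diverged (loss not finite at epoch %d)", ep),
           call. = FALSE)
    }
    history[ep] <- pl$loss
    g <- mlp_backward(net, cache, pl$dOut)
    upd <- adam_step(params, c(g$W, g$b), state, lr)
    params <- upd$params; state <- upd$state
    net <- set_net_params(net, params)
    if (verbose && ep %% 50L == 0L) {
      message(sprintf("[pretrain] epoch %d  L_Prior = %.3e", ep, pl$loss))
    }
  }
  net$pretrain_history <- history
  net
}

#' Train the neural field against a hologram
#'
#' Full-batch Adam minimization of `L_Data + L_BC`: each epoch evaluates
#' the field on the full lattice, runs the multi-slice forward model to
#' the detector, and back-propagates the intensity mismatch through the
#' FFTs, the slice transmissions and the network.  The phase and
#' absorbance coefficients are held fixed when their true values are known
#' (synthetic benchmarking) or optimized jointly when they are not
#' (experimental mode).  Reference schedules: 3000 epochs at 1e-4
#' (synthetic), 2000 at 1e-5 (experimental).
#'
#' @inheritParams pretrain_field
#' @param H A [hologram()].
#' @param phi,A Initial phase / absorbance coefficients (scalar or
#'   `L x M` maps; maps cannot be trainable).
#' @param trainable_coeffs Optimize scalar `phi` and `A` along with the
#'   network weights.
#' @param patience Early-stopping patience in epochs on the 10-epoch
#'   smoothed data loss (overfitting to shot noise sets in once the data
#'   loss reaches the noise floor); `NULL` disables early stopping.
#' @param min_epochs Epochs to run before early stopping may trigger
#'   (guards against the optimizer's initial transient, whose loss dip can
#'   otherwise stall the patience counter).
#' @param warmup Linear learning-rate warmup length in epochs.  The
#'   pre-trained occupancy fills the whole axial label window, so the
#'   initial simulated hologram is far from the measurement; full-size
#'   Adam steps at that point can overshoot the physical solution into
#'   the saturated empty-volume state.  Ramping the rate avoids this.
#' @param restart_every Warm-restart period in epochs (`NULL` to disable):
#'   the Adam moment estimates are re-initialized every this many epochs.
#'   With a full-batch global forward model the accumulated momentum
#'   aligns with a collective "shrink the whole volume" direction that
#'   can carry the iterate through the physical optimum into the empty
#'   state; periodic restarts damp exactly that mode while leaving
#'   converged coordinates in place.
#' @return A list of class `field_fit`: `net`, `phi`, `A`, `history`
#'   (data-frame of per-epoch `l_data`, `l_bc`), `epochs_run`.
#' @export
train_field <- function(net, H, depth, grid, phi, A, epochs = 3000L,
                        lr = 1e-4, trainable_coeffs = FALSE,
                        patience = 200L, min_epochs = 200L, warmup = 100L,
                        restart_every = 100L, verbose = FALSE) {
  stopifnot(epochs >= 1, lr > 0)
  Hmat <- hologram_intensity(H)
  if (nrow(Hmat) != grid$L || ncol(Hmat) != grid$M) {
    stop("hologram shape does not match grid", call. = FALSE)
  }
  if (trainable_coeffs && (length(phi) != 1L || length(A) != 1L)) {
    stop("only scalar coefficients can be trainable", call. = FALSE)
  }
  feats <- encode_coords(lattice_coords(grid, depth), net)
  faces <- boundary_face_indices(grid$L, grid$M, depth$n_slices)
  dims <- c(grid$L, grid$M, depth$n_slices)
  npix <- grid$L * grid$M
  params <- net_params(net)
  if (trainable_coeffs) params <- c(params, list(phi = phi, A = A))
  state <- adam_init(params)
  l_data <- numeric(epochs); l_bc <- numeric(epochs)
  best_smooth <- Inf; best_ep <- 0L; ep_run <- 0L
  for (ep in seq_len(epochs)) {
    if (trainable_coeffs) {
      phi <- params[[length(params) - 1L]]
      A <- max(params[[length(params)]], 0)  # absorbance stays nonnegative
    }
    cache <- mlp_forward(net, feats)
    o <- cache$out
    vol <- object_volume(array(o[, 1L], dims), array(o[, 2L], dims),
                         phi = phi, A = A)
    fw <- ms_forward(vol, depth, grid)
    resid <- fw$intensity - Hmat
    ld <- mean(resid^2)
    bc <- boundary_loss_from_o(o, grid, depth, faces)
    if (!is.finite(ld) || !is.finite(bc$loss)) {
      stop(sprintf("training diverged (loss not finite at epoch %d)", ep),
           call. = FALSE)
    }
    l_data[ep] <- ld; l_bc[ep] <- bc$loss
    msb <- ms_backward(fw, 2 * resid / npix)
    dOut <- cbind(as.vector(msb$o_phi), as.vector(msb$o_A)) + bc$dOut
    g <- mlp_backward(net, cache, dOut)
    grads <- c(g$W, g$b)
    if (trainable_coeffs) grads <- c(grads, list(phi = msb$phi, A = msb$A))
    lr_ep <- if (!is.null(warmup) && warmup > 0L) {
      lr * min(1, ep / warmup)
    } else lr
    if (!is.null(restart_every) && ep > 1L &&
        (ep - 1L) %% restart_every == 0L) {
      state <- adam_init(params)
    }
    upd <- adam_step(params, grads, state, lr_ep)
    params <- upd$params; state <- upd$state
    net <- set_net_params(net, params[seq_len(2L * length(net$W))])
    ep_run <- ep
    if (verbose && ep %% 50L == 0L) {
      message(sprintf("[train] epoch %d  L_Data = %.3e  L_BC = %.3e",
                      ep, ld, bc$loss))
    }
    if (!is.null(patience) && ep >= 10L) {
      smooth <- mean(l_data[(ep - 9L):ep])
      if (smooth < best_smooth - 1e-12) { best_smooth <- smooth; best_ep <- ep }
      else if (ep >= max(min_epochs, 10L) && ep - best_ep >= patience) break
    }
  }
  if (trainable_coeffs) {
    phi <- params[[length(params) - 1L]]
    A <- max(params[[length(params)]], 0)
  }
  structure(
    list(net = net, phi = phi, A = A,
         history = data.frame(epoch = seq_len(ep_run),
                              l_data = l_data[seq_len(ep_run)],
                              l_bc = l_bc[seq_len(ep_run)]),
         epochs_run = ep_run),
    class = "field_fit"
  )
}

#' Extract phase and absorbance maps from a trained field
#'
#' Materializes the object values near the object plane and collapses them
#' axially: the phase map is the phase coefficient times the slice-sum of
#' `o_phi` over the window (so a one-slice object reproduces its
#' coefficient exactly, and multi-slice occupancy accumulates), and
#' likewise for absorbance.
#'
#' @param net A trained [field_network()], a `field_fit` (whose
#'   coefficients then override `phi`, `A`), or an already materialized
#'   [object_volume()].
#' @param phi,A Coefficients (scalar or `L x M` maps).
#' @param depth A [depth_grid()].
#' @param grid A [wavefield_grid()].
#' @param window Integer slice indices to sum over; defaults to the
#'   pre-training window when a `mask_label_stack` is given, or all slices.
#' @return A [reconstruction_result()].
#' @export
extract_maps <- function(net, phi = NULL, A = NULL, depth, grid,
                         window = NULL) {
  if (inherits(net, "field_fit")) {
    phi <- net$phi; A <- net$A; net <- net$net
  }
  if (inherits(window, "mask_label_stack")) window <- window$window
  if (is.null(window)) window <- seq_len(depth$n_slices)
  vol <- if (inherits(net, "object_volume")) {
    net$phi <- phi; net$A <- A
    net
  } else {
    materialize_volume(net, grid, depth, phi = phi, A = A)
  }
  sum_phi <- apply(vol$o_phi[, , window, drop = FALSE], c(1, 2), sum)
  sum_A <- apply(vol$o_A[, , window, drop = FALSE], c(1, 2), sum)
  reconstruction_result(phase = phi * sum_phi, absorbance = A * sum_A,
                        method = "neural_field",
                        details = list(window = window, phi = phi, A = A))
}

#' Reconstruction result container
#'
#' @param phase Phase map in radians.
#' @param absorbance Absorbance map (amplitude log-attenuation).
#' @param method Method name string.
#' @param details Free-form provenance list (config, epochs, residuals...).
#' @return An object of class `recon_result`.
#' @export
reconstruction_result <- function(phase, absorbance, method,
                                  details = list()) {
  stopifnot(identical(dim(phase), dim(absorbance)))
  structure(list(phase = phase, absorbance = absorbance, method = method,
                 details = details),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %s: %d x %d, phase in [%.3f, %.3f] rad, absorbance in [%.4f, %.4f]\n",
              x$method, nrow(x$phase), ncol(x$phase),
              min(x$phase), max(x$phase), min(x$absorbance), max(x$absorbance)))
  invisible(x)
}
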