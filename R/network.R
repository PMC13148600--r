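#' Coordinate-based neural field for object occupancy
#'
#' A small fully connected network mapping normalized 3-D coordinates to
#' two object values (occupancy channels for phase and absorbance).  The
#' input is lifted by a fixed random Fourier-feature projection
#' `[sin(2 pi B c), cos(2 pi B c)]` with `B ~ N(0, sigma^2)` (Gaussian
#' positional encoding), followed by three dense layers with swish
#' activations and a 2-channel sigmoid output, so both object values lie
#' in (0, 1) for every input.
#'
#' @param sigma Gaussian scale of the Fourier-feature matrix; 15 is the
#'   synthetic-hologram default, 25 suits the experimental geometry.
#' @param n_freq Number of random frequencies; the encoding width is
#'   `2 * n_freq` (default 64, i.e. width 128).
#' @param hidden Integer vector of hidden-layer widths (default
#'   `c(128, 128, 128)`).
#' @param seed Seed for the Fourier matrix and the weight initialization;
#'   the same seed and architecture give bit-identical networks.
#' @param precision `"double"` (default) or `"single"`: arithmetic used
#'   for the dense-layer evaluation.  Single precision halves the time
#'   and memory of the lattice-sized forward/backward passes (standard
#'   practice for neural-network training) while the optimizer state,
#'   weights and the wave optics stay in double; use double where
#'   gradients are compared against finite differences.
#' @return An object of class `field_network`.
#' @export
field_network <- function(sigma = 15, n_freq = 64L, hidden = c(128L, 128L, 128L),
                          seed = 1L, precision = c("double", "single")) {
  precision <- match.arg(precision)
  stopifnot(sigma > 0, n_freq >= 1, all(hidden >= 1))
  with_seed(seed, {
    B <- matrix(stats::rnorm(n_freq * 3L, sd = sigma), n_freq, 3L)
    dims <- c(2L * n_freq, hidden, 2L)
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (k in seq_along(W)) {
      fan_in <- dims[k]; fan_out <- dims[k + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))  # Glorot uniform
      W[[k]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
      b[[k]] <- rep(0, fan_out)
    }
    structure(list(B = B, W = W, b = b, sigma = sigma, n_freq = n_freq,
                   hidden = hidden, seed = seed, precision = precision),
              class = "field_network")
  })
}

#' @export
print.field_network <- function(x, ...) {
  cat(sprintf(
    "<field_network> encoding width %d (sigma = %g), hidden [%s], 2 sigmoid outputs\n",
    2L * x$n_freq, x$sigma, paste(x$hidden, collapse = ", ")))
  invisible(x)
}

#' Fourier-feature positional encoding
#'
#' @param coords Numeric `n x 3` matrix of normalized coordinates in
#'   `[0, 1]^3`.
#' @param net A [field_network()].
#' @return `n x (2 n_freq)` feature matrix `[sin(2 pi B c), cos(2 pi B c)]`.
#' @export
encode_coords <- function(coords, net) {
  stopifnot(inherits(net, "field_network"))
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("`coords` must be n x 3", call. = FALSE)
  ang <- 2 * pi * (coords %*% t(net$B))
  cbind(sin(ang), cos(ang))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# swish(z) = z * sigmoid(z); returns value and local derivative
swish <- function(z) {
  s <- sigmoid(z)
  list(a = z * s, d = s + z * s * (1 - s))
}

# Forward pass from precomputed features.  The heavy per-layer work runs
# in compiled code; the activation cache of the latest forward stays on
# the C++ side (training is single-threaded and every backward call
# immediately follows its own forward).
mlp_forward <- function(net, feats, keep_cache = TRUE) {
  out <- if (identical(net$precision, "single")) {
    .fastmlp_forward_f32(feats, net$W, net$b, keep_cache)
  } else {
    .fastmlp_forward(feats, net$W, net$b, keep_cache)
  }
  list(out = out)
}

# Reverse pass: gradients of the loss w.r.t. weights and biases given
# dL/d(out), using the cached activations of the preceding forward.
mlp_backward <- function(net, cache, dOut) {
  if (identical(net$precision, "single")) {
    .fastmlp_backward_f32(net$W, dOut)
  } else {
    .fastmlp_backward(net$W, dOut)
  }
}

#' Evaluate the neural field at normalized coordinates
#'
#' @inheritParams encode_coords
#' @return `n x 2` matrix of object values `(o_phi, o_A)`, each in (0, 1).
#' @export
field_forward <- function(coords, net) {
  if (is.null(net$W)) stop("network is not initialized", call. = FALSE)
  mlp_forward(net, encode_coords(coords, net))$out
}

#' Normalized training lattice for a grid and depth range
#'
#' Builds the full `L x M x N` coordinate lattice fed to the neural field:
#' `x` and `y` are pixel coordinates normalized by the lateral extents
#' (`l / L`, `m / M`) and `z` is affinely mapped from `[z_1, z_N]` to
#' `[0, 1]`.  The first index varies fastest, matching
#' `array(..., c(L, M, N))` layout.
#'
#' @param grid A [wavefield_grid()].
#' @param depth A [depth_grid()].
#' @return `(L M N) x 3` coordinate matrix.
#' @export
lattice_coords <- function(grid, depth) {
  xt <- seq_len(grid$L) / grid$L
  yt <- seq_len(grid$M) / grid$M
  zt <- (depth$z - depth$z1) / (depth$zN - depth$z1)
  cbind(rep(xt, times = grid$M * depth$n_slices),
        rep(rep(yt, each = grid$L), times = depth$n_slices),
        rep(zt, each = grid$L * grid$M))
}

# Materialize the field over a lattice as an object_volume.
materialize_volume <- function(net, grid, depth, phi, A, feats = NULL) {
  if (is.null(feats)) feats <- encode_coords(lattice_coords(grid, depth), net)
  o <- mlp_forward(net, feats)$out
  dims <- c(grid$L, grid$M, depth$n_slices)
  object_volume(array(o[, 1L], dims), array(o[, 2L], dims), phi = phi, A = A)
}

# ---- Adam optimizer on a flat list of parameter arrays ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Pack/unpack network weights to a flat list for the optimizer.
net_params <- function(net) c(net$W, net$b)
set_net_params <- function(net, params) {
  nl <- length(net$W)
  net$W <- params[seq_len(nl)]
  net$b <- params[nl + seq_len(nl)]
  net
}
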