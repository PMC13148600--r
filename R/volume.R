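#' Voxelized object occupancy volume
#'
#' Holds the per-voxel object values `o_phi` and `o_A` (occupancy in
#' `[0, 1]`, shape `L x M x N`) together with the phase-shift and
#' absorbance coefficients.  A voxel fully occupied by the object
#' (`o = 1`) modulates the transmitted field by
#' `exp(i phi - A)`: `phi` is the (signed, typically negative for
#' `n = 1 - delta + i kappa` materials) phase shift in radians and `A` the
#' dimensionless amplitude absorbance.  The coefficients may be scalars or
#' per-pixel `L x M` maps (used when distinct objects carry distinct known
#' coefficients).
#'
#' @param o_phi,o_A Numeric arrays `L x M x N` with values in `[0, 1]`.
#' @param phi Phase coefficient, scalar or `L x M` matrix (rad; <= 0 for
#'   refractive-index-decrement materials).
#' @param A Absorbance coefficient, scalar or `L x M` matrix (>= 0).
#' @return An object of class `object_volume`.
#' @export
object_volume <- function(o_phi, o_A, phi, A) {
  if (!identical(dim(o_phi), dim(o_A)) || length(dim(o_phi)) != 3L) {
    stop("`o_phi` and `o_A` must be L x M x N arrays of equal shape",
         call. = FALSE)
  }
  rng <- range(o_phi, o_A)
  if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12) {
    stop("object values must lie in [0, 1]", call. = FALSE)
  }
  if (any(A < 0)) stop("absorbance coefficient must be >= 0", call. = FALSE)
  structure(list(o_phi = o_phi, o_A = o_A, phi = phi, A = A),
            class = "object_volume")
}

# Slice-wise complex transmission exp(i phi o_phi - A o_A).
slice_transmission <- function(vol, i) {
  exp(1i * vol$phi * vol$o_phi[, , i] - vol$A * vol$o_A[, , i])
}

#' Multi-slice forward model: object volume to detector intensity
#'
#' Propagates the unit incident field through the volume slice by slice
#' (from `z_N` down to `z_1`, angular-spectrum steps of `dz`, modulating by
#' each slice's transmission), then performs a single free-space jump over
#' `z_1` to the detector plane at z = 0 (all object values between `z_1`
#' and the detector are taken to be zero).  Returns the simulated
#' detector-plane intensity.
#'
#' @param vol An [object_volume()].
#' @param depth A [depth_grid()] with `n_slices` matching `dim(vol$o_phi)[3]`.
#' @param grid A [wavefield_grid()] with matching lateral shape.
#' @return Numeric `L x M` intensity matrix (`|U_0|^2`).
#' @export
multislice_forward <- function(vol, depth, grid) {
  ms_forward(vol, depth, grid, keep_cache = FALSE)$intensity
}

# Forward pass with optional cache of per-slice incoming fields and
# transmissions, for the reverse-mode gradient below.
ms_forward <- function(vol, depth, grid, keep_cache = TRUE) {
  stopifnot(inherits(vol, "object_volume"), inherits(depth, "depth_grid"),
            inherits(grid, "wavefield_grid"))
  dims <- dim(vol$o_phi)
  if (dims[1] != grid$L || dims[2] != grid$M) {
    stop("object volume lateral shape does not match grid", call. = FALSE)
  }
  if (dims[3] != depth$n_slices) {
    stop("object volume slice count does not match depth grid", call. = FALSE)
  }
  N <- depth$n_slices
  Kdz <- asm_transfer(grid, depth$dz)
  Kz1 <- asm_transfer(grid, depth$z1)
  U <- matrix(1 + 0i, grid$L, grid$M)  # incident beam U_N = 1
  Ucache <- if (keep_cache) vector("list", N) else NULL
  Tcache <- if (keep_cache) vector("list", N) else NULL
  for (i in N:2) {
    Ti <- slice_transmission(vol, i)
    if (keep_cache) { Ucache[[i]] <- U; Tcache[[i]] <- Ti }
    U <- prop_apply(U * Ti, Kdz)
  }
  T1 <- slice_transmission(vol, 1L)
  if (keep_cache) { Ucache[[1L]] <- U; Tcache[[1L]] <- T1 }
  U0 <- prop_apply(U * T1, Kz1)
  list(intensity = Mod(U0)^2, U0 = U0,
       Ucache = Ucache, Tcache = Tcache, Kdz = Kdz, Kz1 = Kz1,
       vol = vol, depth = depth, grid = grid)
}

# Reverse-mode gradient of a scalar loss through the multi-slice model.
# `dL_dI` is the derivative of the loss w.r.t. the detector intensity.
# Returns gradients w.r.t. the object value arrays and the (scalar)
# coefficients.  Uses Wirtinger calculus: the adjoint of propagation by a
# kernel K is propagation by Conj(K).
ms_backward <- function(fw, dL_dI) {
  vol <- fw$vol
  N <- fw$depth$n_slices
  dims <- dim(vol$o_phi)
  g_ophi <- array(0, dims)
  g_oA <- array(0, dims)
  g_phi <- 0
  g_A <- 0
  gU <- dL_dI * fw$U0                       # dL/dU0*
  gW <- prop_apply(gU, Conj(fw$Kz1))        # adjoint of the z1 jump
  for (i in 1:N) {
    if (i > 1L) gW <- prop_apply(gU, Conj(fw$Kdz))
    Ti <- fw$Tcache[[i]]
    gT <- Conj(fw$Ucache[[i]]) * gW         # dL/dT_i*
    common <- Conj(gT) * Ti
    g_ophi[, , i] <- 2 * Re(common * (1i * vol$phi))
    g_oA[, , i] <- -2 * Re(common) * vol$A
    g_phi <- g_phi + sum(2 * Re(common * 1i) * vol$o_phi[, , i])
    g_A <- g_A - sum(2 * Re(common) * vol$o_A[, , i])
    gU <- Conj(Ti) * gW
  }
  list(o_phi = g_ophi, o_A = g_oA, phi = g_phi, A = g_A)
}
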