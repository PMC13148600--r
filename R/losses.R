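#' Pre-training (prior) loss
#'
#' Mean squared error between both object-value channels of the field and
#' the mask label stack, averaged over all lattice points of the full
#' depth range (labels are 0 outside the axial window) and over the two
#' channels.
#'
#' @param net A [field_network()].
#' @param labels A `mask_label_stack` from [build_label_stack()].
#' @param depth A [depth_grid()].
#' @param grid A [wavefield_grid()].
#' @return Scalar loss.
#' @export
loss_prior <- function(net, labels, depth, grid) {
  o <- field_forward(lattice_coords(grid, depth), net)
  prior_loss_from_o(o, labels, grid, depth)$loss
}

prior_loss_from_o <- function(o, labels, grid, depth) {
  stopifnot(inherits(labels, "mask_label_stack"))
  lab <- as.vector(labels$labels)
  if (length(lab) != nrow(o)) stop("label stack shape mismatch", call. = FALSE)
  r1 <- o[, 1L] - lab
  r2 <- o[, 2L] - lab
  n <- length(lab)
  loss <- (sum(r1^2) + sum(r2^2)) / (2 * n)
  list(loss = loss, dOut = cbind(r1, r2) / n)
}

#' Boundary-condition loss
#'
#' Sum of the three face-pair terms: for each axis, the mean squared object
#' value (both channels) on the two opposing faces of the 3-D volume
#' (x = dx and L dx; y = dy and M dy; z = z_1 and z_N), where the target
#' boundary object values are 0.
#'
#' @inheritParams loss_prior
#' @return Scalar loss `L_BC = L_BC,x + L_BC,y + L_BC,z`.
#' @export
loss_boundary <- function(net, depth, grid) {
  o <- field_forward(lattice_coords(grid, depth), net)
  boundary_loss_from_o(o, grid, depth)$loss
}

# Lattice row indices of the three face pairs (first index fastest).
boundary_face_indices <- function(L, M, N) {
  l <- rep(seq_len(L), times = M * N)
  m <- rep(rep(seq_len(M), each = L), times = N)
  i <- rep(seq_len(N), each = L * M)
  list(x = which(l == 1L | l == L),
       y = which(m == 1L | m == M),
       z = which(i == 1L | i == N))
}

boundary_loss_from_o <- function(o, grid, depth, faces = NULL) {
  if (is.null(faces)) {
    faces <- boundary_face_indices(grid$L, grid$M, depth$n_slices)
  }
  loss <- 0
  dOut <- matrix(0, nrow(o), 2L)
  for (idx in faces) {
    n_el <- 2L * length(idx)
    loss <- loss + (sum(o[idx, 1L]^2) + sum(o[idx, 2L]^2)) / n_el
    dOut[idx, ] <- dOut[idx, ] + 2 * o[idx, ] / n_el
  }
  list(loss = loss, dOut = dOut)
}

#' Data (hologram-fit) loss
#'
#' Mean squared error between the detector intensity simulated by the
#' multi-slice forward model on the field-materialized object volume and
#' the measured hologram.
#'
#' @inheritParams loss_prior
#' @param H A [hologram()] (background-normalized).
#' @param phi,A Phase and absorbance coefficients (scalar or `L x M` map).
#' @return Scalar loss.
#' @export
loss_data <- function(net, H, depth, grid, phi, A) {
  vol <- materialize_volume(net, grid, depth, phi = phi, A = A)
  I <- multislice_forward(vol, depth, grid)
  mean((I - hologram_intensity(H))^2)
}
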