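#' Angular spectrum transfer function
#'
#' Frequency-domain free-space propagation kernel on the grid's discrete
#' FFT frequency lattice:
#' `exp(i 2 pi (n_med / lambda) d sqrt(1 - (lambda fx / n_med)^2 - (lambda fy / n_med)^2))`.
#' Evanescent components (negative radicand) are zeroed (hard cutoff); at
#' the propagation distances used here, many orders of magnitude beyond the
#' wavelength, the difference from exponential decay is below float noise.
#'
#' @param grid A [wavefield_grid()] (only the metadata is used).
#' @param distance Propagation distance in metres; may be negative for
#'   back-propagation.
#' @return Complex `L x M` matrix in unshifted FFT ordering.
#' @export
asm_transfer <- function(grid, distance) {
  stopifnot(inherits(grid, "wavefield_grid"))
  if (!is.finite(distance)) stop("`distance` must be finite", call. = FALSE)
  lam <- grid$wavelength / grid$n_med  # in-medium wavelength
  fx <- fft_freq(grid$L, grid$dx)
  fy <- fft_freq(grid$M, grid$dy)
  rad <- 1 - outer((lam * fx)^2, rep(1, grid$M)) -
    outer(rep(1, grid$L), (lam * fy)^2)
  kernel <- matrix(0 + 0i, grid$L, grid$M)
  prop <- rad >= 0
  kernel[prop] <- exp(2i * pi * distance / lam * sqrt(rad[prop]))
  kernel
}

# Apply a precomputed frequency-domain kernel (internal hot path).
prop_apply <- function(field, kernel) {
  stats::fft(stats::fft(field) * kernel, inverse = TRUE) / length(field)
}

#' Free-space propagation of a wavefield
#'
#' Propagates the field by `distance` with the angular spectrum method:
#' `IFFT(FFT(field) * asm_transfer(grid, distance))`.  Grid metadata is
#' unchanged.
#'
#' @inheritParams asm_transfer
#' @param U A [wavefield_grid()] carrying the field to propagate.
#' @return A `wavefield_grid` with the propagated field.
#' @export
propagate <- function(U, distance) {
  stopifnot(inherits(U, "wavefield_grid"))
  if (any(!is.finite(Re(U$field))) || any(!is.finite(Im(U$field)))) {
    stop("field contains NaN or Inf", call. = FALSE)
  }
  U$field <- prop_apply(U$field, asm_transfer(U, distance))
  U
}

#' Back-propagate a hologram to the object plane
#'
#' Treats the square root of the measured intensity as a real, zero-phase
#' amplitude at the detector and propagates it backwards by `distance`.
#' The intensity of the result is the in-focus reconstructed hologram used
#' for object-mask segmentation.
#'
#' @param H A [hologram()] or a nonnegative intensity matrix.
#' @param distance Detector-to-object distance in metres (> 0).
#' @param grid A [wavefield_grid()] supplying the optical metadata.
#' @return A `wavefield_grid` holding the complex in-focus field.
#' @export
backpropagate_to_object <- function(H, distance, grid) {
  I <- hologram_intensity(H)
  if (any(I < 0)) stop("hologram intensities must be nonnegative", call. = FALSE)
  stopifnot(inherits(grid, "wavefield_grid"))
  if (nrow(I) != grid$L || ncol(I) != grid$M) {
    stop("hologram shape does not match grid", call. = FALSE)
  }
  grid$field <- sqrt(I) + 0i
  propagate(grid, -distance)
}
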