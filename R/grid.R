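#' X-ray wavelength from photon energy
#'
#' Converts a photon energy in keV to the corresponding vacuum wavelength
#' using `lambda = h c / E`.
#'
#' @param energy_kev Photon energy in keV (positive scalar).
#' @return Wavelength in metres.
#' @examples
#' xray_wavelength(9.344) * 1e9  # nm
#' @export
xray_wavelength <- function(energy_kev) {
  if (!is.numeric(energy_kev) || length(energy_kev) != 1L ||
      !is.finite(energy_kev) || energy_kev <= 0) {
    stop("`energy_kev` must be a positive finite scalar", call. = FALSE)
  }
  # h*c = 1.23984193 eV um
  1.23984193e-9 / energy_kev
}

#' Complex wavefield on a regular pixel grid
#'
#' A `wavefield_grid` holds a complex scalar field sampled on an `L x M`
#' pixel lattice together with the optical metadata needed for angular
#' spectrum propagation: pixel pitches, wavelength and the refractive index
#' of the surrounding medium.  Holograms are background-normalized, so the
#' incident beam is represented by the unit field `1 + 0i`, which is also
#' the default.
#'
#' @param L,M Grid size in pixels along x (rows) and y (columns); both >= 2.
#' @param dx,dy Pixel pitch in metres; `dy` defaults to `dx`.
#' @param wavelength Wavelength in metres (in vacuum; the in-medium
#'   wavelength is `wavelength / n_med`).
#' @param n_med Real refractive index of the surrounding medium (>= 1).
#' @param field Optional complex `L x M` matrix; defaults to the unit
#'   incident field.
#' @return An object of class `wavefield_grid`.
#' @export
wavefield_grid <- function(L, M = L, dx, dy = dx, wavelength, n_med = 1,
                           field = NULL) {
  L <- as.integer(L); M <- as.integer(M)
  if (is.na(L) || is.na(M) || L < 2L || M < 2L) {
    stop("grid must be at least 2 x 2 pixels", call. = FALSE)
  }
  if (!all(is.finite(c(dx, dy, wavelength))) || dx <= 0 || dy <= 0 ||
      wavelength <= 0) {
    stop("`dx`, `dy` and `wavelength` must be positive and finite",
         call. = FALSE)
  }
  if (!is.finite(n_med) || n_med < 1) {
    stop("`n_med` must be finite and >= 1", call. = FALSE)
  }
  if (is.null(field)) {
    field <- matrix(1 + 0i, L, M)
  } else {
    field <- as_complex_matrix(field)
    if (nrow(field) != L || ncol(field) != M) {
      stop("`field` must be an L x M matrix", call. = FALSE)
    }
  }
  structure(
    list(field = field, L = L, M = M, dx = dx, dy = dy,
         wavelength = wavelength, n_med = n_med),
    class = "wavefield_grid"
  )
}

#' @export
print.wavefield_grid <- function(x, ...) {
  cat(sprintf(
    "<wavefield_grid> %d x %d px, dx = %.3g nm, dy = %.3g nm, lambda = %.4g nm, n_med = %g\n",
    x$L, x$M, x$dx * 1e9, x$dy * 1e9, x$wavelength * 1e9, x$n_med))
  invisible(x)
}

as_complex_matrix <- function(x) {
  if (!is.matrix(x)) stop("expected a matrix", call. = FALSE)
  if (!is.complex(x)) {
    storage.mode(x) <- "double"
    x <- x + 0i
  }
  x
}

#' Axial slice grid around the approximate object depth
#'
#' Defines the discretized depths used by the multi-slice forward model and
#' the neural field: `n_slices` planes spaced `dz` apart and centred on the
#' approximate object depth `z_prime` (measured from the detector plane at
#' z = 0).  With the default `n_slices = 81` the volume spans
#' `[z_prime - 40 dz, z_prime + 40 dz]`.
#'
#' @param z_prime Approximate object depth in metres (> 0).
#' @param dz Slice spacing in metres (> 0).
#' @param n_slices Odd number of slices (so that `z_prime` is itself a
#'   slice); default 81.
#' @return An object of class `depth_grid` with elements `z`, `z1`, `zN`,
#'   `dz`, `n_slices`, `z_prime`.
#' @export
depth_grid <- function(z_prime, dz, n_slices = 81L) {
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 3L || n_slices %% 2L == 0L) {
    stop("`n_slices` must be an odd integer >= 3", call. = FALSE)
  }
  if (!is.finite(z_prime) || !is.finite(dz) || dz <= 0 || z_prime <= 0) {
    stop("`z_prime` and `dz` must be positive and finite", call. = FALSE)
  }
  half <- (n_slices - 1L) %/% 2L
  z1 <- z_prime - half * dz
  if (z1 <= 0) {
    stop("slice volume must lie strictly between source and detector (z1 > 0)",
         call. = FALSE)
  }
  z <- z1 + (seq_len(n_slices) - 1) * dz
  structure(
    list(z = z, z1 = z1, zN = z[n_slices], dz = dz,
         n_slices = n_slices, z_prime = z_prime,
         i_prime = half + 1L),
    class = "depth_grid"
  )
}

#' @export
print.depth_grid <- function(x, ...) {
  cat(sprintf(
    "<depth_grid> %d slices, dz = %.3g nm, z in [%.6g, %.6g] um, z' = %.6g um\n",
    x$n_slices, x$dz * 1e9, x$z1 * 1e6, x$zN * 1e6, x$z_prime * 1e6))
  invisible(x)
}

# Discrete FFT frequency lattice (standard unshifted ordering), cycles/m.
fft_freq <- function(n, d) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1L))
  k / (n * d)
}
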