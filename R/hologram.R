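#' Background-normalized intensity hologram
#'
#' @param intensity Nonnegative numeric `L x M` matrix, normalized so the
#'   background level is ~1.
#' @param mu Mean photon count per pixel for shot-noise-limited holograms;
#'   `NULL` for noise-free.
#' @param seed RNG seed used to draw the photon counts, if any.
#' @param provenance Free-text provenance string.
#' @return An object of class `hologram`.
#' @export
hologram <- function(intensity, mu = NULL, seed = NULL, provenance = "") {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("`intensity` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(intensity))) stop("intensity contains NaN or Inf", call. = FALSE)
  if (any(intensity < 0)) stop("intensity must be nonnegative", call. = FALSE)
  structure(list(intensity = intensity, mu = mu, seed = seed,
                 provenance = provenance),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d, mean = %.4f%s\n",
              nrow(x$intensity), ncol(x$intensity), mean(x$intensity),
              if (is.null(x$mu)) " (noise-free)"
              else sprintf(", mu = %g, seed = %s", x$mu,
                           format(x$seed))))
  invisible(x)
}

# Accept either a hologram object or a bare intensity matrix.
hologram_intensity <- function(H) {
  if (inherits(H, "hologram")) H$intensity
  else if (is.matrix(H) && is.numeric(H)) H
  else stop("expected a hologram or a numeric matrix", call. = FALSE)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's
# random state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Apply Poisson shot noise to a noise-free hologram
#'
#' Generates a shot-noise-limited (SNL) hologram: the expected photon
#' count at pixel (p, q) is `lambda_pq = mu * H_pq / Hbar`, where `Hbar`
#' is the spatial mean of the noise-free hologram and `mu` the mean photon
#' count per pixel; counts are drawn as `C_pq ~ Poisson(lambda_pq)` and
#' rescaled to the normalized-intensity scale as `H'_pq = C_pq / mu`.
#' Draws are made pixel by pixel in a fixed (column-major) order under the
#' given seed, so results are bit-reproducible.
#'
#' @param H Noise-free [hologram()] (or intensity matrix).
#' @param mu Mean photon count per pixel (> 0).
#' @param seed Integer RNG seed.
#' @return A [hologram()] with `mu` and `seed` recorded.
#' @export
apply_shot_noise <- function(H, mu, seed) {
  I <- hologram_intensity(H)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    stop("`mu` must be a positive scalar", call. = FALSE)
  }
  lambda <- mu * I / mean(I)
  counts <- with_seed(seed, stats::rpois(length(lambda), as.vector(lambda)))
  hologram(matrix(counts / mu, nrow(I), ncol(I)), mu = mu, seed = seed,
           provenance = "shot-noise-limited")
}
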