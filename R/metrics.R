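#' Region-wise mean and standard deviation
#'
#' @param map Numeric matrix.
#' @param regions Named list of logical masks of the same shape (e.g. the
#'   `masks` element of [render_phantom()]: per-object regions plus
#'   background).
#' @return A data frame with one row per region: `region`, `mean`, `sd`,
#'   `n` (pixel count).
#' @export
region_stats <- function(map, regions) {
  stopifnot(is.matrix(map), is.list(regions), length(regions) >= 1)
  rows <- lapply(names(regions), function(nm) {
    msk <- regions[[nm]]
    if (!identical(dim(msk), dim(map))) {
      stop("region mask shape does not match map", call. = FALSE)
    }
    v <- map[msk]
    if (length(v) == 0L) {
      stop(sprintf("region '%s' is empty; statistics undefined", nm),
           call. = FALSE)
    }
    data.frame(region = nm, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v))
  })
  do.call(rbind, rows)
}

#' Percentage error of a reconstructed value against a reference
#'
#' `100 |recon - ref| / |ref|`.  Vectorized over both arguments.
#'
#' @param recon_mean Reconstructed value(s), e.g. region means.
#' @param ref_value Nonzero reference value(s).
#' @return Percentage error(s).
#' @export
percentage_error <- function(recon_mean, ref_value) {
  if (any(ref_value == 0)) stop("reference value must be nonzero", call. = FALSE)
  100 * abs(recon_mean - ref_value) / abs(ref_value)
}

#' Average percentage error over object regions
#'
#' For each named object region, the percentage error of the region-mean
#' reconstructed value against its reference; the unweighted mean over the
#' regions is the single summary number reported per method and noise
#' level.
#'
#' @param map Reconstructed map.
#' @param regions Named list of logical object masks (background excluded
#'   by simply not listing it).
#' @param refs Named numeric vector of reference values, names matching
#'   `regions`.
#' @return List with `per_region` (named percentage errors) and `average`.
#' @export
average_percentage_error <- function(map, regions, refs) {
  nm <- names(refs)
  stopifnot(all(nm %in% names(regions)))
  per <- vapply(nm, function(r) {
    percentage_error(mean(map[regions[[r]]]), refs[[r]])
  }, numeric(1))
  list(per_region = per, average = mean(per))
}

#' Mean absolute error over a region
#'
#' @param map,ref Numeric matrices of equal shape.
#' @param region Optional logical mask; default the whole map.
#' @return Scalar MAE.
#' @export
mae <- function(map, ref, region = NULL) {
  stopifnot(identical(dim(map), dim(ref)))
  if (is.null(region)) return(mean(abs(map - ref)))
  if (!identical(dim(region), dim(map))) {
    stop("region mask shape does not match map", call. = FALSE)
  }
  if (!any(region)) stop("region is empty", call. = FALSE)
  mean(abs(map[region] - ref[region]))
}

# Reflect-pad a matrix by r pixels (half-sample symmetric: the edge
# sample is duplicated, as in scipy.ndimage mode "reflect").
pad_reflect <- function(x, r) {
  idx1 <- c(seq(r, 1), seq_len(nrow(x)), seq(nrow(x), nrow(x) - r + 1L))
  idx2 <- c(seq(r, 1), seq_len(ncol(x)), seq(ncol(x), ncol(x) - r + 1L))
  x[idx1, idx2]
}

# Separable truncated-Gaussian filter with reflective boundaries
# (radius = floor(truncate * sigma + 0.5)).
gaussian_filter2 <- function(x, sigma, truncate = 3.5) {
  r <- as.integer(floor(truncate * sigma + 0.5))
  k <- exp(-0.5 * (seq(-r, r))^2 / sigma^2)
  k <- k / sum(k)
  p <- pad_reflect(x, r)
  # filter along rows (first index)
  tmp <- matrix(0, nrow(x), ncol(p))
  for (j in seq_len(2L * r + 1L)) {
    tmp <- tmp + k[j] * p[(j - 1L) + seq_len(nrow(x)), ]
  }
  out <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(2L * r + 1L)) {
    out <- out + k[j] * tmp[, (j - 1L) + seq_len(ncol(x))]
  }
  out
}

#' Structural similarity (SSIM) map, mean and centerline profile
#'
#' Local-window SSIM with a Gaussian weighting window (sigma = 1.5,
#' 11 x 11 support) and the standard stabilizers `K1 = 0.01`, `K2 = 0.03`.
#' `data_range` must be supplied from the reference map's dynamic range so
#' that SSIM is comparable across methods (e.g. 0.3 for the synthetic
#' phase maps, 0.03 for absorbance).  The mean excludes the
#' half-window border; the profile is the SSIM map along the horizontal
#' centerline.
#'
#' @param x,y Numeric matrices of equal shape.
#' @param data_range Dynamic range of the data (> 0).
#' @param sigma Gaussian window sigma in pixels.
#' @param K1,K2 Stabilizing constants.
#' @return List with `map` (full SSIM map), `mean` (border-cropped mean)
#'   and `profile` (horizontal centerline of the map).
#' @export
ssim_map <- function(x, y, data_range, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  stopifnot(identical(dim(x), dim(y)))
  if (!is.numeric(data_range) || data_range <= 0) {
    stop("`data_range` must be > 0", call. = FALSE)
  }
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  f <- function(z) gaussian_filter2(z, sigma)
  ux <- f(x); uy <- f(y)
  vx <- f(x * x) - ux * ux
  vy <- f(y * y) - uy * uy
  vxy <- f(x * y) - ux * uy
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  r <- as.integer(floor(3.5 * sigma + 0.5))
  interior <- S[(r + 1L):(nrow(S) - r), (r + 1L):(ncol(S) - r)]
  list(map = S, mean = mean(interior),
       profile = S[, (ncol(S) + 1L) %/% 2L])
}
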