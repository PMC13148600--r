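#' Edge-based object mask segmentation of an in-focus hologram
#'
#' Segments the rough 2-D object shape from the in-focus intensity image
#' obtained by [backpropagate_to_object()]: Sobel gradient magnitude,
#' Otsu threshold on the normalized gradient, morphological closing, hole
#' filling, and removal of small connected components.  Every step is
#' parameterized.
#'
#' @param img Numeric `L x M` intensity image.
#' @param threshold Gradient threshold in `[0, 1]` on the normalized
#'   gradient magnitude; `NULL` (default) selects it as `otsu_frac` times
#'   the Otsu threshold.
#' @param otsu_frac Fraction of the Otsu threshold used when `threshold`
#'   is `NULL` (default 1, i.e. plain Otsu).  Otsu splits the gradient
#'   histogram at the strongest edges, so when several objects have very
#'   different contrast the faint ones fall below the plain Otsu level;
#'   the reconstruction workflow passes a permissive fraction (the mask
#'   is only a candidate region there, see
#'   [neural_holo_reconstruct()]).
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels (default 1)
#'   applied before the gradient, so pixel-to-pixel shot noise does not
#'   swamp the object edges; 0 disables.
#' @param close_radius Radius in pixels of the disc structuring element
#'   used for closing (default 2).
#' @param min_area_frac Minimum connected-component area as a fraction of
#'   the image (default 0.001); smaller components are discarded.
#' @param shrink_radius Final erosion radius in pixels (default 0, off).
#'   The thresholded gradient band straddles the object boundary, so the
#'   filled mask overshoots the object by about the band half-width; a
#'   one-pixel shrink compensates when a tight mask is wanted.  Leave at
#'   0 when the mask feeds the label stack (candidate regions should be
#'   generous, and thin structures must survive).
#' @return Integer `{0, 1}` matrix of the same shape.
#' @export
segment_object_mask <- function(img, threshold = NULL, smooth_sigma = 1,
                                otsu_frac = 1, close_radius = 2L,
                                min_area_frac = 0.001, shrink_radius = 0L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("`img` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(img))) stop("image contains NaN or Inf", call. = FALSE)
  if (smooth_sigma > 0) img <- gaussian_filter2(img, smooth_sigma)
  g <- sobel_magnitude(img)
  rng <- max(g) - min(g)
  if (rng <= .Machine$double.eps * max(1, max(abs(g)))) {
    return(matrix(0L, nrow(img), ncol(img)))  # constant image: empty mask
  }
  gn <- (g - min(g)) / rng
  if (is.null(threshold)) {
    threshold <- otsu_frac * EBImage::otsu(EBImage::Image(gn))
  }
  edges <- EBImage::Image(gn > threshold)
  brush <- EBImage::makeBrush(2L * close_radius + 1L, shape = "disc")
  closed <- EBImage::closing(edges, brush)
  filled <- EBImage::fillHull(closed)
  lab <- EBImage::bwlabel(filled)
  m <- EBImage::imageData(lab)
  if (max(m) > 0) {
    sizes <- tabulate(m[m > 0])
    keep <- which(sizes >= min_area_frac * length(m))
    m <- matrix(as.integer(m %in% keep), nrow(img), ncol(img))
  } else {
    m <- matrix(0L, nrow(img), ncol(img))
  }
  if (shrink_radius > 0 && any(m > 0)) {
    er <- EBImage::erode(EBImage::Image(m),
                         EBImage::makeBrush(2L * as.integer(shrink_radius) + 1L,
                                            "disc"))
    m <- matrix(as.integer(EBImage::imageData(er) > 0), nrow(img), ncol(img))
  }
  m
}

# Sobel gradient magnitude with edge replication.
sobel_magnitude <- function(img) {
  p <- pad_replicate(img, 1L)
  n1 <- nrow(img); n2 <- ncol(img)
  sh <- function(di, dj) p[di + seq_len(n1), dj + seq_len(n2)]
  gx <- (sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)) - (sh(0, 0) + 2 * sh(0, 1) + sh(0, 2))
  gy <- (sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) - (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))
  sqrt(gx^2 + gy^2)
}

# Replicate-pad a matrix by r pixels on every side.
pad_replicate <- function(x, r) {
  idx1 <- c(rep(1L, r), seq_len(nrow(x)), rep(nrow(x), r))
  idx2 <- c(rep(1L, r), seq_len(ncol(x)), rep(ncol(x), r))
  x[idx1, idx2]
}

#' Replicate an object mask into a pre-training label stack
#'
#' Builds the mask label arrays used to pre-train the neural field: the
#' same 2-D binary mask is replicated at each slice of the axial window
#' `z in [z' - w_z dz, z' + w_z dz]` (that is, `2 w_z + 1` label arrays);
#' slices outside the window carry the label 0 everywhere.
#'
#' @param mask Binary `L x M` matrix (the segmented object mask).
#' @param depth A [depth_grid()].
#' @param w_z Axial half-window in slices, an integer between 5 and 10.
#' @return An object of class `mask_label_stack`: list with `labels`
#'   (`L x M x N` array), `window` (slice indices carrying the mask),
#'   `w_z`, `mask`.
#' @export
build_label_stack <- function(mask, depth, w_z) {
  stopifnot(inherits(depth, "depth_grid"))
  w_z <- as.integer(w_z)
  if (is.na(w_z) || w_z < 5L || w_z > 10L) {
    stop("`w_z` must be an integer between 5 and 10", call. = FALSE)
  }
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    stop("`mask` must be a binary matrix", call. = FALSE)
  }
  window <- depth$i_prime + seq(-w_z, w_z)
  if (min(window) < 1L || max(window) > depth$n_slices) {
    stop("label window [z' - w_z dz, z' + w_z dz] exceeds the depth grid",
         call. = FALSE)
  }
  labels <- array(0, dim = c(nrow(mask), ncol(mask), depth$n_slices))
  for (i in window) labels[, , i] <- mask
  structure(list(labels = labels, window = window, w_z = w_z,
                 mask = matrix(as.integer(mask), nrow(mask), ncol(mask))),
            class = "mask_label_stack")
}
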