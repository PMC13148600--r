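#' @name phantom_shapes
#' @title Parametric phantom shapes
#'
#' @description Shape generators for phantom objects.  Each returns a
#' closure that rasterizes a binary mask on an `L x M` pixel grid (pixel
#' coordinates are 1-based pixel centres).  `shape_glyph()` renders
#' stylized Greek letters (alpha, beta, gamma) from built-in vector stroke
#' outlines; exact glyph geometry is not critical because all quantitative
#' evaluation is region-mean based.
#'
#' @param cx,cy Centre in pixels.
#' @param r Radius in pixels (disc) / outer radius (annulus).
#' @param r_in Inner radius in pixels (annulus).
#' @param w,h Width and height in pixels (bar).
#' @param letter One of `"alpha"`, `"beta"`, `"gamma"`.
#' @param size Glyph box side in pixels.
#' @return A function `(L, M) -> logical L x M mask`.
NULL

#' @rdname phantom_shapes
#' @export
shape_disc <- function(cx, cy, r) {
  function(L, M) {
    px <- matrix(seq_len(L), L, M)
    py <- matrix(seq_len(M), L, M, byrow = TRUE)
    (px - cx)^2 + (py - cy)^2 <= r^2
  }
}

#' @rdname phantom_shapes
#' @export
shape_annulus <- function(cx, cy, r, r_in) {
  stopifnot(r_in < r)
  function(L, M) {
    px <- matrix(seq_len(L), L, M)
    py <- matrix(seq_len(M), L, M, byrow = TRUE)
    d2 <- (px - cx)^2 + (py - cy)^2
    d2 <= r^2 & d2 >= r_in^2
  }
}

#' @rdname phantom_shapes
#' @export
shape_bar <- function(cx, cy, w, h) {
  function(L, M) {
    px <- matrix(seq_len(L), L, M)
    py <- matrix(seq_len(M), L, M, byrow = TRUE)
    abs(px - cx) <= w / 2 & abs(py - cy) <= h / 2
  }
}

# Built-in vector stroke outlines for the Greek glyphs, in a unit box.
# A stroke is either a segment (x1,y1)-(x2,y2) or a circular arc
# (cx, cy, r); pixels within `hw` of a stroke belong to the glyph.
glyph_strokes <- function(letter) {
  switch(letter,
    alpha = list(
      list(type = "circle", cx = 0.42, cy = 0.50, r = 0.23),
      list(type = "seg", x1 = 0.62, y1 = 0.80, x2 = 0.82, y2 = 0.22)
    ),
    beta = list(
      list(type = "seg", x1 = 0.30, y1 = 0.12, x2 = 0.30, y2 = 0.88),
      list(type = "circle", cx = 0.48, cy = 0.66, r = 0.17),
      list(type = "circle", cx = 0.50, cy = 0.32, r = 0.19)
    ),
    gamma = list(
      list(type = "seg", x1 = 0.25, y1 = 0.85, x2 = 0.52, y2 = 0.45),
      list(type = "seg", x1 = 0.75, y1 = 0.85, x2 = 0.40, y2 = 0.12)
    ),
    stop("unknown glyph letter: ", letter, call. = FALSE)
  )
}

# Distance from points (x, y) to a stroke primitive (unit-box coords).
stroke_distance <- function(s, x, y) {
  if (s$type == "circle") {
    abs(sqrt((x - s$cx)^2 + (y - s$cy)^2) - s$r)
  } else {
    vx <- s$x2 - s$x1; vy <- s$y2 - s$y1
    tt <- pmin(pmax(((x - s$x1) * vx + (y - s$y1) * vy) / (vx^2 + vy^2), 0), 1)
    sqrt((x - (s$x1 + tt * vx))^2 + (y - (s$y1 + tt * vy))^2)
  }
}

#' @rdname phantom_shapes
#' @param hw Stroke half-width as a fraction of the glyph box (default 0.06).
#' @export
shape_glyph <- function(letter, cx, cy, size, hw = 0.06) {
  strokes <- glyph_strokes(letter)
  function(L, M) {
    px <- matrix(seq_len(L), L, M)
    py <- matrix(seq_len(M), L, M, byrow = TRUE)
    # map pixel centres into the glyph unit box (x right, y up)
    u <- (px - (cx - size / 2)) / size
    v <- 1 - (py - (cy - size / 2)) / size
    inside <- matrix(FALSE, L, M)
    for (s in strokes) inside <- inside | (stroke_distance(s, u, v) <= hw)
    inside & u >= 0 & u <= 1 & v >= 0 & v <= 1
  }
}

#' Phantom specification
#'
#' Describes a set of thin (single-slice) phantom objects on a pixel grid:
#' each object has a binary shape mask, a signed phase shift (rad) and a
#' nonnegative absorbance.  Objects must be mutually disjoint.
#'
#' @param objects List of `list(shape = <shape fn>, phase = <rad>,
#'   absorbance = <dimensionless>, label = <name>)`.
#' @param L,M Grid size in pixels.
#' @param dx Pixel pitch in metres.
#' @param z_prime Object depth (distance to the detector) in metres.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(objects, L, M = L, dx, z_prime) {
  for (ob in objects) {
    if (is.null(ob$shape) || is.null(ob$phase) || is.null(ob$absorbance) ||
        is.null(ob$label)) {
      stop("each object needs `shape`, `phase`, `absorbance`, `label`",
           call. = FALSE)
    }
    if (ob$absorbance < 0) stop("absorbance must be >= 0", call. = FALSE)
  }
  structure(list(objects = objects, L = as.integer(L), M = as.integer(M),
                 dx = dx, z_prime = z_prime),
            class = "phantom_spec")
}

#' Default three-letter phantom
#'
#' The reference phantom: three absorbing and phase-shifting objects shaped
#' as the Greek letters alpha, beta and gamma with phase shifts
#' -0.3, -0.2, -0.1 rad and absorbances 0.03, 0.02, 0.01, laid out side by
#' side.  At the default size this is a 128 x 128 grid with 10 nm pixels
#' and an object depth of 100 um; smaller grids scale the glyphs and may
#' scale the depth to keep a comparable Fresnel geometry.
#'
#' @param L Grid side in pixels (square grid).
#' @param dx Pixel pitch in metres.
#' @param z_prime Object depth in metres.
#' @param stroke_hw Glyph stroke half-width as a fraction of the glyph
#'   box (default 0.06); the glyphs scale proportionally with the grid.
#' @return A [phantom_spec()].
#' @export
default_phantom <- function(L = 128L, dx = 10e-9, z_prime = 100e-6,
                            stroke_hw = 0.06) {
  size <- 0.22 * L
  cy <- 0.5 * L
  mk <- function(letter, fx, phase, absorbance) {
    list(shape = shape_glyph(letter, fx * L, cy, size, hw = stroke_hw),
         phase = phase, absorbance = absorbance, label = letter)
  }
  phantom_spec(
    list(mk("alpha", 0.25, -0.3, 0.03),
         mk("beta", 0.50, -0.2, 0.02),
         mk("gamma", 0.75, -0.1, 0.01)),
    L = L, dx = dx, z_prime = z_prime
  )
}

#' Rasterize a phantom into reference maps and region masks
#'
#' @param spec A [phantom_spec()].
#' @return A list with `phase` (rad) and `absorbance` reference maps,
#'   `masks` (named list of logical region masks, one per object plus
#'   `background`), and the spec itself.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  L <- spec$L; M <- spec$M
  phase <- matrix(0, L, M)
  absorb <- matrix(0, L, M)
  occupied <- matrix(0L, L, M)
  masks <- list()
  for (ob in spec$objects) {
    m <- ob$shape(L, M)
    occupied <- occupied + m
    phase <- phase + ob$phase * m
    absorb <- absorb + ob$absorbance * m
    masks[[ob$label]] <- m
  }
  if (any(occupied > 1L)) {
    stop("phantom object masks overlap", call. = FALSE)
  }
  masks$background <- occupied == 0L
  list(phase = phase, absorbance = absorb, masks = masks, spec = spec)
}

#' Simulate a noise-free hologram from thin-object maps
#'
#' Applies the object transmission `exp(i phase - absorbance)` to a unit
#' incident field and propagates it to the detector with the angular
#' spectrum method; the recorded intensity is the background-normalized
#' noise-free hologram.
#'
#' @param phase,absorbance Numeric `L x M` maps (rad / dimensionless).
#' @param distance Object-detector distance in metres (> 0).
#' @param grid A [wavefield_grid()] with the optical metadata.
#' @return A [hologram()] with `mu` unset.
#' @export
simulate_hologram <- function(phase, absorbance, distance, grid) {
  if (!identical(dim(phase), dim(absorbance))) {
    stop("`phase` and `absorbance` must have the same shape", call. = FALSE)
  }
  if (any(!is.finite(phase)) || any(!is.finite(absorbance))) {
    stop("maps contain NaN or Inf", call. = FALSE)
  }
  if (distance <= 0) stop("`distance` must be > 0", call. = FALSE)
  stopifnot(inherits(grid, "wavefield_grid"))
  grid$field <- exp(1i * phase - absorbance)
  U0 <- propagate(grid, distance)
  hologram(Mod(U0$field)^2,
           provenance = sprintf("simulated, distance = %g m", distance))
}
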