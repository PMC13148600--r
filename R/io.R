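#' Read and write NPY arrays
#'
#' Minimal NPY (v1.0) support for float32/float64 numeric arrays, the
#' package's lossless raster interchange format.  `write_npy()` stores
#' doubles in Fortran order; `read_npy()` accepts `<f8`/`<f4` in either
#' order.
#'
#' @param x Numeric vector, matrix or array.
#' @param path File path ending in `.npy`.
#' @return `read_npy()` returns a numeric array/matrix; `write_npy()`
#'   returns `path` invisibly.
#' @export
write_npy <- function(x, path) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  shp <- if (is.null(dim(x))) length(x) else dim(x)
  shape_str <- if (length(shp) == 1L) sprintf("(%d,)", shp)
    else sprintf("(%s)", paste(shp, collapse = ", "))
  dict <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': %s, }",
                  shape_str)
  # pad so that magic(6) + version(2) + hlen(2) + header is a multiple of 64
  hlen <- length(charToRaw(dict)) + 1L  # + newline
  pad <- (64L - (10L + hlen) %% 64L) %% 64L
  header <- paste0(dict, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
  writeBin(as.integer(length(charToRaw(header))), con, size = 2L,
           endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.vector(x, mode = "double"), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_npy
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, c(as.raw(0x93), charToRaw("NUMPY")))) {
    stop("not an NPY file: ", path, call. = FALSE)
  }
  ver <- readBin(con, "raw", 2L)
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little",
                  signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shp <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shp <- shp[!is.na(shp)]
  n <- prod(shp)
  x <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    stop("unsupported NPY dtype: ", descr, call. = FALSE))
  if (length(shp) <= 1L) return(x)
  if (fortran) array(x, dim = shp)
  else aperm(array(x, dim = rev(shp)), rev(seq_along(shp)))
}

#' Read a hologram from NPY or TIFF
#'
#' NPY input is read losslessly.  Integer TIFF input (8/16-bit) is
#' promoted to float in `[0, 1]` with the promotion scale recorded in the
#' provenance; if a JSON sidecar (`<path>.json`) written by
#' [write_hologram()] is present, its `scale`/`offset` are applied and
#' `mu`/`seed` restored.
#'
#' @param path File path (`.npy`, `.tif`, `.tiff`).
#' @return A [hologram()].
#' @export
read_hologram <- function(path) {
  ext <- tolower(tools::file_ext(path))
  meta <- read_sidecar(paste0(path, ".json"))
  if (ext == "npy") {
    I <- read_npy(path)
    if (length(dim(I)) != 2L) stop("hologram must be 2-D", call. = FALSE)
  } else if (ext %in% c("tif", "tiff")) {
    I <- tiff::readTIFF(path)
    if (length(dim(I)) != 2L) stop("hologram must be 2-D (single channel)",
                                   call. = FALSE)
    if (!is.null(meta)) I <- I * meta$scale + meta$offset
  } else {
    stop("unknown hologram format: .", ext, call. = FALSE)
  }
  hologram(I, mu = meta$mu, seed = meta$seed,
           provenance = sprintf("read from %s", path))
}

#' @rdname read_hologram
#' @param H A [hologram()] to write.  NPY output is lossless; TIFF output
#'   is 16-bit with scale/offset recorded in the sidecar.
#' @export
write_hologram <- function(H, path) {
  stopifnot(inherits(H, "hologram"))
  ext <- tolower(tools::file_ext(path))
  scale <- 1; offset <- 0
  if (ext == "npy") {
    write_npy(H$intensity, path)
  } else if (ext %in% c("tif", "tiff")) {
    offset <- min(H$intensity)
    scale <- max(max(H$intensity) - offset, .Machine$double.eps)
    tiff::writeTIFF((H$intensity - offset) / scale, path,
                    bits.per.sample = 16L, compression = "none")
  } else {
    stop("unknown hologram format: .", ext, call. = FALSE)
  }
  sidecar <- list(format = ext, scale = scale, offset = offset,
                  mu = H$mu, seed = H$seed, hbar = mean(H$intensity),
                  provenance = H$provenance)
  jsonlite::write_json(sidecar[!vapply(sidecar, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Sidecar schema: if the file exists it must contain scale and offset.
read_sidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("scale", "offset")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("malformed sidecar %s: missing key '%s'", path, key),
           call. = FALSE)
    }
  }
  meta
}

#' Write reconstruction maps and a run manifest
#'
#' Writes `phase.npy`, `absorbance.npy` and a `manifest.json` describing
#' the method and its provenance details into `dir`.
#'
#' @param result A [reconstruction_result()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_maps <- function(result, dir) {
  stopifnot(inherits(result, "recon_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_npy(result$phase, file.path(dir, "phase.npy"))
  write_npy(result$absorbance, file.path(dir, "absorbance.npy"))
  details <- result$details
  details$residual <- NULL  # keep the manifest small; history goes to CSV
  if (!is.null(result$details$residual)) {
    utils::write.csv(
      data.frame(iter = seq_along(result$details$residual),
                 residual = result$details$residual),
      file.path(dir, "residual.csv"), row.names = FALSE)
  }
  manifest <- list(method = result$method, details = details,
                   shape = dim(result$phase))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read an optics configuration (YAML or JSON)
#'
#' Required keys: `wavelength_m`, `dx_m`, `dz_m`, `z_prime_m`, `n_slices`;
#' optional: `dy_m` (defaults to `dx_m`), `n_med` (default 1), `L`, `M`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return Named list of validated optics parameters.
#' @export
read_optics_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
    else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
    else stop("unknown config format: .", ext, call. = FALSE)
  for (key in c("wavelength_m", "dx_m", "dz_m", "z_prime_m", "n_slices")) {
    if (is.null(cfg[[key]])) {
      stop(sprintf("config error: missing key '%s'", key), call. = FALSE)
    }
  }
  cfg$dy_m <- cfg$dy_m %||% cfg$dx_m
  cfg$n_med <- cfg$n_med %||% 1
  for (key in c("wavelength_m", "dx_m", "dy_m", "dz_m", "z_prime_m")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      stop(sprintf("config error: '%s' must be a positive number", key),
           call. = FALSE)
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
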