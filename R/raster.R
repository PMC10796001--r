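#' Elevation raster objects
#'
#' The "2.5D" representation of a point cloud: a regular x-y grid whose
#' pixels hold elevation in metres (or 16-bit integer levels once
#' quantized). Row 1 is the northernmost row; pixel `(r, c)` covers the
#' half-open square
#' `[x_min + (c-1) p, x_min + c p)` x `(y_max - r p, y_max - (r-1) p]`
#' where `p` is the pixel size. Missing pixels (no points assigned) are
#' `NA` in `values`.
#'
#' @param values numeric matrix of elevations (metres) or quantized levels;
#'   `NA` marks missing pixels.
#' @param origin numeric `c(x_min, y_max)` in metres: the north-west corner
#'   of pixel (1, 1).
#' @param pixel_size pixel edge length in metres (> 0).
#' @param quantized logical; `TRUE` when `values` holds integer levels.
#' @param z_min,z_scale quantization metadata (see [quantize()]); required
#'   when `quantized` is `TRUE`.
#' @return an object of class `elev_raster`.
#' @export
elev_raster <- function(values, origin, pixel_size, quantized = FALSE,
                        z_min = NULL, z_scale = NULL) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a positive scalar")
  if (length(origin) != 2L) stop("'origin' must be c(x_min, y_max)")
  if (quantized && (is.null(z_min) || is.null(z_scale)))
    stop("quantized raster requires z_min and z_scale metadata")
  structure(list(values = values, origin = as.numeric(origin),
                 pixel_size = as.numeric(pixel_size),
                 quantized = isTRUE(quantized),
                 z_min = z_min, z_scale = z_scale),
            class = "elev_raster")
}

#' @export
dim.elev_raster <- function(x) dim(x$values)

#' @export
print.elev_raster <- function(x, ...) {
  d <- dim(x$values)
  n_miss <- sum(is.na(x$values))
  cat(sprintf("<elev_raster> %d x %d pixels @ %.3g m%s\n", d[1], d[2],
              x$pixel_size, if (x$quantized) " (quantized, 16-bit)" else ""))
  cat(sprintf("  origin (x_min, y_max): (%.3f, %.3f)  missing: %d (%.1f%%)\n",
              x$origin[1], x$origin[2], n_miss, 100 * n_miss / prod(d)))
  if (n_miss < prod(d)) {
    rng <- range(x$values, na.rm = TRUE)
    cat(sprintf("  values: [%.4g, %.4g]%s\n", rng[1], rng[2],
                if (x$quantized) " levels" else " m"))
  }
  invisible(x)
}

stopifnot_same_grid <- function(a, b, what = "rasters") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(what, " differ in shape: ", paste(dim(a$values), collapse = "x"),
         " vs ", paste(dim(b$values), collapse = "x"))
  if (max(abs(a$origin - b$origin)) > 1e-9 ||
      abs(a$pixel_size - b$pixel_size) > 1e-12)
    stop(what, " differ in georeference (origin/pixel size)")
  invisible(TRUE)
}

#' Rasterize a point cloud to an elevation grid
#'
#' Lays a uniform rectangular grid over the cloud's x-y bounding box (or an
#' explicitly given one), assigns every point to the pixel containing it,
#' and stores the arithmetic mean of the assigned z-values per pixel.
#' Pixels receiving no points are `NA` (missing); [impute_missing()] fills
#' them. Passing the same `bbox` for every flight guarantees that all
#' rasters of a time series share one pixel grid.
#'
#' @param cloud a [point_cloud()].
#' @param pixel_size pixel edge length in metres. The 0.05 m default
#'   resolves 1.2 m-wide plots into ~24 pixel columns.
#' @param bbox optional `c(x_min, x_max, y_min, y_max)` to fix the grid
#'   frame; defaults to the cloud's bounding box. Points outside are
#'   dropped.
#' @return an unquantized [elev_raster()].
#' @export
rasterize <- function(cloud, pixel_size = 0.05, bbox = NULL) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) == 0L) stop("empty point cloud")
  if (pixel_size <= 0) stop("'pixel_size' must be > 0")
  if (is.null(bbox)) {
    bbox <- c(min(cloud[, 1]), max(cloud[, 1]),
              min(cloud[, 2]), max(cloud[, 2]))
  } else {
    inside <- cloud[, 1] >= bbox[1] & cloud[, 1] <= bbox[2] &
      cloud[, 2] >= bbox[3] & cloud[, 2] <= bbox[4]
    cloud <- point_cloud(unclass(cloud)[inside, , drop = FALSE])
    if (nrow(cloud) == 0L) stop("no points inside 'bbox'")
  }
  nc <- max(1L, as.integer(ceiling((bbox[2] - bbox[1]) / pixel_size - 1e-9)))
  nr <- max(1L, as.integer(ceiling((bbox[4] - bbox[3]) / pixel_size - 1e-9)))
  col <- pmin(nc, floor((cloud[, 1] - bbox[1]) / pixel_size) + 1L)
  row <- pmin(nr, floor((bbox[4] - cloud[, 2]) / pixel_size) + 1L)
  row <- pmax(1L, row)  # y == y_max lands in row 1
  idx <- (col - 1L) * nr + row
  sums <- rowsum(cloud[, 3], idx)
  counts <- rowsum(rep(1, length(idx)), idx)
  values <- matrix(NA_real_, nr, nc)
  values[as.integer(rownames(sums))] <- sums / counts
  elev_raster(values, origin = c(bbox[1], bbox[4]), pixel_size = pixel_size)
}

#' Impute missing raster pixels by iterated median filtering
#'
#' Every missing pixel with at least one defined value inside its
#' `window` x `window` neighbourhood is replaced by the median of those
#' defined values; defined pixels are never modified. The pass repeats on
#' the updated raster until no further pixel can be filled, so gaps wider
#' than the window close from their rims inward. The number of pixels that
#' remain missing (isolated regions with no defined pixels at all) is
#' attached as attribute `"still_missing"`.
#'
#' @param raster an [elev_raster()] with at least one defined pixel.
#' @param window odd neighbourhood width in pixels, >= 3.
#' @return the imputed `elev_raster` with attribute `still_missing`.
#' @export
impute_missing <- function(raster, window = 3L) {
  stopifnot(inherits(raster, "elev_raster"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("'window' must be odd and >= 3")
  v <- raster$values
  if (all(is.na(v))) stop("all pixels missing; nothing to impute from")
  repeat {
    if (!anyNA(v)) break
    res <- impute_pass_cpp(v, window)
    v <- res$values
    if (res$n_imputed == 0L) break
  }
  out <- raster
  out$values <- v
  attr(out, "still_missing") <- sum(is.na(v))
  out
}

#' Quantize an elevation raster to 16-bit levels
#'
#' Maps defined elevations linearly onto integer levels so the raster can
#' be stored as a 16-bit greyscale PNG: level = round((z - z_min)/z_scale)
#' with `z_min` the minimum defined elevation. For a fully defined raster
#' `z_scale = (z_max - z_min)/65535`, so z_min maps to level 0 and z_max to
#' 65535. If missing pixels are still present, 65534 levels are used
#' instead, reserving one PNG level to encode missingness (see
#' [write_raster_png()]). A constant raster gets `z_scale = 1`, all levels
#' 0. Quantization is lossy by at most `z_scale/2` per pixel;
#' [dequantize()] inverts it.
#'
#' @param raster an unquantized [elev_raster()].
#' @return the quantized `elev_raster` (metadata in `z_min`, `z_scale`).
#' @export
quantize <- function(raster) {
  stopifnot(inherits(raster, "elev_raster"))
  if (raster$quantized) stop("raster is already quantized")
  v <- raster$values
  if (all(is.na(v))) stop("no defined pixels to quantize")
  z_min <- min(v, na.rm = TRUE)
  z_max <- max(v, na.rm = TRUE)
  n_levels <- if (anyNA(v)) 65534 else 65535
  z_scale <- if (z_max > z_min) (z_max - z_min) / n_levels else 1
  lv <- round((v - z_min) / z_scale)
  elev_raster(lv, raster$origin, raster$pixel_size, quantized = TRUE,
              z_min = z_min, z_scale = z_scale)
}

#' Restore metric elevations from a quantized raster
#'
#' Inverts [quantize()]: elevation = z_min + level * z_scale. The second
#' quantize/dequantize round trip is exact (levels are fixed points).
#'
#' @param raster a quantized [elev_raster()].
#' @return the dequantized `elev_raster` (metres).
#' @export
dequantize <- function(raster) {
  stopifnot(inherits(raster, "elev_raster"))
  if (!raster$quantized) stop("raster is not quantized")
  if (is.null(raster$z_min) || is.null(raster$z_scale))
    stop("quantization metadata (z_min, z_scale) missing")
  elev_raster(raster$z_min + raster$values * raster$z_scale,
              raster$origin, raster$pixel_size, quantized = FALSE)
}

# --- 16-bit greyscale PNG ------------------------------------------------

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32_cpp(body)
  c(writeBin(length(data), raw(), size = 4L, endian = "big"),
    body,
    writeBin(as.integer(crc %% 2^32 - (crc >= 2^31) * 2^32), raw(),
             size = 4L, endian = "big"))
}

write_png_gray16 <- function(levels, path) {
  nr <- nrow(levels); nc <- ncol(levels)
  lv <- as.integer(t(levels))  # row-major scanlines
  hi <- as.raw(lv %/% 256L)
  lo <- as.raw(lv %% 256L)
  scan_data <- matrix(raw(), nrow = 2L * nc + 1L, ncol = nr)
  scan_data[1L, ] <- as.raw(0L)  # filter type 0 per scanline
  scan_data[seq(2L, 2L * nc, by = 2L), ] <- matrix(hi, nc, nr)
  scan_data[seq(3L, 2L * nc + 1L, by = 2L), ] <- matrix(lo, nc, nr)
  ihdr <- c(writeBin(c(nc, nr), raw(), size = 4L, endian = "big"),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # 16-bit, greyscale
  idat <- zlib_compress_cpp(as.vector(scan_data), 6L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", 26L)
  if (length(hdr) < 26L ||
      !identical(hdr[1:8], as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))))
    stop("not a PNG file: ", path)
  as.integer(hdr[25L])  # IHDR bit depth byte
}

sidecar_path <- function(path) sub("\\.png$", ".json", path, ignore.case = TRUE)

#' Write and read quantized rasters as 16-bit PNG plus JSON sidecar
#'
#' The PNG stores the 16-bit levels; the sidecar (same path with `.json`
#' extension) stores the georeference and quantization metadata
#' (`origin_x`, `origin_y`, `pixel_size`, `z_min`, `z_scale`,
#' `missing_level`). If the raster has missing pixels they are written as
#' the reserved level 0 with all defined levels shifted up by one (the
#' quantizer leaves headroom for this; `missing_level` records the scheme).
#' The round trip is bit-exact: `read_raster_png(write_raster_png(r))`
#' reproduces levels, mask and metadata.
#'
#' @param raster a quantized [elev_raster()].
#' @param path output PNG path.
#' @return `write_raster_png` returns `path` invisibly; `read_raster_png`
#'   returns the quantized `elev_raster`.
#' @export
write_raster_png <- function(raster, path) {
  stopifnot(inherits(raster, "elev_raster"))
  if (!raster$quantized) stop("raster must be quantized before writing PNG")
  v <- raster$values
  has_missing <- anyNA(v)
  if (has_missing) {
    if (max(v, na.rm = TRUE) > 65534)
      stop("levels exceed 65534; cannot reserve a missing level")
    stored <- v + 1
    stored[is.na(stored)] <- 0
    missing_level <- 0L
  } else {
    if (max(v) > 65535) stop("levels exceed 16-bit range")
    stored <- v
    missing_level <- NULL
  }
  write_png_gray16(stored, path)
  meta <- list(origin_x = raster$origin[1], origin_y = raster$origin[2],
               pixel_size = raster$pixel_size, z_min = raster$z_min,
               z_scale = raster$z_scale,
               missing_level = if (has_missing) missing_level else NA)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_raster_png
#' @export
read_raster_png <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("missing sidecar metadata file: ", side)
  if (png_bit_depth(path) != 16L)
    stop("not a 16-bit PNG: ", path)
  meta <- jsonlite::read_json(side)
  stored <- round(png::readPNG(path) * 65535)
  if (!is.null(meta$missing_level) && !is.na(meta$missing_level)) {
    v <- stored - 1
    v[stored == meta$missing_level] <- NA_real_
  } else {
    v <- stored
  }
  elev_raster(v, origin = c(meta$origin_x, meta$origin_y),
              pixel_size = meta$pixel_size, quantized = TRUE,
              z_min = meta$z_min, z_scale = meta$z_scale)
}
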