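#' Point cloud objects
#'
#' A point cloud is an n x 3 numeric matrix of `(x, y, z)` positions in
#' metres, all in one shared projected (georeferenced) coordinate frame.
#' This is the common input of the rasterization pipeline: one cloud per
#' UAV flight, all flights sharing the frame so that later rasters align
#' pixel-for-pixel with the first one.
#'
#' @param xyz an n x 3 numeric matrix or a data frame with columns
#'   `x`, `y`, `z` (metres).
#' @return an object of class `point_cloud` (an n x 3 matrix with columns
#'   `x`, `y`, `z`).
#' @examples
#' pc <- point_cloud(cbind(runif(10), runif(10), 100 + runif(10)))
#' nrow(pc)
#' @export
point_cloud <- function(xyz) {
  if (is.data.frame(xyz)) xyz <- as.matrix(xyz[, c("x", "y", "z")])
  if (!is.matrix(xyz) || ncol(xyz) != 3L)
    stop("'xyz' must be an n x 3 matrix or a data frame with x, y, z")
  storage.mode(xyz) <- "double"
  if (!all(is.finite(xyz)))
    stop("point cloud contains non-finite coordinates")
  colnames(xyz) <- c("x", "y", "z")
  class(xyz) <- c("point_cloud", class(xyz))
  xyz
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points\n", nrow(x)))
  cat(sprintf("  x: [%.3f, %.3f] m  y: [%.3f, %.3f] m  z: [%.3f, %.3f] m\n",
              min(x[, 1]), max(x[, 1]), min(x[, 2]), max(x[, 2]),
              min(x[, 3]), max(x[, 3])))
  invisible(x)
}

as_point_cloud <- function(x) {
  if (inherits(x, "point_cloud")) x else point_cloud(x)
}

#' Remove outlier points by central-mass quantile trimming
#'
#' Keeps exactly the points whose x, y and z coordinates each lie within the
#' central `central_mass` probability interval of that coordinate's empirical
#' distribution, i.e. between the `(1 - central_mass)/2` and
#' `1 - (1 - central_mass)/2` empirical quantiles (inclusive). Stray returns
#' (birds, multipath echoes) sit in the far tails of z and occasionally x/y,
#' so symmetric trimming of a tiny tail mass removes them without touching
#' the canopy.
#'
#' @param cloud a [point_cloud()] (or coercible matrix).
#' @param central_mass fraction of the central probability mass to retain in
#'   each coordinate, in (0, 1]. The default keeps 99.9%.
#' @return the filtered `point_cloud`.
#' @examples
#' pc <- point_cloud(cbind(runif(1000), runif(1000), runif(1000)))
#' bad <- point_cloud(rbind(unclass(pc), c(0.5, 0.5, 1000)))
#' nrow(filter_outliers(bad))
#' @export
filter_outliers <- function(cloud, central_mass = 0.999) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) == 0L) stop("empty point cloud")
  if (!is.numeric(central_mass) || central_mass <= 0 || central_mass > 1)
    stop("'central_mass' must be in (0, 1]")
  if (central_mass == 1) return(cloud)
  tail <- (1 - central_mass) / 2
  keep <- rep(TRUE, nrow(cloud))
  for (j in 1:3) {
    q <- stats::quantile(cloud[, j], c(tail, 1 - tail), names = FALSE)
    keep <- keep & cloud[, j] >= q[1] & cloud[, j] <= q[2]
  }
  point_cloud(unclass(cloud)[keep, , drop = FALSE])
}

#' Read and write point clouds as plain XYZ text
#'
#' The XYZ dialect is one point per line, `x y z` in metres, whitespace or
#' comma separated; lines starting with `#` are skipped. It is the
#' format-agnostic interchange used throughout the test-suite.
#'
#' @param path file path.
#' @param cloud a [point_cloud()].
#' @return `read_xyz` returns a `point_cloud`; `write_xyz` returns `path`
#'   invisibly.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty point cloud file: ", path)
  lines <- gsub(",", " ", lines, fixed = TRUE)
  vals <- scan(text = lines, what = numeric(), quiet = TRUE)
  if (length(vals) %% 3L != 0L)
    stop("malformed XYZ file (not a multiple of 3 values): ", path)
  point_cloud(matrix(vals, ncol = 3L, byrow = TRUE))
}

#' @rdname read_xyz
#' @export
write_xyz <- function(cloud, path) {
  cloud <- as_point_cloud(cloud)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%.6f %.6f %.6f",
                     cloud[, 1], cloud[, 2], cloud[, 3]), con)
  invisible(path)
}

# --- minimal LAS 1.2 binary I/O (point record format 0) ------------------
#
# Only the subset needed to exchange plain xyz clouds with LiDAR processing
# chains: public header block (227 bytes), point format 0 (20-byte records),
# scaled int32 coordinates. No variable-length records, no colour, no LAZ.

LAS_HEADER_SIZE <- 227L
LAS_P0_SIZE <- 20L

#' Read and write point clouds in the LAS 1.2 binary format
#'
#' A deliberately small LAS implementation: version 1.2, point data record
#' format 0, coordinates stored as scaled 32-bit integers. `write_las` picks
#' offsets at the coordinate minima and the given `scale` (metres per
#' integer step, default 1 mm, the conventional LiDAR quantization).
#' Compressed LAZ is not supported.
#'
#' @param path file path.
#' @param cloud a [point_cloud()].
#' @param scale coordinate scale in metres per integer step.
#' @return `read_las` returns a `point_cloud`; `write_las` returns `path`
#'   invisibly. Round-tripping reproduces coordinates to within `scale/2`.
#' @export
read_las <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- rawToChar(readBin(con, "raw", 4L))
  if (sig != "LASF") stop("not a LAS file (bad signature): ", path)
  seek(con, 24L)
  ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  seek(con, 96L)
  offset_to_points <- readBin(con, "integer", 1L, size = 4L)
  seek(con, 104L)
  pdr_format <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
  pdr_length <- readBin(con, "integer", 1L, size = 2L, signed = FALSE)
  n_points <- readBin(con, "integer", 1L, size = 4L)
  if (pdr_format != 0L)
    stop("unsupported LAS point format ", pdr_format, " (only 0 supported)")
  seek(con, 131L)
  scales <- readBin(con, "double", 3L)
  offs <- readBin(con, "double", 3L)
  seek(con, offset_to_points)
  rec <- readBin(con, "raw", n_points * pdr_length)
  idx <- rep(seq(0L, by = pdr_length, length.out = n_points), each = 12L) +
    rep(1:12, times = n_points)
  xyz_int <- readBin(rec[idx], "integer", 3L * n_points, size = 4L)
  m <- matrix(xyz_int, ncol = 3L, byrow = TRUE)
  point_cloud(cbind(m[, 1] * scales[1] + offs[1],
                    m[, 2] * scales[2] + offs[2],
                    m[, 3] * scales[3] + offs[3]))
}

#' @rdname read_las
#' @export
write_las <- function(cloud, path, scale = 0.001) {
  cloud <- as_point_cloud(cloud)
  n <- nrow(cloud)
  offs <- c(min(cloud[, 1]), min(cloud[, 2]), min(cloud[, 3]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("LASF"), con)
  writeBin(rep(0L, 2L), con, size = 2L)            # source id, encoding
  writeBin(raw(8L), con)                           # project GUID 1-3
  writeBin(raw(8L), con)                           # project GUID 4
  writeBin(c(1L, 2L), con, size = 1L)              # version 1.2
  writeBin(charToRaw(sprintf("%-32s", "fieldchm")), con)
  writeBin(charToRaw(sprintf("%-32s", "fieldchm")), con)
  writeBin(c(1L, 2024L), con, size = 2L)           # day, year
  writeBin(LAS_HEADER_SIZE, con, size = 2L)        # header size
  writeBin(LAS_HEADER_SIZE, con, size = 4L)        # offset to point data
  writeBin(0L, con, size = 4L)                     # number of VLRs
  writeBin(0L, con, size = 1L)                     # point format 0
  writeBin(LAS_P0_SIZE, con, size = 2L)            # record length
  writeBin(n, con, size = 4L)                      # number of points
  writeBin(rep(0L, 5L), con, size = 4L)            # points by return
  writeBin(rep(scale, 3L), con)                    # x/y/z scale
  writeBin(offs, con)                              # x/y/z offset
  writeBin(c(max(cloud[, 1]), offs[1],
             max(cloud[, 2]), offs[2],
             max(cloud[, 3]), offs[3]), con)       # max/min x, y, z
  xyz_int <- cbind(as.integer(round((cloud[, 1] - offs[1]) / scale)),
                   as.integer(round((cloud[, 2] - offs[2]) / scale)),
                   as.integer(round((cloud[, 3] - offs[3]) / scale)))
  tail_bytes <- raw(8L)                            # intensity..point source
  rec <- vapply(seq_len(n), function(i) {
    c(writeBin(xyz_int[i, ], raw(), size = 4L), tail_bytes)
  }, raw(LAS_P0_SIZE))
  writeBin(as.vector(rec), con)
  invisible(path)
}

#' Read a point cloud, dispatching on the file extension
#'
#' `.las` goes through [read_las()]; anything else is treated as XYZ text.
#' @param path file path.
#' @return a `point_cloud`.
#' @export
read_point_cloud <- function(path) {
  if (grepl("\\.las$", path, ignore.case = TRUE)) read_las(path)
  else read_xyz(path)
}
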