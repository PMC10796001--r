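#' Region-of-interest specification
#'
#' A reproducible, config-driven replacement for interactive ROI selection:
#' the raster is first rotated counter-clockwise about its centre, then
#' cropped to a pixel rectangle. Applying the same `roi_spec` to every
#' flight of a series (all rasterized on the shared time-zero grid) yields
#' pixel-aligned rasters.
#'
#' @param rotation_deg counter-clockwise rotation in degrees.
#' @param crop integer `c(row_start, row_stop, col_start, col_stop)`,
#'   0-based half-open pixel bounds in the rotated raster, or `NULL` for
#'   the full extent.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(rotation_deg = 0, crop = NULL) {
  if (!is.null(crop)) {
    crop <- as.integer(crop)
    if (length(crop) != 4L || crop[2] <= crop[1] || crop[4] <= crop[3])
      stop("'crop' must be c(row_start, row_stop, col_start, col_stop), stop > start")
    if (any(crop[c(1, 3)] < 0L)) stop("'crop' starts must be >= 0")
  }
  structure(list(rotation_deg = rotation_deg, crop = crop),
            class = "roi_spec")
}

rot90_exact <- function(m, quarter_turns) {
  switch(as.character(quarter_turns %% 4L),
         "0" = m,
         "1" = t(m[, rev(seq_len(ncol(m))), drop = FALSE]),
         "2" = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
         "3" = t(m)[, rev(seq_len(nrow(m))), drop = FALSE])
}

rotate_values <- function(v, angle_deg) {
  if (angle_deg %% 90 == 0) return(rot90_exact(v, as.integer(angle_deg / 90)))
  a <- angle_deg * pi / 180
  nr <- nrow(v); nc <- ncol(v)
  w_o <- ceiling(abs(nc * cos(a)) + abs(nr * sin(a)))
  h_o <- ceiling(abs(nr * cos(a)) + abs(nc * sin(a)))
  cr_o <- (h_o + 1) / 2; cc_o <- (w_o + 1) / 2
  cr_i <- (nr + 1) / 2; cc_i <- (nc + 1) / 2
  g <- expand.grid(r = seq_len(h_o), c = seq_len(w_o))
  dx_o <- g$c - cc_o; dy_o <- -(g$r - cr_o)
  dx_i <- cos(a) * dx_o + sin(a) * dy_o
  dy_i <- -sin(a) * dx_o + cos(a) * dy_o
  out <- bilinear_cpp(v, -dy_i + cr_i, dx_i + cc_i, FALSE)
  matrix(out, h_o, w_o)
}

#' Rotate and crop a raster to the region of interest
#'
#' Rotation by multiples of 90 degrees is exact (pure index permutation);
#' other angles use bilinear resampling onto the rotated bounding box, with
#' pixels that fall outside the source marked missing. The crop is applied
#' after rotation and must lie inside the rotated raster. For zero rotation
#' the georeference origin is updated so pixel-to-field coordinate mapping
#' stays exact; for rotated rasters the applied transform is recorded in
#' the `"roi_transform"` attribute.
#'
#' @param raster an [elev_raster()].
#' @param roi a [roi_spec()].
#' @return the transformed `elev_raster`.
#' @export
rotate_and_crop <- function(raster, roi) {
  stopifnot(inherits(raster, "elev_raster"), inherits(roi, "roi_spec"))
  v <- rotate_values(raster$values, roi$rotation_deg)
  crop <- roi$crop
  if (is.null(crop)) crop <- c(0L, nrow(v), 0L, ncol(v))
  if (crop[2] > nrow(v) || crop[4] > ncol(v))
    stop(sprintf("crop [%d,%d)x[%d,%d) exceeds rotated raster %d x %d",
                 crop[1], crop[2], crop[3], crop[4], nrow(v), ncol(v)))
  vc <- v[(crop[1] + 1L):crop[2], (crop[3] + 1L):crop[4], drop = FALSE]
  if (roi$rotation_deg %% 360 == 0) {
    origin <- c(raster$origin[1] + crop[3] * raster$pixel_size,
                raster$origin[2] - crop[1] * raster$pixel_size)
    out <- elev_raster(vc, origin, raster$pixel_size,
                       quantized = raster$quantized,
                       z_min = raster$z_min, z_scale = raster$z_scale)
  } else {
    out <- elev_raster(vc, raster$origin, raster$pixel_size,
                       quantized = raster$quantized,
                       z_min = raster$z_min, z_scale = raster$z_scale)
    attr(out, "roi_transform") <- list(angle_deg = roi$rotation_deg,
                                       src_dim = dim(raster$values),
                                       crop = crop)
  }
  out
}

#' Field coordinates of raster pixel centres
#'
#' Maps 1-based (row, col) pixel centres to georeferenced (x, y) metres,
#' undoing any ROI rotation recorded on the raster.
#'
#' @param raster an [elev_raster()].
#' @param row,col pixel indices (vectorized, may be fractional).
#' @return a two-column matrix of (x, y).
#' @export
px_to_xy <- function(raster, row, col) {
  tr <- attr(raster, "roi_transform")
  if (!is.null(tr)) {
    row <- row + tr$crop[1]; col <- col + tr$crop[3]
    a <- tr$angle_deg * pi / 180
    nr <- tr$src_dim[1]; nc <- tr$src_dim[2]
    if (tr$angle_deg %% 90 == 0) {
      q <- as.integer(tr$angle_deg / 90) %% 4L
      d_o <- switch(as.character(q),
                    "0" = dim(raster$values),
                    "1" = c(nc, nr), "2" = c(nr, nc), "3" = c(nc, nr))
      h_o <- d_o[1]; w_o <- d_o[2]
    } else {
      w_o <- ceiling(abs(nc * cos(a)) + abs(nr * sin(a)))
      h_o <- ceiling(abs(nr * cos(a)) + abs(nc * sin(a)))
    }
    dx_o <- col - (w_o + 1) / 2; dy_o <- -(row - (h_o + 1) / 2)
    dx_i <- cos(a) * dx_o + sin(a) * dy_o
    dy_i <- -sin(a) * dx_o + cos(a) * dy_o
    row <- -dy_i + (nr + 1) / 2
    col <- dx_i + (nc + 1) / 2
  }
  cbind(x = raster$origin[1] + (col - 0.5) * raster$pixel_size,
        y = raster$origin[2] - (row - 0.5) * raster$pixel_size)
}

# local maxima of d exceeding `prom`, thinned so kept peaks are at least
# `sep` apart (strongest first)
find_peaks <- function(d, prom, sep) {
  n <- length(d)
  if (n == 0L) return(integer(0))
  left <- c(-Inf, d[-n]); right <- c(d[-1], -Inf)
  cand <- which(d > prom & d >= left & d >= right)
  if (length(cand) <= 1L || sep <= 1) return(cand)
  keep <- logical(length(d))
  for (i in cand[order(-d[cand])]) {
    lo <- max(1L, i - sep + 1L); hi <- min(n, i + sep - 1L)
    if (!any(keep[lo:hi])) keep[i] <- TRUE
  }
  which(keep)
}

#' Projection profile and plot-edge detection
#'
#' Collapses the raster to a 1D profile (per-column means for
#' `axis = "cols"`, per-row means for `"rows"`), normalizes it to `[0, 1]`,
#' and detects plot edges in its first difference: a left (start) edge is a
#' positive derivative peak, a right (stop) edge a negative one, each
#' required to exceed `min_prominence` in magnitude and to be at least
#' `min_separation` pixels from a stronger peak of the same sign. Edges are
#' reduced to an alternating start/stop sequence (strongest kept within
#' runs) and returned as 0-based half-open interval bounds. Assumes an
#' elevation scale on which plots are higher than alleys (e.g. a canopy
#' height model of a grown crop).
#'
#' @param raster an [elev_raster()] with no missing pixels, or a matrix.
#' @param axis `"cols"` to profile across columns (vertical plot edges) or
#'   `"rows"` (horizontal block edges).
#' @param min_prominence minimum derivative magnitude, as a fraction of the
#'   normalized profile range.
#' @param min_separation minimum pixel distance between same-sign peaks.
#' @return an object of class `edge_profile`: list with `sums`,
#'   `derivative`, `left_edges`, `right_edges`.
#' @export
edge_profile <- function(raster, axis = c("cols", "rows"),
                         min_prominence = 0.1, min_separation = 2) {
  axis <- match.arg(axis)
  v <- if (inherits(raster, "elev_raster")) raster$values else raster
  if (anyNA(v)) stop("raster must be fully defined (impute first)")
  s <- if (axis == "cols") colMeans(v) else rowMeans(v)
  if (length(s) < 2L) stop("fewer than 2 profile samples")
  rng <- range(s)
  if (rng[2] - rng[1] <= 0) stop("flat profile: no edges detected")
  s <- (s - rng[1]) / (rng[2] - rng[1])
  d <- diff(s)
  lefts <- find_peaks(d, min_prominence, min_separation)
  rights <- find_peaks(-d, min_prominence, min_separation)
  if (length(lefts) == 0L || length(rights) == 0L)
    stop("no edges detected (prominence ", min_prominence, ")")
  # enforce alternation: within a run of same-sign edges keep the strongest
  ev <- rbind(data.frame(pos = lefts, left = TRUE, mag = d[lefts]),
              data.frame(pos = rights, left = FALSE, mag = -d[rights]))
  ev <- ev[order(ev$pos), ]
  run <- cumsum(c(TRUE, ev$left[-1] != ev$left[-nrow(ev)]))
  ev <- do.call(rbind, lapply(split(ev, run),
                              function(g) g[which.max(g$mag), ]))
  if (!ev$left[1]) ev <- ev[-1, , drop = FALSE]
  if (nrow(ev) > 0L && ev$left[nrow(ev)]) ev <- ev[-nrow(ev), , drop = FALSE]
  if (nrow(ev) == 0L) stop("no complete plot intervals detected")
  structure(list(sums = s, derivative = d,
                 left_edges = ev$pos[ev$left],
                 right_edges = ev$pos[!ev$left]),
            class = "edge_profile")
}

#' @export
print.edge_profile <- function(x, ...) {
  cat(sprintf("<edge_profile> %d samples, %d intervals\n",
              length(x$sums), length(x$left_edges)))
  invisible(x)
}

#' Fit the skew of plot columns within a block
#'
#' Field plots imaged as parallelograms share, within one block, a common
#' shear: plot boundaries drift east-west along the plot length. The shear
#' is estimated by a 1-parameter search: candidate shears are applied in
#' reverse and the one maximizing the sharpness (sum of squared first
#' differences) of the resulting column-mean profile is returned, grid
#' search followed by golden-section refinement. The coefficient is
#' expressed as eastward offset per unit northward distance (so it matches
#' the convention of [field_design()]'s `skew_shear`); 0 means the block is
#' already rectangular.
#'
#' @param raster an [elev_raster()] or matrix covering (at least) the block.
#' @param block_rect optional 0-based half-open `c(row_start, row_stop,
#'   col_start, col_stop)` restricting the fit to one block.
#' @param shear_range search interval.
#' @param n_grid number of coarse grid points.
#' @return the fitted shear coefficient (dimensionless).
#' @export
fit_parallelogram <- function(raster, block_rect = NULL,
                              shear_range = c(-0.15, 0.15), n_grid = 31L) {
  v <- if (inherits(raster, "elev_raster")) raster$values else raster
  if (anyNA(v)) stop("raster must be fully defined")
  if (!is.null(block_rect))
    v <- v[(block_rect[1] + 1L):block_rect[2],
           (block_rect[3] + 1L):block_rect[4], drop = FALSE]
  if (max(v) - min(v) <= 0) stop("degenerate block: uniform values")
  sharpness <- function(s) {
    corr <- shear_values(v, s, ref_row = nrow(v))
    sum(diff(colMeans(corr))^2)
  }
  grid <- seq(shear_range[1], shear_range[2], length.out = n_grid)
  scores <- vapply(grid, sharpness, numeric(1))
  i <- which.max(scores)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(n_grid, i + 1L)]
  opt <- stats::optimize(sharpness, c(lo, hi), maximum = TRUE,
                         tol = 1e-4)
  opt$maximum
}

# Undo a field-convention shear of `shear` (eastward offset per unit
# northward distance): out[r, c] = in[r, c - shear * (r - ref_row)].
# Row index grows southward, so this samples further west on northern rows.
shear_values <- function(v, shear, ref_row) {
  if (shear == 0) return(v)
  nr <- nrow(v); nc <- ncol(v)
  shift <- -shear * (seq_len(nr) - ref_row)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr) + rep(shift, times = nc)
  matrix(bilinear_cpp(v, rows, cols, TRUE), nr, nc)
}

#' Shear a raster horizontally (affine rectification)
#'
#' Displaces each row east-west by `shear * (northward distance from the
#' reference row)`, with linear interpolation and border replication; the
#' output keeps the input shape. Applying the negated shear of
#' [fit_parallelogram()] turns skewed parallelogram plots back into
#' rectangles; composing with the inverse shear returns the original
#' raster up to interpolation error.
#'
#' @param raster an [elev_raster()] or matrix.
#' @param shear shear coefficient (eastward offset per unit northward
#'   distance).
#' @param rows optional 1-based row range (two-vector) to restrict the
#'   transform to a horizontal band (e.g. one block); other rows are
#'   untouched.
#' @param ref_row reference row that stays fixed (default: last row of the
#'   transformed band, i.e. its south edge).
#' @return object of the same type as the input.
#' @export
apply_affine <- function(raster, shear, rows = NULL, ref_row = NULL) {
  if (!is.finite(shear)) stop("'shear' must be finite")
  is_raster <- inherits(raster, "elev_raster")
  v <- if (is_raster) raster$values else raster
  if (is.null(rows)) rows <- c(1L, nrow(v))
  band <- rows[1]:rows[2]
  if (is.null(ref_row)) ref_row <- length(band)
  v[band, ] <- shear_values(v[band, , drop = FALSE], -shear, ref_row)
  if (is_raster) {
    out <- raster
    out$values <- v
    out
  } else v
}

#' Plot segmentation of a field raster
#'
#' Detects block bands from the row profile and plot intervals from the
#' per-block column profiles (optionally after per-block shear
#' rectification), and combines them into disjoint pixel rectangles, one
#' per field plot. Plots are indexed row-major: `block` 1 is the
#' northernmost band, `variant` 1 the westernmost plot within its block.
#'
#' @param raster a fully defined [elev_raster()] on a scale where plots are
#'   higher than alleys (typically a late-season canopy height model).
#' @param expected_blocks,expected_plots_per_block if given, segmentation
#'   fails with an informative error when the detected counts disagree.
#' @param min_prominence passed to [edge_profile()].
#' @param correct_shear estimate and correct a per-block shear
#'   ([fit_parallelogram()]) before detecting plot columns.
#' @param shear_range search range for the shear fit.
#' @return an object of class `plot_segmentation`: list with `plots` (data
#'   frame: variant, block, row_start, row_stop, col_start, col_stop;
#'   0-based half-open), `block_shear` (one coefficient per block) and
#'   `shape` (raster dimensions).
#' @export
segment_plots <- function(raster, expected_blocks = NULL,
                          expected_plots_per_block = NULL,
                          min_prominence = 0.1, correct_shear = FALSE,
                          shear_range = c(-0.15, 0.15)) {
  v <- if (inherits(raster, "elev_raster")) raster$values else raster
  if (anyNA(v)) stop("raster must be fully defined (impute first)")
  # block bands from the row profile
  row_sep <- if (!is.null(expected_blocks))
    max(2L, floor(nrow(v) / expected_blocks / 2)) else 2L
  pr <- edge_profile(v, "rows", min_prominence, row_sep)
  n_blocks <- length(pr$left_edges)
  if (!is.null(expected_blocks) && n_blocks != expected_blocks)
    stop(sprintf("detected %d blocks but expected %d",
                 n_blocks, expected_blocks))
  plots <- NULL
  block_shear <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    r0 <- pr$left_edges[b]; r1 <- pr$right_edges[b]
    band <- v[(r0 + 1L):r1, , drop = FALSE]
    if (correct_shear) {
      block_shear[b] <- fit_parallelogram(band, shear_range = shear_range)
      band <- shear_values(band, block_shear[b], ref_row = nrow(band))
    }
    col_sep <- if (!is.null(expected_plots_per_block))
      max(2L, floor(ncol(v) / expected_plots_per_block / 2)) else 2L
    pc <- edge_profile(band, "cols", min_prominence, col_sep)
    n_plots <- length(pc$left_edges)
    if (!is.null(expected_plots_per_block) &&
        n_plots != expected_plots_per_block)
      stop(sprintf("detected %d plots in block %d but expected %d",
                   n_plots, b, expected_plots_per_block))
    plots <- rbind(plots, data.frame(
      variant = seq_len(n_plots), block = b,
      row_start = r0, row_stop = r1,
      col_start = pc$left_edges, col_stop = pc$right_edges))
  }
  seg <- structure(list(plots = plots, block_shear = block_shear,
                        shape = dim(v)),
                   class = "plot_segmentation")
  stopifnot_disjoint(seg)
  seg
}

stopifnot_disjoint <- function(seg) {
  p <- seg$plots
  n <- nrow(p)
  if (n < 2L) return(invisible(TRUE))
  o <- order(p$block, p$col_start)
  p <- p[o, ]
  same <- p$block[-n] == p$block[-1]
  if (any(same & p$col_stop[-n] > p$col_start[-1]))
    stop("internal error: overlapping plot rectangles")
  invisible(TRUE)
}

#' @export
print.plot_segmentation <- function(x, ...) {
  cat(sprintf("<plot_segmentation> %d plots in %d block(s), raster %d x %d\n",
              nrow(x$plots), length(x$block_shear),
              x$shape[1], x$shape[2]))
  if (any(x$block_shear != 0))
    cat("  block shear:", paste(signif(x$block_shear, 3), collapse = ", "),
        "\n")
  invisible(x)
}

#' Rectify all blocks of a raster with the shears stored in a segmentation
#'
#' Applies each block's fitted shear correction to the corresponding row
#' band, so that rasters from other flights align with the rectangles of
#' [segment_plots()].
#'
#' @param raster an [elev_raster()] or matrix with the segmentation's shape.
#' @param seg a [segment_plots()] result.
#' @return the rectified raster.
#' @export
rectify_blocks <- function(raster, seg) {
  stopifnot(inherits(seg, "plot_segmentation"))
  out <- raster
  p <- seg$plots
  for (b in seq_along(seg$block_shear)) {
    if (seg$block_shear[b] == 0) next
    rows <- c(p$row_start[p$block == b][1] + 1L,
              p$row_stop[p$block == b][1])
    out <- apply_affine(out, -seg$block_shear[b], rows = rows)
  }
  out
}

#' Shrink segmentation rectangles by a fixed margin
#'
#' Insets every rectangle by `margin` pixels on all four sides, guarding
#' per-plot statistics against boundary pixels that straddle plot and
#' alley.
#'
#' @param seg a [segment_plots()] result.
#' @param margin non-negative inset in pixels.
#' @return the shrunken `plot_segmentation`.
#' @export
shrink_rectangles <- function(seg, margin = 2L) {
  stopifnot(inherits(seg, "plot_segmentation"))
  margin <- as.integer(margin)
  if (margin < 0L) stop("'margin' must be >= 0")
  if (margin == 0L) return(seg)
  p <- seg$plots
  p$row_start <- p$row_start + margin; p$row_stop <- p$row_stop - margin
  p$col_start <- p$col_start + margin; p$col_stop <- p$col_stop - margin
  bad <- p$row_stop <= p$row_start | p$col_stop <= p$col_start
  if (any(bad))
    stop(sprintf("margin %d collapses %d rectangle(s)", margin, sum(bad)))
  seg$plots <- p
  seg
}
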