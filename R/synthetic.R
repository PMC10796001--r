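#' Design of a synthetic field-plot trial
#'
#' Describes the geometry and stochastic settings of a simulated trial:
#' rectangular plots arranged side by side in horizontal blocks, blocks
#' stacked north to south, narrow alleys between plots and wider gaps
#' between blocks, a gently undulating ground surface, and uniform random
#' LiDAR point scatter with additive elevation noise. The defaults
#' reproduce a spring-barley trial of 3 blocks x 48 plots of 1.2 x 9 m
#' (a ~80 x 35 m field).
#'
#' @param n_blocks number of blocks (stacked top/north to bottom/south).
#' @param plots_per_block plots (variants) per block, west to east.
#' @param plot_length_m,plot_width_m plot dimensions in metres (length runs
#'   north-south, width east-west).
#' @param alley_width_m alley between adjacent plots within a block, metres.
#' @param block_gap_m gap between adjacent blocks, metres.
#' @param margin_m bare-ground border around the plot array, metres.
#' @param skew_shear lateral (east-west) offset of plot boundaries per metre
#'   of plot length: 0 means axis-aligned rectangles, a nonzero value skews
#'   every plot into a parallelogram (the terrain itself stays unsheared).
#' @param terrain_amplitude_m,terrain_wavelength_m amplitude and wavelength
#'   of the smooth ground surface, a sum of two orthogonal sinusoids:
#'   `z = base + a sin(2 pi x / w) + a cos(2 pi y / w)`.
#' @param base_elevation_m mean ground elevation, metres.
#' @param point_density_per_m2 LiDAR return density, points per m².
#' @param noise_sd_m standard deviation of additive Gaussian elevation
#'   noise per point, metres.
#' @param seed integer RNG seed; the same design generates bit-identical
#'   clouds.
#' @return an object of class `field_design`.
#' @export
field_design <- function(n_blocks = 3L, plots_per_block = 48L,
                         plot_length_m = 9, plot_width_m = 1.2,
                         alley_width_m = 0.4, block_gap_m = 2,
                         margin_m = 2, skew_shear = 0,
                         terrain_amplitude_m = 0.2,
                         terrain_wavelength_m = 25,
                         base_elevation_m = 100,
                         point_density_per_m2 = 200,
                         noise_sd_m = 0.03, seed = 1L) {
  lens <- c(plot_length_m = plot_length_m, plot_width_m = plot_width_m,
            alley_width_m = alley_width_m, block_gap_m = block_gap_m)
  if (any(lens <= 0)) stop("all plot/alley dimensions must be > 0")
  if (n_blocks < 1L || plots_per_block < 1L)
    stop("need at least one block and one plot per block")
  if (point_density_per_m2 <= 0) stop("'point_density_per_m2' must be > 0")
  if (noise_sd_m < 0) stop("'noise_sd_m' must be >= 0")
  if (terrain_amplitude_m < 0) stop("'terrain_amplitude_m' must be >= 0")
  if (terrain_wavelength_m <= 0) stop("'terrain_wavelength_m' must be > 0")
  d <- list(n_blocks = as.integer(n_blocks),
            plots_per_block = as.integer(plots_per_block),
            plot_length_m = plot_length_m, plot_width_m = plot_width_m,
            alley_width_m = alley_width_m, block_gap_m = block_gap_m,
            margin_m = margin_m, skew_shear = skew_shear,
            terrain_amplitude_m = terrain_amplitude_m,
            terrain_wavelength_m = terrain_wavelength_m,
            base_elevation_m = base_elevation_m,
            point_density_per_m2 = point_density_per_m2,
            noise_sd_m = noise_sd_m, seed = as.integer(seed))
  d$width_m <- 2 * margin_m + plots_per_block * plot_width_m +
    (plots_per_block - 1) * alley_width_m
  d$height_m <- 2 * margin_m + n_blocks * plot_length_m +
    (n_blocks - 1) * block_gap_m
  structure(d, class = "field_design")
}

#' @export
print.field_design <- function(x, ...) {
  cat(sprintf(
    "<field_design> %d blocks x %d plots (%.1f x %.1f m), field %.1f x %.1f m\n",
    x$n_blocks, x$plots_per_block, x$plot_width_m, x$plot_length_m,
    x$width_m, x$height_m))
  cat(sprintf("  terrain +/-%.2f m (wavelength %.0f m), %g pts/m2, noise sd %g m, shear %g\n",
              x$terrain_amplitude_m, x$terrain_wavelength_m,
              x$point_density_per_m2, x$noise_sd_m, x$skew_shear))
  invisible(x)
}

#' Ground-surface elevation of a synthetic field
#'
#' @param design a [field_design()].
#' @param x,y coordinates in metres (vectorized).
#' @return ground elevation in metres.
#' @export
terrain_elevation <- function(design, x, y) {
  a <- design$terrain_amplitude_m
  w <- design$terrain_wavelength_m
  design$base_elevation_m + a * sin(2 * pi * x / w) + a * cos(2 * pi * y / w)
}

# Plot layout in field coordinates (x east, y north, origin at the SW
# corner). Block 1 is the northernmost. Returns one row per plot with the
# unsheared rectangle and the block's shear reference (its south edge).
plot_layout <- function(design) {
  pitch_x <- design$plot_width_m + design$alley_width_m
  grid <- expand.grid(variant = seq_len(design$plots_per_block),
                      block = seq_len(design$n_blocks))
  x0 <- design$margin_m + (grid$variant - 1) * pitch_x
  y_top <- design$height_m - design$margin_m -
    (grid$block - 1) * (design$plot_length_m + design$block_gap_m)
  data.frame(variant = grid$variant, block = grid$block,
             x0 = x0, x1 = x0 + design$plot_width_m,
             y0 = y_top - design$plot_length_m, y1 = y_top)
}

# Sheared corner coordinates of one layout row: x displaced by
# skew_shear * (y - y0) so the south edge stays put.
plot_corners <- function(layout_row, skew_shear) {
  dy <- layout_row$y1 - layout_row$y0
  dx <- skew_shear * dy
  data.frame(
    x1 = layout_row$x0,       y1 = layout_row$y0,
    x2 = layout_row$x1,       y2 = layout_row$y0,
    x3 = layout_row$x1 + dx,  y3 = layout_row$y1,
    x4 = layout_row$x0 + dx,  y4 = layout_row$y1)
}

default_growth <- function() {
  list(A_mean = 0.9, A_rel_amplitude = 0.15, A_jitter = 0.02,
       B_range = c(0.12, 0.18), C_range = c(-7, -5))
}

#' Generate a multi-temporal synthetic LiDAR survey with known truth
#'
#' Simulates one point cloud per flight date over a plot trial. Ground
#' points follow the smooth terrain everywhere; inside each (possibly
#' sheared) plot the returns instead sample the canopy top surface at
#' `terrain + S(t)`, where `S(t) = A / (1 + exp(-B t - C))` with that
#' plot's logistic parameters. Every z gets additive Gaussian noise of sd
#' `noise_sd_m`. Alleys, margins and block gaps contain ground returns
#' only. Point positions are uniform random at the design density, drawn
#' independently per flight (as real repeated scans are).
#'
#' Per-plot asymptotic heights A vary smoothly across the field
#' (`A = A_mean (1 + a sin(2 pi x/W) cos(2 pi y/H))` plus a small random
#' component), emulating spatially correlated growth heterogeneity; B and
#' C are drawn uniformly from their ranges.
#'
#' @param design a [field_design()].
#' @param times flight dates in days since the first flight, strictly
#'   increasing, first usually 0 (pre-emergence ground survey).
#' @param growth list of trajectory settings: `A_mean` (m),
#'   `A_rel_amplitude` (relative spatial modulation of A), `A_jitter`
#'   (relative per-plot random component of A), `B_range` (per-day),
#'   `C_range` (dimensionless). Defaults emulate spring barley reaching
#'   ~0.9 m with mid-growth around day 40.
#' @return a list with `clouds` (list of [point_cloud()], one per time,
#'   each with attribute `time_days`), `truth` (data frame: variant, block,
#'   corner coordinates x1..y4, A, B, C) and `design`.
#' @examples
#' fd <- field_design(n_blocks = 1, plots_per_block = 3, plot_length_m = 4,
#'                    point_density_per_m2 = 50, seed = 7)
#' sim <- generate_field(fd, times = c(0, 20, 40, 60))
#' sim$truth[, c("variant", "A", "B", "C")]
#' @export
generate_field <- function(design, times, growth = default_growth()) {
  stopifnot(inherits(design, "field_design"))
  if (length(times) == 0L) stop("'times' must be non-empty")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(design$seed)

  layout <- plot_layout(design)
  n_plots <- nrow(layout)
  # smooth + small random spatial pattern in A
  cx <- (layout$x0 + layout$x1) / 2
  cy <- (layout$y0 + layout$y1) / 2
  A <- growth$A_mean * (1 + growth$A_rel_amplitude *
                          sin(2 * pi * cx / design$width_m) *
                          cos(2 * pi * cy / design$height_m)) *
    (1 + stats::runif(n_plots, -growth$A_jitter, growth$A_jitter))
  B <- stats::runif(n_plots, growth$B_range[1], growth$B_range[2])
  C <- stats::runif(n_plots, growth$C_range[1], growth$C_range[2])

  corners <- do.call(rbind, lapply(seq_len(n_plots), function(i)
    plot_corners(layout[i, ], design$skew_shear)))
  truth <- cbind(layout[, c("variant", "block")], corners,
                 data.frame(A = A, B = B, C = C))

  n_points <- round(design$point_density_per_m2 *
                      design$width_m * design$height_m)
  clouds <- lapply(times, function(t) {
    x <- stats::runif(n_points, 0, design$width_m)
    y <- stats::runif(n_points, 0, design$height_m)
    z <- terrain_elevation(design, x, y)
    idx <- locate_plot(design, layout, x, y)
    inplot <- !is.na(idx)
    if (any(inplot)) {
      s <- logistic_curve(t, A[idx[inplot]], B[idx[inplot]], C[idx[inplot]])
      z[inplot] <- z[inplot] + s
    }
    if (design$noise_sd_m > 0)
      z <- z + stats::rnorm(n_points, 0, design$noise_sd_m)
    pc <- point_cloud(cbind(x, y, z))
    attr(pc, "time_days") <- t
    pc
  })
  list(clouds = clouds, truth = truth, design = design)
}

# Row index into `layout` of the plot containing each (x, y), NA when in an
# alley/margin/gap. Membership is tested in shear-corrected coordinates.
locate_plot <- function(design, layout, x, y) {
  pitch_x <- design$plot_width_m + design$alley_width_m
  pitch_y <- design$plot_length_m + design$block_gap_m
  # block from y (block 1 at the top)
  y_rel <- design$height_m - design$margin_m - y
  block <- floor(y_rel / pitch_y) + 1
  in_len <- y_rel >= 0 & (y_rel - (block - 1) * pitch_y) <= design$plot_length_m
  ok_b <- in_len & block >= 1 & block <= design$n_blocks
  # shear correction relative to the block's south edge
  y0_block <- design$height_m - design$margin_m -
    (block - 1) * pitch_y - design$plot_length_m
  x_corr <- x - design$skew_shear * (y - y0_block)
  x_rel <- x_corr - design$margin_m
  variant <- floor(x_rel / pitch_x) + 1
  in_wid <- x_rel >= 0 & (x_rel - (variant - 1) * pitch_x) <= design$plot_width_m
  ok <- ok_b & in_wid & variant >= 1 & variant <= design$plots_per_block
  idx <- rep(NA_integer_, length(x))
  idx[ok] <- (block[ok] - 1) * design$plots_per_block + variant[ok]
  idx
}

#' Write and read the ground-truth table of a synthetic field
#'
#' One CSV row per plot: variant, block, the four corner coordinates, and
#' the logistic parameters A, B, C. Reading back reproduces the values.
#'
#' @param truth the `truth` data frame from [generate_field()].
#' @param path CSV path.
#' @return `write_truth_table` returns `path` invisibly; `read_truth_table`
#'   returns the data frame.
#' @export
write_truth_table <- function(truth, path) {
  if (NROW(truth) == 0L) stop("empty truth table")
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.csv(path)
}

#' Evaluate the true canopy height of synthetic plots
#'
#' @param truth truth table from [generate_field()].
#' @param times days since first flight.
#' @return matrix of heights, one row per plot, one column per time.
#' @export
truth_heights <- function(truth, times) {
  out <- vapply(times, function(t)
    logistic_curve(t, truth$A, truth$B, truth$C), numeric(nrow(truth)))
  out <- matrix(out, nrow = nrow(truth))
  dimnames(out) <- list(NULL, paste0("t", times))
  out
}
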