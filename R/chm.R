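#' Maximum filter ("deformable blanket")
#'
#' Replaces every pixel by the maximum over the `window` x `window`
#' neighbourhood centred on it (truncated at the borders). On a rasterized
#' canopy this drapes a tight upper surface over the noisy per-pixel
#' means — neighbouring pixels may sample different depths into the canopy,
#' and the local maximum tracks the canopy top. Output is everywhere >=
#' input.
#'
#' @param raster a fully defined [elev_raster()] (or matrix).
#' @param window odd window width in pixels, >= 1 (1 = identity).
#' @return the filtered raster, same type as the input.
#' @export
max_filter <- function(raster, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("'window' must be odd and >= 1")
  is_raster <- inherits(raster, "elev_raster")
  v <- if (is_raster) raster$values else raster
  if (anyNA(v)) stop("raster must be fully defined (impute first)")
  if (window > 1L) v <- max_filter_cpp(v, window)
  if (is_raster) {
    out <- raster
    out$values <- v
    out
  } else v
}

#' Canopy height model: max-filtered surface minus time-zero ground
#'
#' Builds the CHM (normalized digital surface model) for one flight: the
#' flight's elevation raster is max-filtered to trace the canopy top, the
#' digital elevation model of the first (pre-emergence) flight is
#' subtracted to remove terrain, and the result is clamped below at zero
#' (negative crop height is noise). The DEM is used as-is, not
#' max-filtered, to avoid inflating the ground level; pass it through
#' [max_filter()] first if the opposite convention is wanted.
#'
#' @param raster_t the flight's imputed [elev_raster()] (metres).
#' @param dem_t0 the time-zero imputed raster, same grid.
#' @param window max-filter window (odd pixels); the default 3 spans
#'   0.15 m at the default 0.05 m pixel.
#' @param time_days days since the first flight; stored on the result.
#' @return an `elev_raster` of canopy heights (metres above ground) with
#'   attribute `time_days`.
#' @export
compute_chm <- function(raster_t, dem_t0, window = 3L, time_days = NA_real_) {
  stopifnot(inherits(raster_t, "elev_raster"), inherits(dem_t0, "elev_raster"))
  if (raster_t$quantized || dem_t0$quantized)
    stop("CHM must be computed on dequantized (metric) rasters")
  stopifnot_same_grid(raster_t, dem_t0, "flight raster and DEM")
  if (anyNA(raster_t$values) || anyNA(dem_t0$values))
    stop("rasters must be fully defined (impute first)")
  top <- max_filter(raster_t, window)
  out <- raster_t
  out$values <- pmax(top$values - dem_t0$values, 0)
  attr(out, "time_days") <- time_days
  class(out) <- c("chm", class(out))
  out
}

#' Per-plot height statistics from a canopy height model
#'
#' Computes, for every segmented plot, the mean, standard deviation,
#' median, minimum, maximum and a configurable set of empirical quantiles
#' (linear interpolation between order statistics) of the CHM pixels inside
#' the margin-shrunken plot rectangle.
#'
#' @param chm a [compute_chm()] result (or any `elev_raster` of heights).
#' @param seg a [segment_plots()] result.
#' @param margin pixel inset applied to every rectangle before collecting
#'   pixels (see [shrink_rectangles()]).
#' @param quantiles quantile fractions to report (besides the median).
#' @param time_days flight time; defaults to the CHM's `time_days`
#'   attribute.
#' @return a data frame with one row per plot: `variant`, `block`,
#'   `time_days`, `n_px`, `mean`, `sd`, `median`, `min`, `max` and one
#'   `q<percent>` column per requested quantile.
#' @export
plot_statistics <- function(chm, seg, margin = 2L,
                            quantiles = c(0.1, 0.25, 0.75, 0.9),
                            time_days = NULL) {
  stopifnot(inherits(seg, "plot_segmentation"))
  v <- if (inherits(chm, "elev_raster")) chm$values else chm
  if (is.null(time_days))
    time_days <- attr(chm, "time_days") %||% NA_real_
  p <- shrink_rectangles(seg, margin)$plots
  if (any(p$row_stop > nrow(v)) || any(p$col_stop > ncol(v)))
    stop("segmentation rectangles exceed CHM bounds")
  qn <- paste0("q", formatC(100 * quantiles, format = "g"))
  rows <- lapply(seq_len(nrow(p)), function(i) {
    px <- v[(p$row_start[i] + 1L):p$row_stop[i],
            (p$col_start[i] + 1L):p$col_stop[i]]
    q <- stats::quantile(px, quantiles, names = FALSE, type = 7)
    out <- data.frame(variant = p$variant[i], block = p$block[i],
                      time_days = time_days, n_px = length(px),
                      mean = mean(px), sd = stats::sd(px),
                      median = stats::median(px),
                      min = min(px), max = max(px))
    out[qn] <- as.list(q)
    out
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-plot statistics as a long-format CSV
#'
#' Columns: `variant`, `block`, `time_days`, `stat_name`, `value` — one row
#' per plot, time and statistic.
#'
#' @param stats data frame from [plot_statistics()] (possibly several
#'   flights row-bound together).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_plot_stats <- function(stats, path) {
  id <- c("variant", "block", "time_days")
  stat_cols <- setdiff(names(stats), c(id, "n_px"))
  long <- do.call(rbind, lapply(stat_cols, function(s)
    data.frame(stats[id], stat_name = s, value = stats[[s]])))
  long <- long[order(long$block, long$variant, long$time_days), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format statistics CSV back into wide form
#'
#' @param path CSV written by [write_plot_stats()].
#' @return a wide data frame, one row per plot and time.
#' @export
read_plot_stats <- function(path) {
  long <- utils::read.csv(path)
  wide <- stats::reshape(long, idvar = c("variant", "block", "time_days"),
                         timevar = "stat_name", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
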