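#' Configuration of an end-to-end pipeline run
#'
#' One object holds every tunable of the processing chain, so a run is
#' fully reproducible from its config. Clouds may be given as file paths
#' (XYZ text or LAS) or as in-memory [point_cloud()] objects.
#'
#' @param clouds list of point clouds or character vector of files, one
#'   per flight, all in one shared coordinate frame; the first flight is
#'   the pre-emergence ground survey.
#' @param times_days flight dates in days since the first flight (strictly
#'   increasing; first usually 0). At least 2 for CHMs, >= 4 for growth
#'   fitting.
#' @param pixel_size raster pixel size, metres.
#' @param central_mass outlier filter retention mass (see
#'   [filter_outliers()]).
#' @param impute_window median-imputation window, odd pixels.
#' @param roi a [roi_spec()].
#' @param expected_blocks,expected_plots_per_block layout hints checked by
#'   segmentation (optional).
#' @param min_prominence edge-detection prominence (see [edge_profile()]).
#' @param correct_shear fit and rectify a per-block shear.
#' @param max_window max-filter window, odd pixels.
#' @param margin_px statistics margin in pixels.
#' @param quantiles quantile fractions reported per plot.
#' @param segment_time_index which flight's CHM to segment on (1-based
#'   index into `times_days`); default the last flight, when the canopy
#'   outlines the plots most clearly.
#' @param out_dir output directory for artifacts, or `NULL` to skip
#'   writing.
#' @param seed integer seed for the (few) stochastic steps (fit restarts).
#' @return an object of class `run_config`.
#' @export
run_config <- function(clouds, times_days, pixel_size = 0.05,
                       central_mass = 0.999, impute_window = 3L,
                       roi = roi_spec(), expected_blocks = NULL,
                       expected_plots_per_block = NULL,
                       min_prominence = 0.1, correct_shear = TRUE,
                       max_window = 3L, margin_px = 2L,
                       quantiles = c(0.1, 0.25, 0.75, 0.9),
                       segment_time_index = NULL, out_dir = NULL,
                       seed = 1L) {
  if (length(clouds) != length(times_days))
    stop("need one cloud per time point")
  if (length(times_days) < 2L) stop("need at least 2 time points")
  if (any(diff(times_days) <= 0))
    stop("'times_days' must be strictly increasing")
  if (is.character(clouds) && anyDuplicated(clouds))
    stop("cloud paths must be distinct")
  structure(list(clouds = clouds, times_days = times_days,
                 pixel_size = pixel_size, central_mass = central_mass,
                 impute_window = as.integer(impute_window), roi = roi,
                 expected_blocks = expected_blocks,
                 expected_plots_per_block = expected_plots_per_block,
                 min_prominence = min_prominence,
                 correct_shear = isTRUE(correct_shear),
                 max_window = as.integer(max_window),
                 margin_px = as.integer(margin_px), quantiles = quantiles,
                 segment_time_index = segment_time_index,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [run_config()]; `clouds` must
#' be file paths (relative paths resolve against the YAML's directory) and
#' `roi` is a mapping with `rotation_deg` and optional `crop`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  clouds <- vapply(y$clouds, function(p) {
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }, character(1))
  roi <- roi_spec(rotation_deg = y$roi$rotation_deg %||% 0,
                  crop = y$roi$crop)
  args <- y[setdiff(names(y), c("clouds", "roi"))]
  args <- args[names(args) %in% names(formals(run_config))]
  do.call(run_config, c(list(clouds = clouds, roi = roi), args))
}

write_artifact <- function(manifest, stage, path, params = list()) {
  manifest[[length(manifest) + 1L]] <- list(
    stage = stage, path = path,
    md5 = unname(tools::md5sum(path)), params = params)
  manifest
}

#' Run the full crop-height pipeline
#'
#' Executes, per flight: outlier filtering, rasterization onto the
#' time-zero grid, median imputation, 16-bit quantization (+ PNG artifact),
#' ROI rotation/crop, and CHM construction against the time-zero DEM. The
#' CHM of the configured segmentation flight is segmented into plots (with
#' optional per-block shear rectification, then applied to every flight),
#' per-plot height statistics are extracted for every flight, and the
#' logistic growth model and relative growth rates are fitted per plot. A
#' failed plot fit is flagged, never fatal. When `out_dir` is set, all
#' artifacts (rasters, CSV tables, segmentation JSON) are written along
#' with a manifest listing every file with its stage, md5 and parameters.
#'
#' @param config a [run_config()].
#' @return an object of class `field_growth`; see [coef.field_growth()],
#'   [predict.field_growth()], [plot.field_growth()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_start <- proc.time()[["elapsed"]]
  times <- config$times_days
  n_t <- length(times)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- list()
  log_stage <- function(fmt, ...) message(sprintf(fmt, ...))

  clouds <- lapply(seq_len(n_t), function(i) {
    ci <- config$clouds[[i]]
    if (is.character(ci)) read_point_cloud(ci) else as_point_cloud(ci)
  })

  # rasterize on the frame fixed by the filtered time-zero cloud
  rasters <- vector("list", n_t)
  bbox <- NULL
  for (i in seq_len(n_t)) {
    n_in <- nrow(clouds[[i]])
    pc <- filter_outliers(clouds[[i]], config$central_mass)
    if (is.null(bbox))
      bbox <- c(min(pc[, 1]), max(pc[, 1]), min(pc[, 2]), max(pc[, 2]))
    r <- rasterize(pc, config$pixel_size, bbox = bbox)
    r <- impute_missing(r, config$impute_window)
    log_stage("t=%g d: %d -> %d points, raster %d x %d, %d px unimputable",
              times[i], n_in, nrow(pc), nrow(r$values), ncol(r$values),
              attr(r, "still_missing"))
    if (!is.null(out_dir)) {
      png_path <- file.path(out_dir, sprintf("raster_t%03d.png", i - 1L))
      write_raster_png(quantize(r), png_path)
      manifest <- write_artifact(manifest, "rasterize", png_path,
                                 list(time_days = times[i],
                                      pixel_size = config$pixel_size))
      manifest <- write_artifact(manifest, "rasterize", sidecar_path(png_path))
    }
    rasters[[i]] <- r
  }
  rasters <- lapply(rasters, rotate_and_crop, roi = config$roi)

  dem <- rasters[[1L]]
  chms <- lapply(seq_len(n_t), function(i)
    compute_chm(rasters[[i]], dem, config$max_window, time_days = times[i]))

  seg_i <- config$segment_time_index %||% n_t
  seg <- segment_plots(chms[[seg_i]],
                       expected_blocks = config$expected_blocks,
                       expected_plots_per_block = config$expected_plots_per_block,
                       min_prominence = config$min_prominence,
                       correct_shear = config$correct_shear)
  log_stage("segmented %d plots in %d block(s) on flight %d",
            nrow(seg$plots), length(seg$block_shear), seg_i)
  if (config$correct_shear)
    chms <- lapply(chms, rectify_blocks, seg = seg)
  if (!is.null(out_dir)) {
    seg_path <- file.path(out_dir, "segmentation.json")
    write_segmentation(seg, chms[[seg_i]], seg_path)
    manifest <- write_artifact(manifest, "segment", seg_path,
                               list(min_prominence = config$min_prominence))
  }

  stats <- do.call(rbind, lapply(seq_len(n_t), function(i)
    plot_statistics(chms[[i]], seg, margin = config$margin_px,
                    quantiles = config$quantiles, time_days = times[i])))

  fits <- fit_all(stats, seed = config$seed)
  log_stage("fitted %d/%d plots; %d RGR intervals",
            sum(fits$fits$converged), nrow(fits$fits), nrow(fits$rgr))

  if (!is.null(out_dir)) {
    stats_path <- file.path(out_dir, "plot_stats.csv")
    write_plot_stats(stats, stats_path)
    manifest <- write_artifact(manifest, "statistics", stats_path,
                               list(margin_px = config$margin_px))
    fits_path <- file.path(out_dir, "logistic_fits.csv")
    write_fits(fits, fits_path)
    manifest <- write_artifact(manifest, "growth", fits_path)
    rgr_path <- file.path(out_dir, "rgr.csv")
    write_rgr(fits, rgr_path)
    manifest <- write_artifact(manifest, "growth", rgr_path)
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
  }
  log_stage("pipeline finished in %.1f s",
            proc.time()[["elapsed"]] - t_start)

  structure(list(stats = stats, fits = fits$fits, rgr = fits$rgr,
                 fit_objects = fits$fit_objects, segmentation = seg,
                 times_days = times, config = config,
                 manifest = manifest),
            class = "field_growth")
}

write_segmentation <- function(seg, raster, path) {
  p <- seg$plots
  centre <- px_to_xy(raster, (p$row_start + p$row_stop) / 2 + 0.5,
                     (p$col_start + p$col_stop) / 2 + 0.5)
  nw <- px_to_xy(raster, p$row_start + 0.5, p$col_start + 0.5)
  se <- px_to_xy(raster, p$row_stop + 0.5, p$col_stop + 0.5)
  out <- list(plots = cbind(p, centre_x = centre[, 1], centre_y = centre[, 2],
                            nw_x = nw[, 1], nw_y = nw[, 2],
                            se_x = se[, 1], se_y = se[, 2]),
              block_shear = seg$block_shear,
              rect_convention = "0-based half-open (row_start,row_stop,col_start,col_stop)")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.field_growth <- function(x, ...) {
  cat(sprintf("<field_growth> %d plots x %d flights (days %s)\n",
              nrow(x$fits), length(x$times_days),
              paste(x$times_days, collapse = ", ")))
  cat(sprintf("  logistic fits converged: %d/%d\n",
              sum(x$fits$converged), nrow(x$fits)))
  conv <- x$fits[x$fits$converged, ]
  if (nrow(conv) > 0)
    cat(sprintf("  A: %.2f-%.2f m  B: %.3f-%.3f /day  C: %.1f-%.1f\n",
                min(conv$A), max(conv$A), min(conv$B), max(conv$B),
                min(conv$C), max(conv$C)))
  invisible(x)
}

#' @export
summary.field_growth <- function(object, ...) {
  print(object)
  cat("\nMedian crop height [m] by flight:\n")
  med <- tapply(object$stats$median, object$stats$time_days, stats::median)
  print(round(med, 3))
  cat("\nLogistic parameters (converged plots):\n")
  conv <- object$fits[object$fits$converged, c("A", "B", "C", "rss")]
  print(summary(conv))
  invisible(object)
}

#' Logistic parameters of every plot
#'
#' @param object a [run_pipeline()] result.
#' @param ... unused.
#' @return data frame: variant, block, A, B, C (non-converged plots `NA`).
#' @export
coef.field_growth <- function(object, ...) {
  object$fits[, c("variant", "block", "A", "B", "C")]
}

#' Predicted median crop heights from the fitted growth curves
#'
#' @param object a [run_pipeline()] result.
#' @param times days since first flight (default: the flight dates).
#' @param ... unused.
#' @return matrix, one row per plot, one column per time.
#' @export
predict.field_growth <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$times_days
  f <- object$fits
  out <- vapply(times, function(t) logistic_curve(t, f$A, f$B, f$C),
                numeric(nrow(f)))
  out <- matrix(out, nrow = nrow(f),
                dimnames = list(sprintf("v%d_b%d", f$variant, f$block),
                                paste0("t", times)))
  out
}

#' @export
residuals.field_growth <- function(object, ...) {
  do.call(rbind, lapply(names(object$fit_objects), function(id) {
    fo <- object$fit_objects[[id]]
    data.frame(plot = id, time_days = fo$times,
               residual = stats::residuals(fo))
  }))
}

#' Visualize a pipeline result
#'
#' `type = "heatmap"` draws the field-layout grid of one logistic
#' parameter (spatial growth heterogeneity); `"curves"` overlays the
#' fitted sigmoids of all plots; `"rgr"` shows the distribution of
#' relative growth rates per flight interval.
#'
#' @param x a [run_pipeline()] result.
#' @param type plot type.
#' @param parameter heat-map parameter.
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.field_growth <- function(x, type = c("heatmap", "curves", "rgr"),
                              parameter = "A", ...) {
  type <- match.arg(type)
  if (type == "heatmap") {
    m <- parameter_grid(x$fits, parameter)
    graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    axes = FALSE, main = paste("parameter", parameter),
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  } else if (type == "curves") {
    tt <- seq(min(x$times_days), max(x$times_days), length.out = 100)
    pred <- predict(x, tt)
    graphics::matplot(tt, t(pred), type = "l", lty = 1,
                      col = grDevices::adjustcolor("forestgreen", 0.25),
                      xlab = "days since first flight",
                      ylab = "median crop height [m]", ...)
  } else {
    iv <- interaction(x$rgr$t1, x$rgr$t2, drop = TRUE)
    graphics::boxplot(x$rgr$rgr ~ iv, xlab = "flight interval (t1.t2)",
                      ylab = "RGR [1/day]", ...)
  }
  invisible(x)
}

#' Root-mean-square deviation against reference height measurements
#'
#' Compares pipeline-computed per-plot median crop heights with an
#' independent reference (e.g. manual ruler measurements at surveyed
#' points, or simulation ground truth): matched on variant, block and —
#' when the reference provides it — time, `RMSD = sqrt(mean((computed -
#' reference)^2))`. Several reference points per plot (the typical manual
#' protocol) all compare against that plot's single computed median.
#'
#' @param stats wide statistics table from [plot_statistics()] /
#'   [run_pipeline()] (`$stats`), or a path to a [write_plot_stats()] CSV.
#' @param reference data frame (or CSV path) with columns `variant`,
#'   `block`, `height`, optional `time_days` and `point`.
#' @return a list of class `height_validation`: `rmsd` (metres), `n`
#'   matched pairs, `bias` (mean computed - reference) and `per_block`
#'   breakdown.
#' @export
validate_against_reference <- function(stats, reference) {
  if (is.character(stats)) stats <- read_plot_stats(stats)
  if (is.character(reference)) reference <- utils::read.csv(reference)
  by <- intersect(c("variant", "block", "time_days"), names(reference))
  m <- merge(reference, stats[, c(by, "median")], by = by)
  if (nrow(m) == 0L) stop("no matched plot/time pairs")
  err <- m$median - m$height
  per_block <- do.call(rbind, lapply(split(err, m$block), function(e)
    data.frame(n = length(e), rmsd = sqrt(mean(e^2)), bias = mean(e))))
  per_block <- cbind(block = as.integer(rownames(per_block)), per_block)
  rownames(per_block) <- NULL
  structure(list(rmsd = sqrt(mean(err^2)), n = length(err),
                 bias = mean(err), per_block = per_block),
            class = "height_validation")
}

#' @export
print.height_validation <- function(x, ...) {
  cat(sprintf("<height_validation> RMSD %.4f m (bias %+.4f m) over %d pairs\n",
              x$rmsd, x$bias, x$n))
  invisible(x)
}
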