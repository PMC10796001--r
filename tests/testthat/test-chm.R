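test_that("max filter dilates spikes and matches the sliding-window oracle", {
  # constant raster unchanged
  rc <- elev_raster(matrix(7, 5, 5), c(0, 5), 1)
  expect_equal(max_filter(rc, 3)$values, rc$values)
  # single spike becomes a 3x3 plateau
  m <- matrix(0, 7, 7); m[4, 4] <- 2.5
  got <- max_filter(elev_raster(m, c(0, 7), 1), 3)$values
  expect_equal(got, oracle_max_filter(m, 3))
  expect_equal(sum(got == 2.5), 9)
  expect_error(max_filter(rc, 4), "odd")
})

test_that("max filter equals the brute-force oracle on random rasters", {
  set.seed(14)
  for (i in 1:20) {
    w <- sample(c(3, 5), 1)
    m <- matrix(rnorm(64 * 64), 64, 64)
    got <- max_filter(m, w)
    expect_identical(got, oracle_max_filter(m, w))
    expect_true(all(got >= m))  # monotone: output >= input
  }
})

test_that("CHM subtracts the time-zero ground and clamps at zero", {
  set.seed(15)
  dem <- random_raster(20, 20, 100, 100.4)
  # no growth: CHM identically zero (max filter raises the surface, but
  # subtracting the *same* raster clamps back to >= 0; use window 1)
  chm0 <- compute_chm(dem, dem, window = 1)
  expect_true(all(chm0$values == 0))
  # constant 0.8 m canopy on flat ground
  flat <- elev_raster(matrix(100, 15, 15), c(0, 15), 1)
  canopy <- elev_raster(matrix(100.8, 15, 15), c(0, 15), 1)
  chm <- compute_chm(canopy, flat, window = 3, time_days = 42)
  expect_equal(chm$values, matrix(0.8, 15, 15), tolerance = 1e-12)
  expect_equal(attr(chm, "time_days"), 42)
  # noisy raster below ground clamps to zero, never negative
  noisy <- elev_raster(matrix(rnorm(225, 99.9, 0.05), 15, 15), c(0, 15), 1)
  expect_true(all(compute_chm(noisy, flat, 3)$values >= 0))
  # georeference mismatch is refused
  off <- elev_raster(matrix(100, 15, 15), c(1, 15), 1)
  expect_error(compute_chm(canopy, off, 3), "georeference")
  expect_error(compute_chm(canopy, elev_raster(matrix(1, 3, 3), c(0, 3), 1)),
               "shape")
})

test_that("in-plot median CHM tracks the generator truth on rough terrain", {
  fd <- tiny_design(noise_sd_m = 0)
  times <- c(0, 28, 56, 84)
  sim <- generate_field(fd, times)
  bb <- c(min(sim$clouds[[1]][, 1]), max(sim$clouds[[1]][, 1]),
          min(sim$clouds[[1]][, 2]), max(sim$clouds[[1]][, 2]))
  rasters <- lapply(sim$clouds, function(pc)
    impute_missing(rasterize(pc, 0.05, bbox = bb)))
  chms <- lapply(seq_along(times), function(i)
    compute_chm(rasters[[i]], rasters[[1]], 3, time_days = times[i]))
  seg <- segment_plots(chms[[4]], expected_blocks = 2,
                       expected_plots_per_block = 5)
  th <- truth_heights(sim$truth, times)
  meds <- NULL
  for (i in seq_along(times)) {
    st <- plot_statistics(chms[[i]], seg, margin = 2)
    st <- st[order(st$block, st$variant), ]
    meds <- cbind(meds, st$median)
  }
  # noise-free: max-filter bias is bounded by the terrain slope over one
  # window (~0.05 m/px * 1 px here), so medians sit close above truth
  expect_lt(sqrt(mean((meds - th)^2)), 0.03)
  # monotone truth implies monotone median CHM (noise 0)
  expect_true(all(diff(t(meds)) >= -1e-9))
})

test_that("plot statistics match the order-statistics oracle", {
  seg1 <- structure(list(plots = data.frame(variant = 1L, block = 1L,
                                            row_start = 0L, row_stop = 2L,
                                            col_start = 0L, col_stop = 2L),
                         block_shear = 0, shape = c(2L, 2L)),
                    class = "plot_segmentation")
  # constant plot
  st <- plot_statistics(elev_raster(matrix(0.5, 2, 2), c(0, 2), 1),
                        seg1, margin = 0)
  expect_equal(st$mean, 0.5); expect_equal(st$median, 0.5)
  expect_equal(st$min, 0.5); expect_equal(st$max, 0.5)
  expect_equal(st$sd, 0)
  # four known pixels: type-7 interpolated quantiles
  vals <- c(0.1, 0.2, 0.3, 0.4)
  st2 <- plot_statistics(elev_raster(matrix(vals, 2, 2), c(0, 2), 1),
                         seg1, margin = 0)
  expect_equal(st2$median, 0.25)
  expect_equal(st2$mean, 0.25)
  for (q in c(0.1, 0.25, 0.75, 0.9)) {
    cn <- paste0("q", formatC(100 * q, format = "g"))
    expect_equal(st2[[cn]], unname(quantile(vals, q, type = 7)))
  }
  expect_equal(st2$n_px, 4L)
})

test_that("the 0.5 quantile equals the median on random plots", {
  set.seed(16)
  seg1 <- structure(list(plots = data.frame(variant = 1L, block = 1L,
                                            row_start = 0L, row_stop = 8L,
                                            col_start = 0L, col_stop = 8L),
                         block_shear = 0, shape = c(8L, 8L)),
                    class = "plot_segmentation")
  for (i in 1:50) {
    m <- matrix(runif(64), 8, 8)
    st <- plot_statistics(elev_raster(m, c(0, 8), 1), seg1, margin = 0,
                          quantiles = 0.5)
    expect_equal(st$q50, st$median)
    expect_true(st$min <= st$q50 && st$q50 <= st$max)
  }
})

test_that("plot statistics survive a long-format CSV round trip", {
  fd <- tiny_design()
  sim <- generate_field(fd, times = c(0, 40, 80))
  bb <- c(min(sim$clouds[[1]][, 1]), max(sim$clouds[[1]][, 1]),
          min(sim$clouds[[1]][, 2]), max(sim$clouds[[1]][, 2]))
  rasters <- lapply(sim$clouds, function(pc)
    impute_missing(rasterize(pc, 0.05, bbox = bb)))
  chm <- compute_chm(rasters[[3]], rasters[[1]], 3, time_days = 80)
  seg <- segment_plots(chm, 2, 5)
  st <- plot_statistics(chm, seg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_plot_stats(st, f)
  back <- read_plot_stats(f)
  back <- back[order(back$block, back$variant), ]
  st_o <- st[order(st$block, st$variant), ]
  expect_equal(back$median, st_o$median, tolerance = 1e-12)
  expect_equal(back$q90, st_o$q90, tolerance = 1e-12)
})
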