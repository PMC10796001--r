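# a block-shaped test raster: `n_plots` plateaus of height 1 on background
# 0, `gap` background columns between plateaus and at both ends
plateau_raster <- function(n_plots = 5, width = 10, gap = 4, nr = 30) {
  nc <- n_plots * width + (n_plots + 1) * gap
  m <- matrix(0, nr, nc)
  starts <- gap + (seq_len(n_plots) - 1) * (width + gap)  # 0-based
  body_rows <- (gap + 1):(nr - gap)  # background rows above and below
  for (s in starts) m[body_rows, (s + 1):(s + width)] <- 1
  list(raster = elev_raster(m, c(0, nr * 0.05), 0.05),
       starts = starts, stops = starts + width)
}

test_that("rotation by 0 and 90 degrees is exact", {
  r <- random_raster(7, 11)
  expect_equal(rotate_and_crop(r, roi_spec(0))$values, r$values)
  got <- rotate_and_crop(r, roi_spec(90))$values
  # independent index oracle: out[i, j] = in[j, nc - i + 1]
  want <- matrix(0, 11, 7)
  for (i in 1:11) for (j in 1:7) want[i, j] <- r$values[j, 11 - i + 1]
  expect_equal(got, want)
  # full-turn identity
  expect_equal(rotate_and_crop(r, roi_spec(360))$values, r$values)
})

test_that("crops update the origin and reject out-of-bounds requests", {
  r <- random_raster(10, 10)
  rc <- rotate_and_crop(r, roi_spec(0, crop = c(2, 8, 3, 9)))
  expect_equal(dim(rc$values), c(6L, 6L))
  expect_equal(rc$values, r$values[3:8, 4:9])
  expect_equal(rc$origin, c(r$origin[1] + 3 * 0.05, r$origin[2] - 2 * 0.05))
  expect_error(rotate_and_crop(r, roi_spec(0, crop = c(0, 11, 0, 10))),
               "exceeds")
})

test_that("arbitrary-angle rotation preserves content approximately", {
  # a bright square rotated 45 deg lands centred, values preserved inside
  m <- matrix(0, 41, 41); m[16:26, 16:26] <- 1
  r <- elev_raster(m, c(0, 41), 1)
  rot <- rotate_and_crop(r, roi_spec(45))
  v <- rot$values
  centre <- v[(nrow(v) %/% 2 - 2):(nrow(v) %/% 2 + 2),
              (ncol(v) %/% 2 - 2):(ncol(v) %/% 2 + 2)]
  expect_true(all(centre > 0.99))
  expect_equal(sum(v, na.rm = TRUE), sum(m), tolerance = 0.05)
})

test_that("pixel centres map to field coordinates and back through the ROI", {
  r <- random_raster(8, 12)
  xy <- px_to_xy(r, 1, 1)
  expect_equal(as.numeric(xy),
               c(r$origin[1] + 0.025, r$origin[2] - 0.025))
  # after a 90 deg rotation the mapped coordinates still index the source
  rot <- rotate_and_crop(r, roi_spec(90))
  xy_rot <- px_to_xy(rot, 1, 1)
  # output pixel (1,1) came from source pixel (1, nc): check its centre
  expect_equal(as.numeric(xy_rot),
               c(r$origin[1] + (12 - 0.5) * 0.05, r$origin[2] - 0.025))
})

test_that("edge profiles find plateau edges within one pixel", {
  px <- plateau_raster(5)
  ep <- edge_profile(px$raster, "cols", min_prominence = 0.1,
                     min_separation = 5)
  expect_length(ep$left_edges, 5)
  expect_length(ep$right_edges, 5)
  expect_true(all(abs(ep$left_edges - px$starts) <= 1))
  expect_true(all(abs(ep$right_edges - px$stops) <= 1))
  expect_equal(length(ep$derivative), length(ep$sums) - 1L)
  # constant raster has a flat profile
  expect_error(edge_profile(elev_raster(matrix(1, 5, 9), c(0, 5), 1), "cols"),
               "flat profile")
})

test_that("edge positions are equivariant under translation", {
  px <- plateau_raster(3, gap = 6)
  ep0 <- edge_profile(px$raster, "cols", min_separation = 5)
  k <- 3L
  shifted <- cbind(matrix(0, nrow(px$raster$values), k), px$raster$values)
  epk <- edge_profile(elev_raster(shifted, c(0, 1), 0.05), "cols",
                      min_separation = 5)
  expect_equal(epk$left_edges, ep0$left_edges + k)
  expect_equal(epk$right_edges, ep0$right_edges + k)
})

test_that("segmentation recovers the synthetic layout and truth centres", {
  fd <- tiny_design(noise_sd_m = 0)
  times <- flight_times()
  sim <- generate_field(fd, times)
  r0 <- impute_missing(rasterize(sim$clouds[[1]], 0.05))
  bb <- c(min(sim$clouds[[1]][, 1]), max(sim$clouds[[1]][, 1]),
          min(sim$clouds[[1]][, 2]), max(sim$clouds[[1]][, 2]))
  rT <- impute_missing(rasterize(sim$clouds[[length(times)]], 0.05, bbox = bb))
  chm <- compute_chm(rT, r0, 3)
  seg <- segment_plots(chm, expected_blocks = 2, expected_plots_per_block = 5)
  expect_equal(nrow(seg$plots), 10L)
  # every truth plot centre falls inside exactly one rectangle
  cx <- (sim$truth$x1 + sim$truth$x3) / 2
  cy <- (sim$truth$y1 + sim$truth$y3) / 2
  col <- (cx - chm$origin[1]) / 0.05  # 0-based pixel coords
  row <- (chm$origin[2] - cy) / 0.05
  p <- seg$plots
  hits <- vapply(seq_along(cx), function(i)
    sum(row[i] >= p$row_start & row[i] < p$row_stop &
          col[i] >= p$col_start & col[i] < p$col_stop), integer(1))
  expect_true(all(hits == 1L))
  # wrong expectation is reported with both counts
  expect_error(segment_plots(chm, expected_plots_per_block = 7),
               "detected 5 plots in block 1 but expected 7")
  expect_error(segment_plots(chm, expected_blocks = 3),
               "detected 2 blocks but expected 3")
})

test_that("a single-plot field yields one rectangle over the plateau", {
  px <- plateau_raster(1, width = 30, gap = 10)
  seg <- segment_plots(px$raster)
  expect_equal(nrow(seg$plots), 1L)
  expect_lte(abs(seg$plots$col_start - px$starts), 1)
  expect_lte(abs(seg$plots$col_stop - px$stops), 1)
})

test_that("shear is recovered from a skewed block and rectification is idempotent", {
  fd <- tiny_design(skew_shear = 0.05, noise_sd_m = 0.02)
  sim <- generate_field(fd, times = c(0, 70))
  r0 <- impute_missing(rasterize(sim$clouds[[1]], 0.05))
  bb <- c(min(sim$clouds[[1]][, 1]), max(sim$clouds[[1]][, 1]),
          min(sim$clouds[[1]][, 2]), max(sim$clouds[[1]][, 2]))
  r1 <- impute_missing(rasterize(sim$clouds[[2]], 0.05, bbox = bb))
  chm <- compute_chm(r1, r0, 3)
  seg <- segment_plots(chm, expected_blocks = 2, correct_shear = TRUE)
  expect_true(all(abs(seg$block_shear - 0.05) < 0.005))
  # unskewed block fits ~0
  fd0 <- tiny_design(noise_sd_m = 0.02)
  sim0 <- generate_field(fd0, times = c(0, 70))
  r00 <- impute_missing(rasterize(sim0$clouds[[1]], 0.05))
  r01 <- impute_missing(rasterize(sim0$clouds[[2]], 0.05,
                                  bbox = c(min(sim0$clouds[[1]][, 1]),
                                           max(sim0$clouds[[1]][, 1]),
                                           min(sim0$clouds[[1]][, 2]),
                                           max(sim0$clouds[[1]][, 2]))))
  chm0 <- compute_chm(r01, r00, 3)
  s0 <- fit_parallelogram(chm0$values)
  expect_lt(abs(s0), 0.01)
  # idempotence: re-estimating after rectification gives ~0
  rect <- rectify_blocks(chm, seg)
  p <- seg$plots[seg$plots$block == 1, ][1, ]
  s_again <- fit_parallelogram(rect$values[(p$row_start + 1):p$row_stop, ])
  expect_lt(abs(s_again), 0.005)
  expect_error(fit_parallelogram(matrix(1, 10, 10)), "degenerate")
})

test_that("affine shear composes with its inverse", {
  set.seed(21)
  # smooth raster so interpolation error stays small
  m <- outer(seq(0, 1, length.out = 40), seq(0, 2, length.out = 60),
             function(a, b) sin(3 * a) + cos(2 * b))
  r <- elev_raster(m, c(0, 2), 0.05)
  expect_equal(apply_affine(r, 0)$values, m)
  back <- apply_affine(apply_affine(r, 0.04), -0.04)
  interior <- back$values[5:35, 5:55] - m[5:35, 5:55]
  grad_step <- max(abs(diff(t(m))))
  expect_lte(max(abs(interior)), 2 * grad_step)
  expect_error(apply_affine(r, NA_real_), "finite")
})

test_that("rectangle shrinking is exact arithmetic with guards", {
  seg <- structure(list(plots = data.frame(variant = 1L, block = 1L,
                                           row_start = 0L, row_stop = 10L,
                                           col_start = 0L, col_stop = 100L),
                        block_shear = 0, shape = c(10L, 100L)),
                   class = "plot_segmentation")
  expect_equal(shrink_rectangles(seg, 0), seg)
  s2 <- shrink_rectangles(seg, 2)
  expect_equal(s2$plots$row_stop - s2$plots$row_start, 6L)
  expect_equal(s2$plots$col_stop - s2$plots$col_start, 96L)
  expect_error(shrink_rectangles(seg, 5), "collapses")
  expect_error(shrink_rectangles(seg, -1), ">= 0")
})
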