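test_that("rasterize places single points and averages within pixels", {
  # one point in the middle of a 1-pixel raster
  r <- rasterize(point_cloud(cbind(0.5, 0.5, 1.5)), pixel_size = 1)
  expect_equal(dim(r$values), c(1L, 1L))
  expect_equal(r$values[1, 1], 1.5)
  # two points in the same pixel average; a second pixel stays missing
  pc <- point_cloud(cbind(c(0.2, 0.8, 1.5), c(0.5, 0.5, 1.5), c(1, 3, 7)))
  r2 <- rasterize(pc, pixel_size = 1, bbox = c(0, 2, 0, 2))
  expect_equal(r2$values[2, 1], 2)        # mean of 1 and 3 (south-west pixel)
  expect_equal(r2$values[1, 2], 7)
  expect_true(is.na(r2$values[1, 1]) && is.na(r2$values[2, 2]))
  expect_error(rasterize(pc, pixel_size = 0), "> 0")
})

test_that("rasterize equals the brute-force group-by oracle", {
  set.seed(101)
  for (i in 1:3) {
    xyz <- cbind(runif(500, 0, 7.3), runif(500, 0, 5.1), runif(500, 99, 101))
    r <- rasterize(point_cloud(xyz), pixel_size = 1)
    expect_equal(r$values, oracle_rasterize(xyz, 1), tolerance = 1e-12)
  }
})

test_that("rasterization conserves points across pixels", {
  set.seed(5)
  xyz <- cbind(runif(2000, 0, 10), runif(2000, 0, 10), runif(2000))
  r <- rasterize(point_cloud(xyz), pixel_size = 0.5)
  # re-derive per-pixel counts and check they sum to the cloud size
  col <- pmin(ncol(r$values), floor((xyz[, 1] - r$origin[1]) / 0.5) + 1)
  row <- pmax(1, pmin(nrow(r$values), floor((r$origin[2] - xyz[, 2]) / 0.5) + 1))
  counts <- table(paste(row, col))
  expect_equal(sum(counts), 2000)
  expect_equal(sum(!is.na(r$values)), length(counts))
})

test_that("median imputation fills gaps and iterates to closure", {
  # fully defined raster is unchanged
  r <- random_raster(6, 6)
  expect_equal(impute_missing(r, 3)$values, r$values)
  # centre pixel = median of its 8 neighbours
  m <- matrix(1:9, 3, 3, byrow = TRUE)
  m[2, 2] <- NA
  m[1, ] <- c(1, 2, 3); m[2, c(1, 3)] <- c(4, 5); m[3, ] <- c(6, 7, 8)
  ri <- impute_missing(elev_raster(m * 1.0, c(0, 3), 1), 3)
  expect_equal(ri$values[2, 2], 4.5)
  expect_equal(attr(ri, "still_missing"), 0L)
  # a gap wider than the window closes over several passes
  big <- matrix(2, 11, 11)
  big[4:8, 4:8] <- NA
  rb <- impute_missing(elev_raster(big, c(0, 11), 1), 3)
  expect_false(anyNA(rb$values))
  expect_equal(rb$values, matrix(2, 11, 11))
  expect_error(impute_missing(elev_raster(matrix(NA_real_, 3, 3), c(0, 3), 1)),
               "all pixels missing|nothing to impute")
  expect_error(impute_missing(r, 4), "odd")
})

test_that("iterated imputation matches the explicit neighbourhood oracle", {
  set.seed(33)
  for (i in 1:20) {
    m <- matrix(runif(100, 50, 60), 10, 10)
    m[sample(100, 45)] <- NA
    if (all(is.na(m))) next
    got <- impute_missing(elev_raster(m, c(0, 10), 1), 3)$values
    expect_equal(got, oracle_impute_closure(m, 3), tolerance = 1e-12)
  }
})

test_that("quantization maps endpoints and bounds the round-trip error", {
  # constant raster: zero range convention
  rc <- quantize(elev_raster(matrix(5, 3, 3), c(0, 3), 1))
  expect_true(all(rc$values == 0))
  expect_equal(rc$z_min, 5)
  # endpoints of the range map to 0 and 65535
  re <- quantize(elev_raster(matrix(c(0, 1, 1.5, 2), 2, 2), c(0, 2), 1))
  expect_equal(min(re$values), 0)
  expect_equal(max(re$values), 65535)
  expect_equal(re$z_min + 65535 * re$z_scale, 2)
  expect_error(quantize(re), "already quantized")
  # round-trip error bound on a raster spanning ~10 m
  set.seed(2)
  r <- random_raster(40, 30, 200, 210)
  back <- dequantize(quantize(r))
  expect_lte(max(abs(back$values - r$values)), (10 / 65535) / 2)
  # second round trip is exact (levels are fixed points)
  q1 <- quantize(r)
  q2 <- quantize(dequantize(q1))
  expect_equal(q2$values, q1$values)
  expect_equal(q2$z_scale, q1$z_scale)
  expect_error(dequantize(r), "not quantized")
})

test_that("16-bit PNG round trip is bit-exact with metadata", {
  set.seed(9)
  r <- quantize(random_raster(50, 80, 100, 102))
  f <- withr::local_tempfile(fileext = ".png")
  write_raster_png(r, f)
  back <- read_raster_png(f)
  expect_identical(back$values, r$values)
  expect_equal(back$origin, r$origin)
  expect_equal(back$pixel_size, r$pixel_size)
  expect_equal(back$z_min, r$z_min)
  expect_equal(back$z_scale, r$z_scale)
})

test_that("PNG encoding preserves the missing-pixel mask", {
  set.seed(10)
  m <- matrix(runif(600, 10, 11), 20, 30)
  m[sample(600, 100)] <- NA
  r <- quantize(elev_raster(m, c(0, 20 * 0.05), 0.05))
  f <- withr::local_tempfile(fileext = ".png")
  write_raster_png(r, f)
  back <- read_raster_png(f)
  expect_identical(is.na(back$values), is.na(r$values))
  expect_identical(back$values, r$values)
})

test_that("PNG reader demands the sidecar and 16-bit depth", {
  r <- quantize(random_raster(4, 4))
  f <- withr::local_tempfile(fileext = ".png")
  write_raster_png(r, f)
  file.remove(sub("\\.png$", ".json", f))
  expect_error(read_raster_png(f), "sidecar")
  # an 8-bit PNG is rejected
  f8 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(16), 4, 4), f8)
  jsonlite::write_json(list(origin_x = 0, origin_y = 1, pixel_size = 1,
                            z_min = 0, z_scale = 1, missing_level = NA),
                       sub("\\.png$", ".json", f8), auto_unbox = TRUE,
                       na = "null")
  expect_error(read_raster_png(f8), "16-bit")
})

test_that("a large raster keeps shape and georeference through PNG", {
  set.seed(11)
  r <- quantize(random_raster(300, 400, 99, 101))
  f <- withr::local_tempfile(fileext = ".png")
  write_raster_png(r, f)
  back <- read_raster_png(f)
  expect_equal(dim(back$values), c(300L, 400L))
  expect_equal(back$origin, r$origin)
  expect_equal(back$pixel_size, r$pixel_size)
})
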