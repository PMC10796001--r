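# Brute-force reference implementations, deliberately written with plain
# loops / sort-and-threshold logic, independent of the package internals.

# empirical-quantile outlier filter: explicit sort-and-threshold per axis
oracle_quantile_filter <- function(xyz, central_mass) {
  tail <- (1 - central_mass) / 2
  keep <- rep(TRUE, nrow(xyz))
  for (j in 1:3) {
    lo <- stats::quantile(xyz[, j], tail, names = FALSE)
    hi <- stats::quantile(xyz[, j], 1 - tail, names = FALSE)
    keep <- keep & xyz[, j] >= lo & xyz[, j] <= hi
  }
  xyz[keep, , drop = FALSE]
}

# group-by-pixel mean via floor() bucketing over the cloud's bounding box
oracle_rasterize <- function(xyz, pixel_size) {
  x_min <- min(xyz[, 1]); x_max <- max(xyz[, 1])
  y_min <- min(xyz[, 2]); y_max <- max(xyz[, 2])
  nc <- max(1L, ceiling((x_max - x_min) / pixel_size - 1e-9))
  nr <- max(1L, ceiling((y_max - y_min) / pixel_size - 1e-9))
  m <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      col_pt <- pmin(nc, floor((xyz[, 1] - x_min) / pixel_size) + 1)
      row_pt <- pmax(1, pmin(nr, floor((y_max - xyz[, 2]) / pixel_size) + 1))
      sel <- row_pt == r & col_pt == c
      if (any(sel)) m[r, c] <- mean(xyz[sel, 3])
    }
  }
  m
}

# sliding-window maximum with explicit loops
oracle_max_filter <- function(m, window) {
  k <- window %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rr <- max(1, r - k):min(nr, r + k)
      cc <- max(1, c - k):min(nc, c + k)
      out[r, c] <- max(m[rr, cc])
    }
  }
  out
}

# one median-imputation pass with explicit neighbourhood medians
oracle_impute_once <- function(m, window) {
  k <- window %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!is.na(m[r, c])) next
      rr <- max(1, r - k):min(nr, r + k)
      cc <- max(1, c - k):min(nc, c + k)
      vals <- m[rr, cc]
      vals <- vals[!is.na(vals)]
      if (length(vals) > 0) out[r, c] <- stats::median(vals)
    }
  }
  out
}

oracle_impute_closure <- function(m, window) {
  repeat {
    nxt <- oracle_impute_once(m, window)
    if (identical(is.na(nxt), is.na(m))) return(nxt)
    m <- nxt
  }
}

# independent logistic least-squares estimate: coarse grid + two local
# refinements, no derivative-based optimizer involved
oracle_grid_logistic <- function(times, heights,
                                 A_lim = NULL, B_lim = c(0.02, 0.5),
                                 C_lim = c(-16, -1), n = 15L, rounds = 3L) {
  if (is.null(A_lim)) A_lim <- c(0.7, 1.3) * max(heights)
  best <- NULL
  for (round in seq_len(rounds)) {
    As <- seq(A_lim[1], A_lim[2], length.out = n)
    Bs <- seq(B_lim[1], B_lim[2], length.out = n)
    Cs <- seq(C_lim[1], C_lim[2], length.out = n)
    g <- expand.grid(A = As, B = Bs, C = Cs)
    sse <- vapply(seq_len(nrow(g)), function(i) {
      pred <- g$A[i] / (1 + exp(-g$B[i] * times - g$C[i]))
      sum((pred - heights)^2)
    }, numeric(1))
    i <- which.min(sse)
    best <- c(A = g$A[i], B = g$B[i], C = g$C[i], sse = sse[i])
    shrink <- function(lim, centre) {
      half <- (lim[2] - lim[1]) / n
      c(centre - 1.5 * half, centre + 1.5 * half)
    }
    A_lim <- shrink(A_lim, g$A[i])
    B_lim <- shrink(B_lim, g$B[i])
    C_lim <- shrink(C_lim, g$C[i])
  }
  best
}

# small standard fixtures -------------------------------------------------

tiny_design <- function(seed = 11, ...) {
  defaults <- list(n_blocks = 2L, plots_per_block = 5L, plot_length_m = 4,
                   plot_width_m = 1.2, alley_width_m = 0.4,
                   block_gap_m = 1.5, margin_m = 1.5,
                   point_density_per_m2 = 150, noise_sd_m = 0.02,
                   seed = seed)
  do.call(field_design, utils::modifyList(defaults, list(...)))
}

flight_times <- function() c(0, 14, 28, 42, 56, 70, 84)

random_raster <- function(nr, nc, lo = 0, hi = 1) {
  elev_raster(matrix(stats::runif(nr * nc, lo, hi), nr, nc),
              origin = c(0, nr * 0.05), pixel_size = 0.05)
}

# median CHM per plot joined with the generator truth; returns the error
# matrix (computed - truth) over all plots x times
pipeline_height_errors <- function(sim, fg) {
  times <- fg$times_days
  th <- truth_heights(sim$truth, times)
  med <- stats::reshape(fg$stats[, c("variant", "block", "time_days", "median")],
                        idvar = c("variant", "block"),
                        timevar = "time_days", direction = "wide")
  med <- med[order(med$block, med$variant), ]
  as.matrix(med[, -(1:2)]) - th
}
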