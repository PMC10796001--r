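#' Relative growth rate
#'
#' The logarithmic growth rate per unit time between two measurements:
#' `RGR = (ln s2 - ln s1) / (t2 - t1)`, with heights in metres and times in
#' days. Doubling over one day gives `log(2)`; no change gives 0.
#'
#' @param s1,s2 median crop heights (metres, > 0) at `t1` and `t2`.
#' @param t1,t2 measurement times in days, `t2 > t1`. All arguments are
#'   vectorized.
#' @return the relative growth rate(s), per day.
#' @examples
#' relative_growth_rate(0.2, 0.4, 10, 11)  # log(2)
#' @export
relative_growth_rate <- function(s1, s2, t1, t2) {
  if (any(s1 <= 0) || any(s2 <= 0))
    stop("heights must be > 0 (logarithm undefined at 0)")
  if (any(t2 <= t1)) stop("'t2' must be greater than 't1'")
  (log(s2) - log(s1)) / (t2 - t1)
}

#' Three-parameter logistic growth curve
#'
#' `S(t) = A / (1 + exp(-B t - C))`: `A` is the asymptotic crop height
#' (metres), `B` the growth velocity (per day), `C` the onset/offset term
#' (dimensionless; the inflection sits at `t = -C/B`, where `S = A/2`).
#' Times are days since the first flight.
#'
#' @param t time(s) in days.
#' @param A asymptotic height, metres.
#' @param B growth velocity, per day.
#' @param C onset/offset, dimensionless.
#' @return height(s) in metres.
#' @export
logistic_curve <- function(t, A, B, C) {
  A / (1 + exp(-B * t - C))
}

logistic_start <- function(times, heights) {
  A0 <- 1.05 * max(heights)
  p <- heights / A0
  interior <- p > 0.01 & p < 0.99
  if (sum(interior) >= 2L) {
    y <- log(p[interior] / (1 - p[interior]))
    fit <- stats::lm.fit(cbind(1, times[interior]), y)
    B0 <- fit$coefficients[2]
    C0 <- fit$coefficients[1]
  } else {
    B0 <- NA_real_
  }
  if (!is.finite(B0) || B0 <= 0) {
    B0 <- 0.1
    C0 <- -B0 * stats::median(times)
  }
  c(A = A0, B = unname(B0), C = unname(C0))
}

#' Fit the logistic growth curve to one plot's height series
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints) of
#' `S(t) = A / (1 + exp(-B t - C))` against median crop heights. The fit
#' is multi-start: a data-driven initial guess (`A0 = 1.05 max(S)`; `B0`,
#' `C0` from the log-linear regression of `ln(S/(A0 - S))` on `t`) plus
#' `n_starts - 1` randomly perturbed restarts, keeping the solution with
#' the lowest residual sum of squares. Bounds keep `A` within (0, 3] m and
#' `B` within (0, 2]/day — a growing cereal, not decay. The fit is flagged
#' non-converged when every start fails or the optimum pins `B` to a
#' bound (unidentifiable series, e.g. constant heights).
#'
#' @param times days since first flight, strictly increasing, >= 4 values.
#' @param heights median crop heights (metres, >= 0), same length.
#' @param n_starts number of optimizer starts (>= 1).
#' @param lower,upper parameter bounds, order (A, B, C).
#' @param seed optional seed for the perturbed restarts (local RNG use).
#' @return an object of class `logistic_fit`: coefficients `A`, `B`, `C`,
#'   plus `rss`, `converged`, `n_points`, and the data. Methods: `print`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' t <- seq(0, 84, by = 14)
#' h <- logistic_curve(t, A = 0.9, B = 0.15, C = -6)
#' fit <- fit_logistic(t, h)
#' coef(fit)
#' @export
fit_logistic <- function(times, heights, n_starts = 5L,
                         lower = c(1e-6, 1e-6, -Inf),
                         upper = c(3, 2, Inf), seed = NULL) {
  if (length(times) != length(heights)) stop("length mismatch")
  if (length(times) < 4L) stop("need at least 4 time points")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (all(heights <= 0)) stop("all-zero height series cannot be fitted")

  start0 <- logistic_start(times, heights)
  starts <- list(start0)
  if (n_starts > 1L) {
    rng <- local_rng(seed)
    on.exit(rng())
    for (i in seq_len(n_starts - 1L)) {
      f <- stats::runif(3, 0.6, 1.4)
      starts[[i + 1L]] <- c(A = start0[["A"]] * f[1],
                            B = start0[["B"]] * f[2],
                            C = start0[["C"]] * f[3] - (i - 2) * 2)
    }
  }
  clamp <- function(s) pmin(pmax(s, lower + c(1e-6, 1e-6, -1e6)),
                            upper - c(1e-6, 1e-6, -1e6) * 0)
  best <- NULL
  df <- data.frame(t = times, S = heights)
  for (s in starts) {
    s <- clamp(s)
    fit <- tryCatch(
      minpack.lm::nlsLM(S ~ A / (1 + exp(-B * t - C)), data = df,
                        start = as.list(s), lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) {
    out <- list(coefficients = c(A = NA_real_, B = NA_real_, C = NA_real_),
                rss = NA_real_, converged = FALSE,
                n_points = length(times), times = times, heights = heights)
    class(out) <- "logistic_fit"
    return(out)
  }
  cf <- best$coef
  at_bound <- cf[["B"]] <= lower[2] * 1.001 || cf[["B"]] >= upper[2] * 0.999 ||
    cf[["A"]] <= lower[1] * 1.001
  out <- list(coefficients = c(A = cf[["A"]], B = cf[["B"]], C = cf[["C"]]),
              rss = best$rss, converged = !at_bound,
              n_points = length(times), times = times, heights = heights)
  class(out) <- "logistic_fit"
  out
}

# run expr with a locally seeded RNG without disturbing the global stream;
# returns a restore function
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  if (!is.null(seed)) set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> S(t) = A / (1 + exp(-B t - C))\n")
  if (x$converged) {
    cat(sprintf("  A = %.4f m, B = %.4f /day, C = %.3f (midpoint %.1f d)\n",
                x$coefficients[1], x$coefficients[2], x$coefficients[3],
                -x$coefficients[3] / x$coefficients[2]))
    cat(sprintf("  rss = %.3g m^2 over %d points\n", x$rss, x$n_points))
  } else {
    cat("  not converged\n")
  }
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
predict.logistic_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times
  else if (is.list(newdata)) newdata$t else newdata
  cf <- object$coefficients
  logistic_curve(t, cf[["A"]], cf[["B"]], cf[["C"]])
}

#' @export
fitted.logistic_fit <- function(object, ...) predict(object)

#' @export
residuals.logistic_fit <- function(object, ...) {
  object$heights - predict(object)
}

#' @export
plot.logistic_fit <- function(x, ...) {
  graphics::plot(x$times, x$heights, xlab = "days since first flight",
                 ylab = "median crop height [m]", pch = 19, ...)
  if (x$converged) {
    tt <- seq(min(x$times), max(x$times), length.out = 200)
    graphics::lines(tt, predict(x, tt))
  }
  invisible(x)
}

#' Fit growth curves and growth rates for every plot
#'
#' Groups a per-plot statistics table by (variant, block), fits the
#' logistic model to each plot's median-height series, and computes the
#' relative growth rate for every consecutive flight pair. A plot whose
#' fit fails is flagged (`converged = FALSE`) and a zero height at either
#' end of an interval leaves that RGR `NA`; neither aborts the batch.
#'
#' @param stats wide data frame from [plot_statistics()] covering all
#'   flights (every plot must have the same time grid).
#' @param ... passed to [fit_logistic()].
#' @return a list of class `growth_fits`: `fits` (data frame: variant,
#'   block, A, B, C, rss, converged, n_points), `rgr` (data frame:
#'   variant, block, t1, t2, rgr) and `fit_objects` (list of
#'   `logistic_fit`, names `v<variant>_b<block>`).
#' @export
fit_all <- function(stats, ...) {
  if (NROW(stats) == 0L) stop("empty statistics table")
  key <- interaction(stats$variant, stats$block, drop = TRUE)
  groups <- split(stats, key)
  times_ref <- sort(unique(stats$time_days))
  fit_rows <- list(); rgr_rows <- list(); objects <- list()
  for (g in groups) {
    g <- g[order(g$time_days), ]
    if (!isTRUE(all.equal(g$time_days, times_ref)))
      stop(sprintf("plot v%d b%d does not cover the common time grid",
                   g$variant[1], g$block[1]))
    id <- sprintf("v%d_b%d", g$variant[1], g$block[1])
    fit <- tryCatch(fit_logistic(g$time_days, g$median, ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      fit_rows[[id]] <- data.frame(variant = g$variant[1], block = g$block[1],
                                   A = NA_real_, B = NA_real_, C = NA_real_,
                                   rss = NA_real_, converged = FALSE,
                                   n_points = nrow(g))
    } else {
      objects[[id]] <- fit
      cf <- coef(fit)
      fit_rows[[id]] <- data.frame(variant = g$variant[1], block = g$block[1],
                                   A = cf[["A"]], B = cf[["B"]], C = cf[["C"]],
                                   rss = fit$rss, converged = fit$converged,
                                   n_points = fit$n_points)
    }
    n <- nrow(g)
    s1 <- g$median[-n]; s2 <- g$median[-1]
    t1 <- g$time_days[-n]; t2 <- g$time_days[-1]
    ok <- s1 > 0 & s2 > 0
    rgr <- rep(NA_real_, n - 1L)
    if (any(ok)) rgr[ok] <- relative_growth_rate(s1[ok], s2[ok], t1[ok], t2[ok])
    rgr_rows[[id]] <- data.frame(variant = g$variant[1], block = g$block[1],
                                 t1 = t1, t2 = t2, rgr = rgr)
  }
  fits <- do.call(rbind, fit_rows)
  rgr <- do.call(rbind, rgr_rows)
  rownames(fits) <- rownames(rgr) <- NULL
  fits <- fits[order(fits$block, fits$variant), ]
  rgr <- rgr[order(rgr$block, rgr$variant, rgr$t1), ]
  rownames(fits) <- rownames(rgr) <- NULL
  structure(list(fits = fits, rgr = rgr, fit_objects = objects),
            class = "growth_fits")
}

#' @export
print.growth_fits <- function(x, ...) {
  cat(sprintf("<growth_fits> %d plots, %d converged; %d RGR intervals\n",
              nrow(x$fits), sum(x$fits$converged), nrow(x$rgr)))
  invisible(x)
}

#' Arrange a fitted parameter on the field layout
#'
#' Builds the block-by-variant grid of one logistic parameter for heat-map
#' display of spatial growth heterogeneity: one row per block (top block
#' first), one column per variant (west to east).
#'
#' @param fits the `fits` data frame of [fit_all()] (or a `growth_fits`).
#' @param parameter `"A"`, `"B"`, `"C"` or `"rss"`.
#' @return a numeric matrix `n_blocks` x `n_variants`; non-converged plots
#'   are `NA`.
#' @export
parameter_grid <- function(fits, parameter = c("A", "B", "C", "rss")) {
  parameter <- match.arg(parameter)
  if (inherits(fits, "growth_fits")) fits <- fits$fits
  blocks <- sort(unique(fits$block))
  variants <- sort(unique(fits$variant))
  m <- matrix(NA_real_, length(blocks), length(variants),
              dimnames = list(paste0("block", blocks),
                              paste0("v", variants)))
  val <- ifelse(fits$converged, fits[[parameter]], NA_real_)
  m[cbind(match(fits$block, blocks), match(fits$variant, variants))] <- val
  m
}

#' Write the per-plot fit table as CSV
#'
#' Columns: variant, block, A, B, C, rss, converged, n_points.
#' @param fits a [fit_all()] result or its `fits` data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  if (inherits(fits, "growth_fits")) fits <- fits$fits
  utils::write.csv(fits, path, row.names = FALSE)
  invisible(path)
}

#' Write the RGR table as CSV
#'
#' Columns: variant, block, t1, t2, rgr.
#' @param rgr a [fit_all()] result or its `rgr` data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_rgr <- function(rgr, path) {
  if (inherits(rgr, "growth_fits")) rgr <- rgr$rgr
  utils::write.csv(rgr, path, row.names = FALSE)
  invisible(path)
}
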