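#' Penalized spline smoothing of an annual series
#'
#' Order-4 (piecewise cubic) penalized smoothing spline evaluated at the
#' input years. `smoothing` is the penalty weight lambda: near zero the
#' fit interpolates, large values tend to the least-squares line; NULL
#' selects it by generalized cross-validation. A quartic-degree variant
#' is available for the alternative reading of "fourth-order".
#'
#' @param values numeric series (length >= 5).
#' @param years matching year axis.
#' @param smoothing penalty parameter lambda (NULL = GCV).
#' @param degree "cubic" (default) or "quartic".
#' @return smoothed numeric series at the input years.
#' @export
smooth_spline_series <- function(values, years = seq_along(values),
                                 smoothing = NULL,
                                 degree = c("cubic", "quartic")) {
  degree <- match.arg(degree)
  if (length(values) < 5) stop("too few points to smooth")
  if (stats::sd(values) == 0) return(values)  # splines reproduce constants
  if (degree == "cubic") {
    fit <- if (is.null(smoothing))
      stats::smooth.spline(years, values, cv = FALSE, all.knots = TRUE)
    else
      stats::smooth.spline(years, values, lambda = smoothing,
                           all.knots = TRUE)
    stats::predict(fit, years)$y
  } else {
    if (!requireNamespace("mgcv", quietly = TRUE))
      stop("the quartic option needs the mgcv package")
    k <- min(length(values) - 1L, 30L)
    fit <- mgcv::gam(values ~ s(years, bs = "ps", m = c(3, 2), k = k),
                     sp = smoothing)
    as.numeric(stats::predict(fit, data.frame(years = years)))
  }
}

#' Tricube-weighted local linear regression
#'
#' At each year, a straight line is fitted by weighted least squares to
#' the `floor(span * n)` nearest years, with tricube weights
#' `(1 - (d/d_max)^3)^3` in the scaled distance; the fitted value at that
#' year is returned. This is the classical locally fitted regression
#' used to draw trend lines through noisy annual series.
#'
#' @param values numeric series (length >= 4).
#' @param years matching year axis.
#' @param span fraction of points in each local neighbourhood, in (0, 1].
#' @return fitted numeric series at the input years.
#' @export
local_regression <- function(values, years = seq_along(values),
                             span = 0.5) {
  n <- length(values)
  if (n < 4) stop("need at least 4 points")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  q <- max(2L, floor(span * n))
  vapply(seq_len(n), function(i) {
    d <- abs(years - years[i])
    dq <- sort(d, partial = q)[q]
    w <- numeric(n)
    inside <- d < dq
    w[inside] <- (1 - (d[inside] / dq)^3)^3
    w[d == 0] <- 1
    if (dq == 0) return(values[i])
    x <- years - years[i]
    sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
    sy <- sum(w * values); sxy <- sum(w * x * values)
    det <- sw * sxx - sx^2
    if (abs(det) < 1e-12 * max(sw * sxx, 1))
      return(sy / sw)  # degenerate neighbourhood: weighted mean
    (sxx * sy - sx * sxy) / det  # intercept at x = 0
  }, numeric(1))
}

#' Period means, trends and acceleration of an annual series
#'
#' For each period the simple average and the ordinary-least-squares
#' slope versus year. The "acceleration" of a flux is reported as the
#' OLS slope over the last period (e.g. the post-2000 trend of an annual
#' attribution increment, in PgC/yr^2 or TgC/yr^2).
#'
#' @param values numeric series.
#' @param years matching year axis.
#' @param periods list of length-2 year ranges.
#' @param trend_units "PgC" (slope in PgC/yr^2) or "TgC" (x 1000).
#' @return list with `stats` (data.frame period_start, period_end, mean,
#'   trend) and `acceleration` (trend of the last period).
#' @export
period_mean_and_trend <- function(values, years,
                                  periods = list(c(1961, 2000),
                                                 c(2001, 2020)),
                                  trend_units = c("PgC", "TgC")) {
  trend_units <- match.arg(trend_units)
  fac <- if (trend_units == "TgC") 1000 else 1
  rows <- lapply(periods, function(p) {
    sel <- years >= p[1] & years <= p[2]
    if (!any(sel)) stop("empty period ", p[1], "-", p[2])
    y <- values[sel]; x <- years[sel]
    trend <- if (length(y) > 1) unname(stats::coef(stats::lm(y ~ x))[2]) else NA_real_
    data.frame(period_start = p[1], period_end = p[2], mean = mean(y),
               trend = trend * fac)
  })
  stats <- do.call(rbind, rows)
  list(stats = stats, acceleration = stats$trend[nrow(stats)])
}

#' Driver-dominance RGB composite
#'
#' Encodes which driver dominates the change at each grid cell:
#' channel_i = |d_i| / sum_j |d_j| with climate mapped to red, CO2 to
#' green and land use to blue, and alpha = min(1, |net| / scale) fading
#' cells with little net change. Channels sum to 1 wherever any driver
#' is nonzero and are invariant to rescaling all drivers by c > 0.
#'
#' @param clim,co2,lulcc per-driver change fields (arrays/matrices of a
#'   common shape).
#' @param net net change field of the same shape.
#' @param alpha_scale |net| value mapping to full opacity.
#' @return list of arrays `r`, `g`, `b`, `alpha` in [0, 1].
#' @export
rgb_driver_composite <- function(clim, co2, lulcc, net, alpha_scale = 1) {
  stopifnot(length(clim) == length(co2), length(co2) == length(lulcc),
            length(lulcc) == length(net))
  tot <- abs(clim) + abs(co2) + abs(lulcc)
  safe <- ifelse(tot == 0, 1, tot)
  r <- abs(clim) / safe
  g <- abs(co2) / safe
  b <- abs(lulcc) / safe
  r[tot == 0] <- 0; g[tot == 0] <- 0; b[tot == 0] <- 0
  alpha <- pmin(1, abs(net) / alpha_scale)
  alpha[net == 0] <- 0
  list(r = r, g = g, b = b, alpha = alpha)
}

#' Ensemble summary tables of attribution terms
#'
#' Mean, sample standard deviation and model count per pool, driver and
#' term, in a deterministic order, for results pooled across models
#' (e.g. the final-year rows of [driver_process_attribution()] stacked
#' with a `model` column).
#'
#' @param results data.frame with columns `model`, `pool`, `driver` and
#'   the term columns of [attribute_pool_change()].
#' @param terms which term columns to summarise.
#' @return data.frame with `pool`, `driver`, `term`, `mean_PgC`,
#'   `sd_PgC`, `n_models`.
#' @export
summary_tables <- function(results,
                           terms = c("input_adj", "output_adj",
                                     "interaction_adj", "delta_actual")) {
  if (nrow(results) == 0) stop("empty results")
  drivers <- intersect(c("CO2", "CLIM", "LULCC", "ALL"),
                       unique(results$driver))
  pools <- intersect(c("vegetation", "soil"), unique(results$pool))
  grid <- expand.grid(term = terms, driver = drivers, pool = pools,
                      stringsAsFactors = FALSE)[, c("pool", "driver", "term")]
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- results$pool == grid$pool[i] & results$driver == grid$driver[i]
    x <- results[[grid$term[i]]][sel]
    x <- x[!is.na(x)]
    data.frame(grid[i, ], mean_PgC = mean(x),
               sd_PgC = if (length(x) > 1) stats::sd(x) else NA_real_,
               n_models = length(x))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
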