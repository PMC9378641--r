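#' Synthetic forcing trajectories for the factorial scenario design
#'
#' Builds the three external forcing series driving the toy land carbon
#' model: atmospheric CO2 (ppm), a global temperature anomaly relative to
#' pre-industrial (K), and the agricultural land fraction (dimensionless).
#' The transient series emulate the historical period; each has a fixed
#' (pre-industrial) counterpart, and the temperature anomaly additionally
#' has a "recycled" variant that repeats the first `recycle_period` years
#' cyclically over the whole axis, mirroring the recycled early-20th-century
#' climate used in factorial land-model experiments.
#'
#' Interannual noise is applied to the temperature anomaly only, from the
#' warming onset year onwards; before the onset the anomaly is exactly
#' zero, so the recycled variant is stationary whenever the axis starts at
#' least `recycle_period` years before the onset. All models in an
#' ensemble share one forcing set (common forcing, different structure).
#'
#' @param years integer vector of consecutive calendar years (>= 40 years).
#' @param co2_spec list with `co2_ref` (pre-industrial ppm) and
#'   `growth_rate` (exponential rate per year); transient CO2 is
#'   `co2_ref * exp(growth_rate * (year - years[1]))`, monotone increasing.
#' @param climate_spec list with `onset` (first transient year), `trend`
#'   (K per year from onset) and `sigma` (standard deviation, K, of the
#'   Gaussian interannual noise; must be >= 0).
#' @param lulcc_spec list with `anchors` (data.frame with columns `year`,
#'   `f_ag` for piecewise-linear interpolation), and optionally
#'   `spike_year` / `spike_size` adding an artificial one-year excursion
#'   (used to exercise the spike correction).
#' @param seed integer seed; the series are deterministic given the seed.
#' @param recycle_period number of initial years repeated by the recycled
#'   climate variant (default 20).
#'
#' @return An object of class `forcing_set`: a list with `years`, `co2`,
#'   `t_anom`, `t_anom_recycled`, `f_ag`, `co2_ref`, `f_ag_ref` (the
#'   pre-industrial agricultural fraction, used by the fixed-land-use
#'   scenarios) and `seed`.
#' @export
#' @examples
#' frc <- generate_forcing(1850:2020, seed = 1)
#' range(frc$co2)
generate_forcing <- function(years,
                             co2_spec = list(co2_ref = 284, growth_rate = 0.0022),
                             climate_spec = list(onset = 1900, trend = 0.010,
                                                 sigma = 0.1),
                             lulcc_spec = list(
                               anchors = data.frame(
                                 year = c(1850, 1900, 1960, 2020),
                                 f_ag = c(0.10, 0.15, 0.28, 0.32)),
                               spike_year = NULL, spike_size = 0),
                             seed = 1L,
                             recycle_period = 20L) {
  years <- as.integer(years)
  if (length(years) < 40L || any(diff(years) != 1L))
    stop("`years` must span at least 40 consecutive calendar years")
  if (is.null(climate_spec$sigma)) climate_spec$sigma <- 0
  if (climate_spec$sigma < 0) stop("climate noise sigma must be >= 0")
  if (is.null(seed)) stop("a seed is required")
  n <- length(years)

  co2_ref <- co2_spec$co2_ref
  co2 <- co2_ref * exp(co2_spec$growth_rate * (years - years[1]))

  onset <- climate_spec$onset
  t_anom <- numeric(n)
  trans <- years >= onset
  t_anom[trans] <- climate_spec$trend * (years[trans] - onset)
  if (climate_spec$sigma > 0) {
    set.seed(as.integer(seed))
    t_anom[trans] <- t_anom[trans] +
      stats::rnorm(sum(trans), sd = climate_spec$sigma)
  }
  t_anom_recycled <- recycle_series(t_anom, recycle_period)

  anchors <- lulcc_spec$anchors
  f_ag <- stats::approx(anchors$year, anchors$f_ag, xout = years,
                        rule = 2)$y
  if (!is.null(lulcc_spec$spike_year) &&
      lulcc_spec$spike_year %in% years) {
    f_ag[years == lulcc_spec$spike_year] <-
      f_ag[years == lulcc_spec$spike_year] + lulcc_spec$spike_size
  }
  f_ag <- pmin(pmax(f_ag, 0), 1)
  stopifnot(all(co2 > 0))

  structure(list(years = years, co2 = co2, t_anom = t_anom,
                 t_anom_recycled = t_anom_recycled, f_ag = f_ag,
                 co2_ref = co2_ref, f_ag_ref = f_ag[1],
                 seed = as.integer(seed)),
            class = "forcing_set")
}

#' Repeat the leading block of a series cyclically
#'
#' @param x numeric vector.
#' @param period number of leading values to recycle over the full length.
#' @return numeric vector of `length(x)`.
#' @keywords internal
recycle_series <- function(x, period) {
  period <- min(as.integer(period), length(x))
  x[((seq_along(x) - 1L) %% period) + 1L]
}

#' Scenario definitions of the factorial design
#'
#' S0 holds CO2, climate and land use at pre-industrial/recycled levels;
#' S1 adds transient CO2; S2 adds transient climate; S3 adds transient
#' land use. Driver effects follow by differencing (see
#' [driver_components()]).
#'
#' @param label one of "S0", "S1", "S2", "S3".
#' @return list with `label` and logical flags `co2_transient`,
#'   `climate_transient`, `lulcc_transient`.
#' @export
scenario_spec <- function(label) {
  label <- match.arg(label, c("S0", "S1", "S2", "S3"))
  k <- as.integer(substring(label, 2))
  list(label = label,
       co2_transient = k >= 1L,
       climate_transient = k >= 2L,
       lulcc_transient = k >= 3L)
}

#' Forcing series as seen by one scenario
#'
#' Selects, per forcing axis, the transient series or its fixed/recycled
#' control according to the scenario flags: fixed pre-industrial CO2 and
#' land use, recycled climate where the respective axis is not transient.
#'
#' @param forcing a `forcing_set`.
#' @param scenario scenario label or a list from [scenario_spec()].
#' @return data.frame with columns `year`, `co2`, `t_anom`, `f_ag`.
#' @export
scenario_forcing <- function(forcing, scenario) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  data.frame(
    year = forcing$years,
    co2 = if (scenario$co2_transient) forcing$co2
          else rep(forcing$co2_ref, length(forcing$years)),
    t_anom = if (scenario$climate_transient) forcing$t_anom
             else forcing$t_anom_recycled,
    f_ag = if (scenario$lulcc_transient) forcing$f_ag
           else rep(forcing$f_ag_ref, length(forcing$years)))
}
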