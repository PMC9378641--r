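#' Correct the land-use spike artefact in an annual series
#'
#' Land-use forcing reconstructions can carry an artificial transition
#' peak around 1960; the affected years are replaced by the mean of the
#' two bracketing years. Idempotent, and touches only the named years.
#'
#' @param values numeric series.
#' @param years matching year axis.
#' @param spike_years years to replace (default 1959:1961).
#' @param bracket two bracketing years whose mean replaces the spike
#'   (default c(1958, 1962)); both must be present.
#' @return corrected numeric series.
#' @export
#' @examples
#' lulcc_spike_correction(c(1, 5, 6, 7, 1.4), 1958:1962)
lulcc_spike_correction <- function(values, years,
                                   spike_years = 1959:1961,
                                   bracket = c(1958, 1962)) {
  if (!all(bracket %in% years)) stop("bracket year(s) missing from series")
  fill <- mean(values[match(bracket, years)])
  values[years %in% spike_years] <- fill
  values
}

soil_or_column <- function(run, variable) {
  if (variable == "Cs") aggregate_soil_pools(run) else run$series[[variable]]
}

#' Driver components of a variable from a scenario quartet
#'
#' Telescoped factorial differences: CO2 = S1 - S0, CLIM = S2 - S1 + S0,
#' LULCC = S3 - S2, NET = S3. The three driver components sum to NET
#' exactly; enabling the spike correction modifies only the LULCC
#' component (default) or the S3 series itself in the affected years.
#'
#' @param quartet `scenario_quartet` with aligned S0..S3 runs.
#' @param variable a series column ("NBP", "NPP", "Rh", "cVeg", ...) or
#'   "Cs" for the aggregated soil-system stock.
#' @param correct_spike apply [lulcc_spike_correction()]?
#' @param correct_on where to apply it: the "difference" series S3 - S2
#'   (default, where the land-use artefact lives) or "net" (S3 directly,
#'   in which case LULCC = corrected S3 - S2 and NET is corrected too).
#' @param ... passed to [lulcc_spike_correction()].
#' @return data.frame with `year`, `CO2`, `CLIM`, `LULCC`, `NET`.
#' @export
driver_components <- function(quartet, variable, correct_spike = FALSE,
                              correct_on = c("difference", "net"), ...) {
  correct_on <- match.arg(correct_on)
  r <- quartet$runs
  years <- r$S0$series$year
  for (s in c("S1", "S2", "S3"))
    if (!identical(r[[s]]$series$year, years))
      stop("scenario year axes are misaligned")
  v <- lapply(r, soil_or_column, variable = variable)
  lulcc <- v$S3 - v$S2
  net <- v$S3
  if (correct_spike) {
    if (correct_on == "difference") {
      lulcc <- lulcc_spike_correction(lulcc, years, ...)
    } else {
      net <- lulcc_spike_correction(net, years, ...)
      lulcc <- net - v$S2
    }
  }
  data.frame(year = years, CO2 = v$S1 - v$S0,
             CLIM = v$S2 - v$S1 + v$S0, LULCC = lulcc, NET = net)
}

#' Per-driver process attribution of a pool's stock change
#'
#' Runs [attribute_pool_change()] on each of the four scenario runs
#' independently and telescopes the resulting terms: CO2 = S1 - S0,
#' CLIM = S2 - S1 + S0, LULCC = S3 - S2, ALL = S3. Because the
#' telescoping is linear, within every driver the three adjusted terms
#' sum to that driver's stock change, and the three drivers sum to ALL
#' term by term.
#'
#' @inheritParams attribute_pool_change
#' @param quartet `scenario_quartet`.
#' @return data.frame as from [attribute_pool_change()] with a leading
#'   `driver` column in CO2/CLIM/LULCC/ALL; a year flagged in any
#'   scenario is flagged (NA terms) for every driver.
#' @export
driver_process_attribution <- function(quartet,
                                       pool = c("vegetation", "soil"),
                                       ref_year = 1959L, end_years = NULL,
                                       endpoint_window = 1L) {
  pool <- match.arg(pool)
  per_scen <- lapply(quartet$runs, attribute_pool_change, pool = pool,
                     ref_year = ref_year, end_years = end_years,
                     endpoint_window = endpoint_window)
  num_cols <- c("input_term", "output_term", "interaction_term",
                "delta_hat", "delta_actual", "correction",
                "input_adj", "output_adj", "interaction_adj")
  flagged <- Reduce(`|`, lapply(per_scen, `[[`, "flagged"))
  combos <- list(CO2 = c(S1 = 1, S0 = -1),
                 CLIM = c(S2 = 1, S1 = -1, S0 = 1),
                 LULCC = c(S3 = 1, S2 = -1),
                 ALL = c(S3 = 1))
  out <- lapply(names(combos), function(drv) {
    w <- combos[[drv]]
    base <- per_scen$S3[c("pool", "ref_year", "year")]
    vals <- lapply(num_cols, function(col) {
      x <- Reduce(`+`, Map(function(s, wt) wt * per_scen[[s]][[col]],
                           names(w), w))
      ifelse(flagged, NA_real_, x)
    })
    names(vals) <- num_cols
    cbind(driver = drv, base, as.data.frame(vals), flagged = flagged)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
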