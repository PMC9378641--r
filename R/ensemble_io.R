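#' Total soil-system carbon under pool-availability rules
#'
#' Model archives report heterogeneous soil-system pools: some models have
#' no litter pool, few report coarse woody debris, and some fold the
#' litter stock into the soil output. The analysis soil pool is the sum
#' of soil, litter and CWD where they exist, never counting litter twice
#' when it is already inside the reported soil pool.
#'
#' @param run a `model_run` (or any list with `series` and `flags`).
#' @return numeric vector of total soil-system carbon (PgC), aligned on
#'   `run$series$year`.
#' @export
#' @examples
#' # models without litter/CWD contribute the bare soil pool
aggregate_soil_pools <- function(run) {
  s <- run$series
  fl <- run$flags
  if (fl$has_litter && !fl$litter_in_soil && all(is.na(s$cLitter)))
    stop("has_litter flag set but cLitter is absent")
  if (fl$has_cwd && all(is.na(s$cCWD)))
    stop("has_cwd flag set but cCWD is absent")
  total <- s$cSoil
  if (fl$has_litter && !fl$litter_in_soil) total <- total + s$cLitter
  if (fl$has_cwd) total <- total + s$cCWD
  total
}

#' Latitude-band region definitions
#'
#' The default partition used throughout: north of 30N, south of 30N, and
#' their union (global). Cells are assigned by grid-cell centre latitude;
#' a centre exactly at 30N counts as north.
#'
#' @param boundary latitude (degrees) separating the two bands.
#' @return list of regions, each with `name` and a vectorised `contains`
#'   predicate over centre latitudes.
#' @export
default_regions <- function(boundary = 30) {
  list(north = list(name = "north", contains = function(lat) lat >= boundary),
       south = list(name = "south", contains = function(lat) lat < boundary),
       global = list(name = "global", contains = function(lat) rep(TRUE, length(lat))))
}

#' Spherical grid-cell areas
#'
#' Areas of a regular lat/lon grid on a sphere of radius 6,371,000 m,
#' from the analytic band integral.
#'
#' @param lat,lon vectors of cell-centre coordinates (degrees), regular
#'   spacing.
#' @return matrix `[length(lat), length(lon)]` of areas in m^2.
#' @export
cell_areas <- function(lat, lon) {
  r_earth <- 6371000
  dlat <- if (length(lat) > 1) abs(lat[2] - lat[1]) else 180
  dlon <- if (length(lon) > 1) abs(lon[2] - lon[1]) else 360
  rad <- pi / 180
  band <- r_earth^2 * (dlon * rad) *
    (sin(pmin(lat + dlat / 2, 90) * rad) -
     sin(pmax(lat - dlat / 2, -90) * rad))
  matrix(band, length(lat), length(lon))
}

#' Area-weighted regional totals of a gridded annual field
#'
#' Reduces a gridded stock (kgC/m^2) or rate (kgC/m^2/s) field to
#' per-region totals in PgC or PgC/yr: total = sum(value * area) * 1e-12,
#' and for rate fields additionally * 365.25 * 86400 seconds per year.
#'
#' @param field matrix `[lat, lon]`.
#' @param lat,lon cell-centre coordinates (degrees).
#' @param areas optional cell areas (m^2); computed with [cell_areas()]
#'   when NULL.
#' @param regions as [default_regions()].
#' @param rate is `field` a per-second rate (TRUE) or a stock (FALSE)?
#' @param missing policy for NA cells: "error" (default) or "zero".
#' @return named numeric vector of per-region totals.
#' @export
regional_totals <- function(field, lat, lon, areas = NULL,
                            regions = default_regions(), rate = FALSE,
                            missing = c("error", "zero")) {
  missing <- match.arg(missing)
  if (is.null(areas)) areas <- cell_areas(lat, lon)
  if (!all(dim(field) == dim(areas)) || nrow(field) != length(lat))
    stop("field, areas and latitude axis must share the grid")
  if (anyNA(field)) {
    if (missing == "error") stop("missing values in field (policy 'error')")
    field[is.na(field)] <- 0
  }
  fac <- 1e-12 * if (rate) 365.25 * 86400 else 1
  vapply(regions, function(rg) {
    sel <- rg$contains(lat)
    sum(field[sel, , drop = FALSE] * areas[sel, , drop = FALSE]) * fac
  }, numeric(1))
}

#' Net land sink from the global carbon budget residual
#'
#' The observation-based net land sink is the residual of fossil-fuel
#' emissions minus atmospheric growth minus the ocean sink.
#'
#' @param budget data.frame with columns `year`, `E_FOS`, `G_ATM`,
#'   `S_OCEAN` (PgC/yr, aligned years).
#' @return data.frame with `year` and `residual` (PgC/yr).
#' @export
compute_budget_residual <- function(budget) {
  stopifnot(all(c("year", "E_FOS", "G_ATM", "S_OCEAN") %in% names(budget)))
  data.frame(year = budget$year,
             residual = budget$E_FOS - budget$G_ATM - budget$S_OCEAN)
}

#' Validate a model run
#'
#' Report-only checks: gaps in the year axis, negative stocks, flags
#' claiming absent pools, and the net-flux closure residual
#' max |NBP(t) - (stocks(t+1) - stocks(t))| over the soil-system plus
#' vegetation total. The closure residual is informational: real model
#' archives include fluxes the reported pools omit (e.g. wood-product
#' pools), so a nonzero residual is not by itself an error.
#'
#' @param run a `model_run`.
#' @return list with `year_gaps`, `negative_stocks`, `flag_issues`,
#'   `closure_residual` (PgC/yr, NA when not computable) and `ok`.
#' @export
validate_run <- function(run) {
  s <- run$series
  gaps <- s$year[c(FALSE, diff(s$year) != 1)]
  stock_cols <- intersect(c("cVeg", "cSoil", "cLitter", "cCWD"), names(s))
  neg <- unique(unlist(lapply(stock_cols, function(v)
    s$year[!is.na(s[[v]]) & s[[v]] < 0])))
  flag_issues <- character(0)
  if (run$flags$has_litter && !run$flags$litter_in_soil &&
      all(is.na(s$cLitter)))
    flag_issues <- c(flag_issues, "has_litter set but cLitter absent")
  if (run$flags$has_cwd && all(is.na(s$cCWD)))
    flag_issues <- c(flag_issues, "has_cwd set but cCWD absent")
  if (!run$flags$has_litter && any(!is.na(s$cLitter)))
    flag_issues <- c(flag_issues, "cLitter present but has_litter unset")

  closure <- NA_real_
  if (length(gaps) == 0 && nrow(s) >= 2) {
    tot <- s$cVeg + tryCatch(aggregate_soil_pools(run),
                             error = function(e) rep(NA_real_, nrow(s)))
    closure <- max(abs(s$NBP[-nrow(s)] - diff(tot)))
  }
  list(year_gaps = gaps, negative_stocks = sort(neg),
       flag_issues = flag_issues, closure_residual = closure,
       ok = length(gaps) == 0 && length(neg) == 0 &&
         length(flag_issues) == 0)
}

#' Write / read an ensemble as tidy CSV
#'
#' Long format with columns model, scenario, region, year, variable,
#' value, units — one row per model-scenario-year-variable. The reader
#' reconstructs `model_run` objects; a written-then-read ensemble is
#' value-identical.
#'
#' @param ensemble an `ensemble` (or list of `scenario_quartet`s).
#' @param path CSV file path.
#' @return `write_ensemble_csv` the path, invisibly; `read_ensemble_csv`
#'   a list of quartet-like lists with `model_id`, `flags`, `runs`.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  quartets <- if (inherits(ensemble, "ensemble")) ensemble$quartets
              else ensemble
  units_of <- c(NBP = "PgC yr-1", NPP = "PgC yr-1", Rh = "PgC yr-1",
                cVeg = "PgC", cSoil = "PgC", cLitter = "PgC", cCWD = "PgC")
  rows <- lapply(quartets, function(q) {
    lapply(q$runs, function(r) {
      s <- r$series
      vars <- names(units_of)
      do.call(rbind, lapply(vars, function(v)
        data.frame(model = r$model_id, scenario = r$scenario,
                   region = r$region, year = s$year, variable = v,
                   value = s[[v]], units = units_of[[v]])))
    })
  })
  tidy <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(tidy) <- NULL
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @param flag_table optional data.frame (model, has_litter, has_cwd,
#'   litter_in_soil); when NULL flags are inferred from NA patterns.
#' @export
read_ensemble_csv <- function(path, flag_table = NULL) {
  tidy <- utils::read.csv(path)
  lapply(split(tidy, tidy$model), function(tm) {
    runs <- lapply(split(tm, tm$scenario), function(tr) {
      wide <- stats::reshape(tr[, c("year", "variable", "value")],
                             idvar = "year", timevar = "variable",
                             direction = "wide")
      names(wide) <- sub("^value\\.", "", names(wide))
      wide <- wide[order(wide$year),
                   c("year", "NBP", "NPP", "Rh", "cVeg", "cSoil",
                     "cLitter", "cCWD")]
      rownames(wide) <- NULL
      wide[-1] <- lapply(wide[-1], as.numeric)
      if (!is.null(flag_table)) {
        fr <- flag_table[flag_table$model == tr$model[1], ]
        flags <- list(has_litter = fr$has_litter, has_cwd = fr$has_cwd,
                      litter_in_soil = fr$litter_in_soil)
      } else {
        flags <- list(has_litter = any(!is.na(wide$cLitter)),
                      has_cwd = any(!is.na(wide$cCWD)),
                      litter_in_soil = FALSE)
      }
      structure(list(model_id = tr$model[1], scenario = tr$scenario[1],
                     region = tr$region[1], flags = flags, series = wide),
                class = "model_run")
    })
    structure(list(model_id = tm$model[1], flags = runs[[1]]$flags,
                   runs = runs),
              class = "scenario_quartet")
  })
}
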