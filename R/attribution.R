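#' Annual change of a stock series
#'
#' Backward difference C(t) - C(t-1); the first year uses the forward
#' difference so the result stays aligned with the input years.
#'
#' @param values numeric vector (length >= 2).
#' @return numeric vector of the same length.
#' @export
#' @examples
#' annual_change(c(1, 3, 6))  # 2 2 3
annual_change <- function(values) {
  if (length(values) < 2) stop("need at least 2 years")
  d <- diff(values)
  c(d[1], d)
}

#' Diagnosed vegetation turnover time
#'
#' tau_v(t) = Cv(t) / (NPP(t) - dCv(t)): the stock divided by its
#' diagnosed outflux. Years where the denominator is non-positive are
#' returned as NA (flagged missing), never clamped.
#'
#' @param Cv vegetation carbon, PgC.
#' @param NPP net primary productivity, PgC/yr.
#' @param dCv annual change in Cv; [annual_change()] of `Cv` by default.
#' @return tau_v in years, NA where undefined.
#' @export
diagnose_tau_v <- function(Cv, NPP, dCv = annual_change(Cv)) {
  den <- NPP - dCv
  ifelse(den > 0, Cv / den, NA_real_)
}

#' Diagnosed soil turnover time
#'
#' tau_s(t) = Cs(t) / Rh(t), NA where Rh <= 0.
#'
#' @param Cs total soil-system carbon, PgC.
#' @param Rh heterotrophic respiration, PgC/yr.
#' @return tau_s in years.
#' @export
diagnose_tau_s <- function(Cs, Rh) ifelse(Rh > 0, Cs / Rh, NA_real_)

#' Diagnosed vegetation-to-soil carbon flux
#'
#' f_vs(t) = dCs(t) + Rh(t): litterfall, mortality and root transfer
#' inferred from the soil balance.
#'
#' @param dCs annual change in total soil-system carbon, PgC/yr.
#' @param Rh heterotrophic respiration, PgC/yr.
#' @return f_vs in PgC/yr.
#' @export
diagnose_f_vs <- function(dCs, Rh) dCs + Rh

#' Steady-state pool approximation
#'
#' C-hat = input * tau: the pool size a single well-mixed pool would
#' settle to under the year's input flux and turnover time. Missing tau
#' propagates.
#'
#' @param input input flux, PgC/yr.
#' @param tau turnover time, yr.
#' @return C-hat, PgC.
#' @export
steady_state_pool <- function(input, tau) input * tau

#' Three-term decomposition of a steady-state stock change
#'
#' Splits dC-hat = input_end*tau_end - input_ref*tau_ref exactly into an
#' input-driven term, a turnover-driven (output) term and an interaction:
#' input_term = d_input * tau_ref, output_term = input_ref * d_tau,
#' interaction = d_input * d_tau. The three terms sum to dC-hat by
#' algebraic identity.
#'
#' @param input_ref,input_end input flux at the reference and end year.
#' @param tau_ref,tau_end turnover time at the reference and end year.
#' @return named numeric vector `c(input, output, interaction)`, PgC.
#' @export
#' @examples
#' decompose_change(50, 60, 8, 9)  # 80 50 10; sums to 540 - 400
decompose_change <- function(input_ref, input_end, tau_ref, tau_end) {
  d_input <- input_end - input_ref
  d_tau <- tau_end - tau_ref
  c(input = d_input * tau_ref,
    output = input_ref * d_tau,
    interaction = d_input * d_tau)
}

#' Proportional adjustment of decomposition terms to the actual change
#'
#' The steady-state decomposition misses non-steady-state behaviour and
#' multi-pool structure, so its sum differs from the directly simulated
#' stock change by delta = dC_actual - sum(terms). Each term absorbs a
#' share of delta proportional to its absolute magnitude, so the adjusted
#' terms sum to the actual change exactly. When every term is zero the
#' whole correction is assigned to the input term (a documented
#' degenerate rule that preserves the sum).
#'
#' @param terms numeric vector `c(input, output, interaction)` from
#'   [decompose_change()].
#' @param delta_actual the simulated stock change dC, PgC.
#' @return named numeric vector of adjusted terms summing to
#'   `delta_actual`.
#' @export
scale_to_actual <- function(terms, delta_actual) {
  delta <- delta_actual - sum(terms)
  tot <- sum(abs(terms))
  adj <- if (tot == 0) {
    terms + c(delta, 0, 0)
  } else {
    terms + abs(terms) / tot * delta
  }
  names(adj) <- names(terms)
  adj
}

#' Annual change aligned with each year's fluxes
#'
#' Forward difference C(t+1) - C(t), with a backward fallback at the
#' last year. Stocks are start-of-year values while fluxes are
#' within-year totals, so the change *during* year t is the forward
#' difference; this is the alignment under which the diagnosed turnover
#' of a single well-mixed pool recovers its true value exactly.
#'
#' @param values numeric vector (length >= 2).
#' @return numeric vector of the same length.
#' @export
flux_aligned_change <- function(values) {
  if (length(values) < 2) stop("need at least 2 years")
  d <- diff(values)
  c(d, d[length(d)])
}

#' Per-year diagnostics for one pool of a run
#'
#' For vegetation: input = NPP, tau from [diagnose_tau_v()], stock =
#' cVeg. For soil: the soil-system stock from [aggregate_soil_pools()],
#' tau from [diagnose_tau_s()], input = [diagnose_f_vs()]. Stock changes
#' entering the diagnostics use [flux_aligned_change()], pairing each
#' year's (start-of-year) stock with that year's fluxes.
#'
#' @param run `model_run`.
#' @param pool "vegetation" or "soil".
#' @return data.frame with `year`, `stock`, `input`, `tau`.
#' @export
run_diagnostics <- function(run, pool = c("vegetation", "soil")) {
  pool <- match.arg(pool)
  s <- run$series
  stock <- if (pool == "vegetation") s$cVeg else aggregate_soil_pools(run)
  # exact forward difference when the run carries the next-year stocks
  # (synthetic runs do); otherwise the backward last-year fallback
  d_stock <- if (!is.null(run$next_stocks) &&
                 is.finite(run$next_stocks[[pool]]))
    diff(c(stock, run$next_stocks[[pool]]))
  else
    flux_aligned_change(stock)
  if (pool == "vegetation") {
    input <- s$NPP
    tau <- diagnose_tau_v(stock, input, d_stock)
  } else {
    input <- diagnose_f_vs(d_stock, s$Rh)
    tau <- diagnose_tau_s(stock, s$Rh)
  }
  data.frame(year = s$year, stock = stock, input = input, tau = tau)
}

#' Attribute a pool's stock change to input, turnover and interaction
#'
#' For each end year t the change C(t) - C(ref_year) is decomposed via
#' the steady-state approximation (input and turnover diagnosed at the
#' reference and end years, [decompose_change()]) and then adjusted
#' proportionally so the three terms sum to the simulated change
#' ([scale_to_actual()]). Endpoint diagnostics are single-year values by
#' default; `endpoint_window > 1` averages the diagnostics (and the
#' stock) over the trailing window ending at each endpoint, which tames
#' interannual noise at the cost of a slightly smeared endpoint.
#'
#' @param run `model_run` covering `ref_year - 1` through
#'   `max(end_years)`.
#' @param pool "vegetation" or "soil".
#' @param ref_year reference year (default 1959).
#' @param end_years end years; default all years after `ref_year`.
#' @param endpoint_window trailing averaging window in years (default 1,
#'   the literal single-year endpoint).
#' @return data.frame with one row per end year: `pool`, `ref_year`,
#'   `year`, raw terms (`input_term`, `output_term`, `interaction_term`),
#'   `delta_hat` (their sum), `delta_actual`, `correction`
#'   (delta_actual - delta_hat), adjusted terms (`input_adj`,
#'   `output_adj`, `interaction_adj`) and `flagged` (TRUE where a
#'   turnover diagnostic was missing at an endpoint).
#' @export
attribute_pool_change <- function(run, pool = c("vegetation", "soil"),
                                  ref_year = 1959L, end_years = NULL,
                                  endpoint_window = 1L) {
  pool <- match.arg(pool)
  dg <- run_diagnostics(run, pool)
  if (!(ref_year %in% dg$year)) stop("ref_year not covered by run")
  if (is.null(end_years)) end_years <- dg$year[dg$year > ref_year]
  if (!all(end_years %in% dg$year)) stop("end year(s) not covered by run")

  endpoint <- function(col, yr) {
    win <- (yr - endpoint_window + 1L):yr
    mean(dg[[col]][dg$year %in% win])
  }
  in_ref <- endpoint("input", ref_year)
  tau_ref <- endpoint("tau", ref_year)
  stock_ref <- endpoint("stock", ref_year)

  out <- lapply(end_years, function(yr) {
    in_end <- endpoint("input", yr)
    tau_end <- endpoint("tau", yr)
    stock_end <- endpoint("stock", yr)
    flagged <- is.na(tau_ref) || is.na(tau_end) || is.na(in_ref) ||
      is.na(in_end)
    if (flagged) {
      terms <- adj <- c(input = NA_real_, output = NA_real_,
                        interaction = NA_real_)
      dhat <- NA_real_
    } else {
      terms <- decompose_change(in_ref, in_end, tau_ref, tau_end)
      dhat <- sum(terms)
      adj <- scale_to_actual(terms, stock_end - stock_ref)
    }
    data.frame(pool = pool, ref_year = ref_year, year = yr,
               input_term = terms[["input"]],
               output_term = terms[["output"]],
               interaction_term = terms[["interaction"]],
               delta_hat = dhat,
               delta_actual = stock_end - stock_ref,
               correction = (stock_end - stock_ref) - dhat,
               input_adj = adj[["input"]], output_adj = adj[["output"]],
               interaction_adj = adj[["interaction"]],
               flagged = flagged)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write attribution terms as tidy CSV
#'
#' Long format: model, scenario, region, pool, year, term, value (PgC),
#' with term in input/output/interaction, their adjusted counterparts,
#' delta_hat, delta_actual and correction.
#'
#' @param terms data.frame from [attribute_pool_change()] (optionally with
#'   `model`, `scenario`, `region`, `driver` columns prepended).
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_terms_csv <- function(terms, path) {
  value_cols <- c(input = "input_term", output = "output_term",
                  interaction = "interaction_term",
                  input_adj = "input_adj", output_adj = "output_adj",
                  interaction_adj = "interaction_adj",
                  delta_hat = "delta_hat", delta_actual = "delta_actual",
                  correction = "correction")
  id_cols <- setdiff(names(terms), c(value_cols, "flagged"))
  tidy <- do.call(rbind, lapply(names(value_cols), function(nm)
    cbind(terms[id_cols], term = nm, value = terms[[value_cols[[nm]]]])))
  tidy <- tidy[order(tidy$year), ]
  rownames(tidy) <- NULL
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(path)
}
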