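# Shared fixtures and an independent straight-line oracle for the
# attribution arithmetic, kept free of package internals on purpose.

default_forcing <- function(seed = 1, ...) {
  generate_forcing(1850:2020, seed = seed, ...)
}

# quiet forcing: no climate noise, flat land use unless asked otherwise
quiet_forcing <- function(trend = 0.010, sigma = 0, f_ag = c(0.1, 0.1),
                          seed = 1) {
  generate_forcing(
    1850:2020,
    climate_spec = list(onset = 1900, trend = trend, sigma = sigma),
    lulcc_spec = list(anchors = data.frame(year = c(1850, 2020),
                                           f_ag = f_ag),
                      spike_year = NULL, spike_size = 0),
    seed = seed)
}

# Independent recomputation of the input/turnover/interaction attribution
# from raw series: stock changes aligned with each year's fluxes
# (forward differences, backward at the last year), diagnosed turnover
# and transfer fluxes, three-term split of the steady-state change,
# proportional adjustment to the simulated change.
oracle_attribution <- function(run, pool, ref_year, end_year) {
  series <- run$series
  flags <- run$flags
  n <- nrow(series)
  if (pool == "vegetation") {
    C <- series$cVeg
    input <- series$NPP
    dC <- diff(c(C, run$next_stocks[["vegetation"]]))
    tau <- C / (input - dC)
    tau[(input - dC) <= 0] <- NA
  } else {
    C <- series$cSoil
    if (flags$has_litter && !flags$litter_in_soil) C <- C + series$cLitter
    if (flags$has_cwd) C <- C + series$cCWD
    dC <- diff(c(C, run$next_stocks[["soil"]]))
    input <- dC + series$Rh
    tau <- C / series$Rh
    tau[series$Rh <= 0] <- NA
  }
  i0 <- match(ref_year, series$year)
  i1 <- match(end_year, series$year)
  d_in <- input[i1] - input[i0]
  d_tau <- tau[i1] - tau[i0]
  terms <- c(input = d_in * tau[i0], output = input[i0] * d_tau,
             interaction = d_in * d_tau)
  delta_actual <- C[i1] - C[i0]
  delta <- delta_actual - sum(terms)
  tot <- sum(abs(terms))
  adj <- if (tot == 0) terms + c(delta, 0, 0)
         else terms + abs(terms) / tot * delta
  list(terms = terms, adj = adj, delta_actual = delta_actual)
}
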