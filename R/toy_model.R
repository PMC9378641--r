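#' Parameters of the toy land carbon model
#'
#' A minimal two-to-three-pool land carbon model (vegetation, optional
#' litter, soil) driven by CO2, temperature anomaly and agricultural land
#' fraction. It stands in for the structural diversity of process-based
#' vegetation models: each "model" of a synthetic ensemble is one
#' parameter draw.
#'
#' Fluxes, annual time step:
#' \deqn{NPP = npp0 [(1-f_{ag}) + f_{ag}\rho_{ag}]
#'       (1 + \beta \ln(CO_2/CO_{2,ref})) (1 + \gamma T)}
#' Vegetation loses carbon at rate \eqn{C_v/\tau_v^{eff}} with
#' \eqn{\tau_v^{eff} = (1-f_{ag})\tau_{v,nat} + f_{ag}\tau_{v,ag}}, plus an
#' episodic clearing flux \eqn{E_{lu} = \lambda_{lu}\max(\Delta f_{ag},0) C_v}
#' of which a fraction `p_atm` is emitted directly to the atmosphere and
#' the rest enters the soil system. Soil turnover responds to warming as
#' \eqn{\tau_s = \tau_{s0}\, q_{10}^{-T/10}}. With a litter pool, the
#' vegetation-to-soil flux passes through litter (turnover `tau_lit`), a
#' fraction `eps_lit` of the litter outflux is transferred to soil and the
#' remainder respired.
#'
#' @param npp0 baseline natural NPP, PgC/yr.
#' @param rho_ag relative productivity of agricultural land, in (0, 1].
#' @param beta CO2 fertilisation coefficient (dimensionless).
#' @param gamma climate sensitivity of NPP, 1/K.
#' @param tau_v_nat,tau_v_ag vegetation turnover times (yr) on natural and
#'   agricultural land.
#' @param tau_lit litter turnover time, yr.
#' @param tau_s0 soil turnover time at zero temperature anomaly, yr.
#' @param q10 temperature sensitivity of soil turnover (>= 1).
#' @param eps_lit fraction of litter outflux transferred to soil, in [0, 1].
#' @param lambda_lu clearing intensity (dimensionless).
#' @param p_atm fraction of cleared biomass emitted directly to the
#'   atmosphere, in [0, 1].
#' @param co2_ref reference (pre-industrial) CO2, ppm.
#' @param cwd_frac fraction of the litter pool reported as coarse woody
#'   debris when `has_cwd` (reporting split only; dynamics are unaffected).
#' @param has_litter does the model carry an explicit litter pool?
#' @param has_cwd does the model report a CWD pool (implies `has_litter`)?
#' @param litter_in_soil is the litter stock folded into the reported soil
#'   pool (implies `has_litter`)?
#'
#' @return object of class `toy_params`.
#' @export
toy_params <- function(npp0 = 55, rho_ag = 0.7, beta = 0.5, gamma = 0,
                       tau_v_nat = 15, tau_v_ag = 2, tau_lit = 3,
                       tau_s0 = 25, q10 = 2, eps_lit = 0.5,
                       lambda_lu = 1, p_atm = 0.6, co2_ref = 284,
                       cwd_frac = 0.4,
                       has_litter = TRUE, has_cwd = FALSE,
                       litter_in_soil = FALSE) {
  p <- list(npp0 = npp0, rho_ag = rho_ag, beta = beta, gamma = gamma,
            tau_v_nat = tau_v_nat, tau_v_ag = tau_v_ag, tau_lit = tau_lit,
            tau_s0 = tau_s0, q10 = q10, eps_lit = eps_lit,
            lambda_lu = lambda_lu, p_atm = p_atm, co2_ref = co2_ref,
            cwd_frac = cwd_frac, has_litter = has_litter,
            has_cwd = has_cwd, litter_in_soil = litter_in_soil)
  taus <- c(p$tau_v_nat, p$tau_v_ag, p$tau_lit, p$tau_s0)
  if (any(taus <= 0)) stop("all turnover times must be > 0")
  fracs <- c(p$eps_lit, p$p_atm, p$cwd_frac)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (p$rho_ag <= 0 || p$rho_ag > 1) stop("rho_ag must lie in (0, 1]")
  if (p$q10 < 1) stop("q10 must be >= 1")
  if ((p$has_cwd || p$litter_in_soil) && !p$has_litter)
    stop("has_cwd and litter_in_soil require has_litter")
  structure(p, class = "toy_params")
}

npp_flux <- function(p, co2, t_anom, f_ag) {
  p$npp0 * ((1 - f_ag) + f_ag * p$rho_ag) *
    (1 + p$beta * log(co2 / p$co2_ref)) * (1 + p$gamma * t_anom)
}

tau_v_eff <- function(p, f_ag) (1 - f_ag) * p$tau_v_nat + f_ag * p$tau_v_ag

#' Analytic pre-industrial steady state of the toy model
#'
#' Closed-form pool sizes under baseline forcing (zero temperature
#' anomaly, reference CO2, pre-industrial agricultural fraction, no
#' clearing flux): every pool equals its input times its turnover time.
#' Starting the model from this state under constant baseline forcing
#' leaves the pools unchanged, so a control run is drift-free by
#' construction and no numerical spin-up is needed.
#'
#' @param params `toy_params`.
#' @param f_ag0 pre-industrial agricultural land fraction (default 0).
#' @return named numeric vector with `Cv`, `Clit` (0 without a litter
#'   pool) and `Cs`, in PgC.
#' @export
#' @examples
#' analytic_steady_state(toy_params(npp0 = 10, tau_v_nat = 20), f_ag0 = 0)
analytic_steady_state <- function(params, f_ag0 = 0) {
  p <- params
  npp <- npp_flux(p, p$co2_ref, 0, f_ag0)
  cv <- npp * tau_v_eff(p, f_ag0)
  if (p$has_litter) {
    clit <- npp * p$tau_lit
    cs <- p$eps_lit * npp * p$tau_s0
  } else {
    clit <- 0
    cs <- npp * p$tau_s0
  }
  c(Cv = cv, Clit = clit, Cs = cs)
}

#' Advance the toy model by one year
#'
#' Explicit annual update. Pools are start-of-year stocks; returned fluxes
#' are within-year totals, so the attribution identities hold exactly:
#' \eqn{\Delta C_v + \Delta C_{lit} + \Delta C_s = NPP - R_h -
#' p_{atm} E_{lu} = NBP} to machine precision.
#'
#' @param state named vector `c(Cv, Clit, Cs)`, PgC.
#' @param params `toy_params`.
#' @param forcing_now list/row with `co2`, `t_anom`, `f_ag` and `d_f_ag`
#'   (the year-over-year change in `f_ag`, used for the clearing flux).
#' @return list with `state` (pools at the start of the next year) and
#'   `fluxes` (`NPP`, `Rh`, `f_vs`, `E_lu`, `NBP`, all PgC/yr).
#' @export
step_toy_model <- function(state, params, forcing_now) {
  p <- params
  cv <- state[["Cv"]]; clit <- state[["Clit"]]; cs <- state[["Cs"]]
  f_ag <- forcing_now$f_ag
  npp <- npp_flux(p, forcing_now$co2, forcing_now$t_anom, f_ag)
  tv <- tau_v_eff(p, f_ag)
  e_lu <- p$lambda_lu * max(forcing_now$d_f_ag, 0) * cv
  veg_loss <- cv / tv
  f_vs <- veg_loss + (1 - p$p_atm) * e_lu
  tau_s <- p$tau_s0 * p$q10^(-forcing_now$t_anom / 10)

  if (p$has_litter) {
    lit_out <- clit / p$tau_lit
    soil_in <- p$eps_lit * lit_out
    rh <- (1 - p$eps_lit) * lit_out + cs / tau_s
    d_clit <- f_vs - lit_out
  } else {
    soil_in <- f_vs
    rh <- cs / tau_s
    d_clit <- 0
  }
  d_cv <- npp - veg_loss - e_lu
  d_cs <- soil_in - cs / tau_s
  nbp <- npp - rh - p$p_atm * e_lu

  new_state <- c(Cv = cv + d_cv, Clit = clit + d_clit, Cs = cs + d_cs)
  if (any(new_state < 0))
    stop(sprintf("pool driven negative (Cv=%.3g, Clit=%.3g, Cs=%.3g); ",
                 new_state[1], new_state[2], new_state[3]),
         "time step too coarse for these parameters/forcing")
  list(state = new_state,
       fluxes = list(NPP = npp, Rh = rh, f_vs = f_vs, E_lu = e_lu,
                     NBP = nbp))
}

#' Run the toy model under one factorial scenario
#'
#' Initialises from the analytic steady state at the start of the forcing
#' axis, steps annually with the scenario-selected forcing (fixed,
#' recycled or transient per axis) and reports the TRENDY-style variables
#' over the requested analysis window. Pools are start-of-year stocks;
#' the internal litter stock is split into reported litter and CWD pools
#' and optionally folded into the reported soil pool according to the
#' availability flags, exactly as heterogeneous model archives report it.
#'
#' @param params `toy_params`.
#' @param forcing `forcing_set` covering spin-up start through end year.
#' @param scenario scenario label ("S0".."S3") or [scenario_spec()] list.
#' @param window length-2 integer vector, first and last reported year
#'   (default c(1958, 2020) so year-over-year changes exist at 1959).
#' @param model_id identifier stored on the run.
#' @return object of class `model_run`: list with `model_id`, `scenario`,
#'   `region`, `flags`, `next_stocks` (vegetation and soil-system stocks
#'   at the start of the year after the window, supporting exact
#'   flux-aligned differences at the last reported year) and `series`, a
#'   data.frame with columns `year`, `NBP`, `NPP`, `Rh`, `cVeg`,
#'   `cSoil`, `cLitter`, `cCWD` (PgC and PgC/yr; absent pools are NA).
#' @export
run_scenario <- function(params, forcing, scenario,
                         window = c(1958L, 2020L), model_id = "toy") {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  frc <- scenario_forcing(forcing, scenario)
  if (window[1] < min(frc$year) || window[2] > max(frc$year))
    stop("analysis window lies outside the forcing span")
  n <- nrow(frc)
  d_f_ag <- c(0, diff(frc$f_ag))
  state <- analytic_steady_state(params, frc$f_ag[1])

  pools <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("Cv", "Clit", "Cs")))
  flux <- matrix(NA_real_, n, 5,
                 dimnames = list(NULL, c("NPP", "Rh", "f_vs", "E_lu", "NBP")))
  for (i in seq_len(n)) {
    pools[i, ] <- state
    stp <- step_toy_model(state, params,
                          list(co2 = frc$co2[i], t_anom = frc$t_anom[i],
                               f_ag = frc$f_ag[i], d_f_ag = d_f_ag[i]))
    state <- stp$state
    flux[i, ] <- unlist(stp$fluxes)
  }

  p <- params
  w <- if (p$has_cwd) p$cwd_frac else 0
  clitter <- if (p$has_litter) pools[, "Clit"] * (1 - w) else rep(NA_real_, n)
  ccwd <- if (p$has_cwd) pools[, "Clit"] * w else rep(NA_real_, n)
  csoil <- pools[, "Cs"] +
    if (p$litter_in_soil) pools[, "Clit"] * (1 - w) else 0

  keep <- frc$year >= window[1] & frc$year <= window[2]
  series <- data.frame(year = frc$year, NBP = flux[, "NBP"],
                       NPP = flux[, "NPP"], Rh = flux[, "Rh"],
                       cVeg = pools[, "Cv"], cSoil = csoil,
                       cLitter = clitter, cCWD = ccwd)[keep, ]
  rownames(series) <- NULL
  # pools at the start of the year after the window, so forward stock
  # differences (the flux-aligned convention) are defined at every
  # reported year
  i_end <- match(window[2], frc$year)
  nxt <- if (i_end < n) pools[i_end + 1L, ] else state
  next_stocks <- c(vegetation = unname(nxt[["Cv"]]),
                   soil = unname(nxt[["Cs"]] +
                                   if (p$has_litter) nxt[["Clit"]] else 0))
  structure(list(model_id = model_id, scenario = scenario$label,
                 region = "global", next_stocks = next_stocks,
                 flags = list(has_litter = p$has_litter,
                              has_cwd = p$has_cwd,
                              litter_in_soil = p$litter_in_soil),
                 series = series),
            class = "model_run")
}

#' Default parameter ranges for ensemble sampling
#'
#' Each range is sampled uniformly and independently per model. The
#' ranges are chosen to produce inter-model spread of the qualitative
#' character seen across process-based vegetation models: a factor ~2 in
#' CO2 fertilisation strength, disagreement even in the sign of the NPP
#' climate response, and broad baseline turnover diversity.
#'
#' @return named list of length-2 numeric ranges.
#' @export
default_param_ranges <- function() {
  list(npp0 = c(45, 65), rho_ag = c(0.5, 0.9), beta = c(0.3, 0.7),
       gamma = c(-0.02, 0.02), tau_v_nat = c(8, 25), tau_v_ag = c(1, 3),
       tau_lit = c(2, 5), tau_s0 = c(15, 40), q10 = c(1.5, 2.5),
       eps_lit = c(0.3, 0.6), lambda_lu = c(0.5, 1), p_atm = c(0.4, 0.8),
       cwd_frac = c(0.3, 0.5))
}

#' Generate a synthetic multi-model ensemble under the factorial design
#'
#' Samples per-model parameters uniformly from `ranges` and
#' pool-availability flags from `flag_probs` (with `has_cwd` and
#' `litter_in_soil` forced FALSE where `has_litter` is FALSE), then runs
#' all four scenarios per model on one shared forcing set. Reproducible
#' for a fixed seed.
#'
#' @param n_models number of models (>= 2).
#' @param forcing shared `forcing_set`; built from defaults with the same
#'   seed when NULL.
#' @param ranges named list of uniform sampling ranges, as
#'   [default_param_ranges()].
#' @param flag_probs named probabilities for `has_litter`, `has_cwd`,
#'   `litter_in_soil`.
#' @param seed integer master seed.
#' @param window analysis window passed to [run_scenario()].
#' @return object of class `ensemble`: list with `quartets` (one
#'   `scenario_quartet` per model: `model_id`, `params`, `flags`, `runs`
#'   S0..S3) and `param_table` (data.frame, one row per model).
#' @export
generate_ensemble <- function(n_models = 18L, forcing = NULL,
                              ranges = default_param_ranges(),
                              flag_probs = c(has_litter = 0.9,
                                             has_cwd = 0.25,
                                             litter_in_soil = 0.1),
                              seed = 1L, window = c(1958L, 2020L)) {
  if (n_models < 2L) stop("n_models must be >= 2")
  bad <- vapply(ranges, function(r) length(r) != 2L || r[2] < r[1], logical(1))
  if (any(bad)) stop("empty parameter range(s): ",
                     paste(names(ranges)[bad], collapse = ", "))
  if (is.null(forcing)) forcing <- generate_forcing(1850:2020, seed = seed)

  set.seed(as.integer(seed) + 1L)
  draws <- lapply(ranges, function(r) stats::runif(n_models, r[1], r[2]))
  has_litter <- stats::runif(n_models) < flag_probs[["has_litter"]]
  has_cwd <- stats::runif(n_models) < flag_probs[["has_cwd"]] & has_litter
  litter_in_soil <- stats::runif(n_models) < flag_probs[["litter_in_soil"]] &
    has_litter
  param_table <- data.frame(model = sprintf("toy%02d", seq_len(n_models)),
                            as.data.frame(draws),
                            has_litter = has_litter, has_cwd = has_cwd,
                            litter_in_soil = litter_in_soil)

  quartets <- lapply(seq_len(n_models), function(i) {
    p <- do.call(toy_params, c(lapply(draws, `[`, i),
                               list(has_litter = has_litter[i],
                                    has_cwd = has_cwd[i],
                                    litter_in_soil = litter_in_soil[i])))
    runs <- lapply(c("S0", "S1", "S2", "S3"), function(s)
      run_scenario(p, forcing, s, window = window,
                   model_id = param_table$model[i]))
    names(runs) <- c("S0", "S1", "S2", "S3")
    structure(list(model_id = param_table$model[i], params = p,
                   flags = runs$S0$flags, runs = runs),
              class = "scenario_quartet")
  })
  structure(list(quartets = quartets, param_table = param_table,
                 forcing = forcing, seed = as.integer(seed)),
            class = "ensemble")
}
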