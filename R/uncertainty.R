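#' Ensemble mean and spread
#'
#' Arithmetic mean and sample (n-1) standard deviation across models,
#' the "mean +/- std. dev." convention for small multi-model ensembles.
#'
#' @param x numeric vector of per-model values (n >= 2 for the sd).
#' @return named numeric vector `c(mean, sd)`.
#' @export
ensemble_stats <- function(x) {
  if (length(x) < 2) stop("need at least 2 models for a spread")
  c(mean = mean(x), sd = stats::sd(x))
}

#' Decompose ensemble spread of a steady-state stock change into four
#' process factors
#'
#' The steady-state change dC-hat = d_input*tau_ref + input_ref*d_tau +
#' d_input*d_tau is bilinear in four per-model factors: baseline input,
#' change in input, baseline turnover and change in turnover. For each
#' factor, dC-hat is recomputed per model using that model's own value of
#' the factor and the multi-model mean of the other three, and the
#' ensemble standard deviation of those values is that factor's spread
#' contribution. The interaction term takes each factor from whichever
#' slot it owns (own value for the factor of interest, ensemble mean
#' otherwise).
#'
#' @param factors data.frame with one row per model and columns
#'   `input_ref`, `d_input`, `tau_ref`, `d_tau` (n >= 2, no missing
#'   values).
#' @return data.frame with `component` (baseline_input, delta_input,
#'   baseline_turnover, delta_turnover, all_own) and `std_PgC`; `all_own`
#'   is the reference spread of dC-hat with every factor at its own
#'   per-model value.
#' @export
spread_decomposition <- function(factors) {
  need <- c("input_ref", "d_input", "tau_ref", "d_tau")
  if (!all(need %in% names(factors))) stop("missing factor column(s)")
  if (nrow(factors) < 2) stop("need at least 2 models")
  if (anyNA(factors[need])) stop("missing factor values")
  mu <- colMeans(factors[need])
  dhat <- function(input_ref, d_input, tau_ref, d_tau)
    d_input * tau_ref + input_ref * d_tau + d_input * d_tau
  own <- list(baseline_input = "input_ref", delta_input = "d_input",
              baseline_turnover = "tau_ref", delta_turnover = "d_tau")
  comp_sd <- vapply(names(own), function(comp) {
    args <- lapply(need, function(f)
      if (f == own[[comp]]) factors[[f]] else rep(mu[[f]], nrow(factors)))
    names(args) <- need
    stats::sd(do.call(dhat, args))
  }, numeric(1))
  all_own <- stats::sd(dhat(factors$input_ref, factors$d_input,
                            factors$tau_ref, factors$d_tau))
  data.frame(component = c(names(own), "all_own"),
             std_PgC = c(unname(comp_sd), all_own))
}

#' Model agreement on the direction of change
#'
#' Fraction of models agreeing with the majority sign; zeros count in the
#' denominator but toward neither sign. Grid cells (or regions) where the
#' fraction falls below the threshold are flagged for stippling.
#'
#' @param changes numeric vector of per-model signed changes (n >= 1).
#' @param threshold agreement threshold below which to stipple
#'   (default 0.8).
#' @return list with `fraction` and logical `stipple`.
#' @export
agreement_fraction <- function(changes, threshold = 0.8) {
  n <- length(changes)
  if (n < 1) stop("need at least one model")
  frac <- max(sum(changes > 0), sum(changes < 0)) / n
  list(fraction = frac, stipple = frac < threshold)
}
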