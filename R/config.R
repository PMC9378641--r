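#' Read a pipeline configuration
#'
#' YAML with `forcing` (years, co2, climate, lulcc blocks), `ensemble`
#' (n_models, parameter ranges, flag probabilities, analysis window) and
#' a master `seed`. The packaged default is at
#' `system.file("extdata", "default_config.yaml", package = "carbattrib")`.
#'
#' @param path YAML file; the packaged default when NULL.
#' @return nested list.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_config.yaml",
                        package = "carbattrib")
  yaml::read_yaml(path)
}

#' Build the shared forcing set from a configuration
#'
#' @param cfg list from [read_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return `forcing_set`.
#' @export
forcing_from_config <- function(cfg, seed = NULL) {
  f <- cfg$forcing
  lspec <- list(anchors = data.frame(year = f$lulcc$anchor_years,
                                     f_ag = f$lulcc$anchor_values),
                spike_year = f$lulcc$spike_year,
                spike_size = f$lulcc$spike_size %||% 0)
  generate_forcing(seq(f$start_year, f$end_year),
                   co2_spec = f$co2, climate_spec = f$climate,
                   lulcc_spec = lspec,
                   seed = seed %||% cfg$seed)
}

#' Build a synthetic ensemble from a configuration
#'
#' @param cfg list from [read_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return `ensemble`.
#' @export
ensemble_from_config <- function(cfg, seed = NULL) {
  e <- cfg$ensemble
  seed <- seed %||% cfg$seed
  generate_ensemble(
    n_models = e$n_models,
    forcing = forcing_from_config(cfg, seed = seed),
    ranges = lapply(e$param_ranges, as.numeric),
    flag_probs = unlist(e$flag_probs),
    seed = seed,
    window = c(e$window_start, e$window_end))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
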