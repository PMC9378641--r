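# Default study configuration: an 18-member synthetic ensemble under the
# four-scenario factorial design, analysed over 1958-2020 (reference year
# 1959 for attribution).
seed: 1

forcing:
  start_year: 1850
  end_year: 2020
  co2:
    co2_ref: 284        # ppm, pre-industrial
    growth_rate: 0.0022 # exponential ppm growth per year (~412 ppm by 2020)
  climate:
    onset: 1900         # first year of warming trend and interannual noise
    trend: 0.010        # K per year (~1.2 K by 2020)
    sigma: 0.1          # K, interannual Gaussian noise, shared by all models
  lulcc:
    anchor_years: [1850, 1900, 1960, 2020]
    anchor_values: [0.10, 0.15, 0.28, 0.32]  # agricultural land fraction
    spike_year: 1960    # artificial excursion exercising the spike correction
    spike_size: 0.02

ensemble:
  n_models: 18
  window_start: 1958
  window_end: 2020
  param_ranges:         # sampled uniformly, independently per model
    npp0: [45, 65]      # PgC/yr baseline natural NPP
    rho_ag: [0.5, 0.9]  # relative productivity of agricultural land
    beta: [0.3, 0.7]    # CO2 fertilisation coefficient
    gamma: [-0.02, 0.02] # 1/K climate sensitivity of NPP
    tau_v_nat: [8, 25]  # yr vegetation turnover, natural land
    tau_v_ag: [1, 3]    # yr vegetation turnover, agricultural land
    tau_lit: [2, 5]     # yr litter turnover
    tau_s0: [15, 40]    # yr soil turnover at zero anomaly
    q10: [1.5, 2.5]     # temperature sensitivity of soil turnover
    eps_lit: [0.3, 0.6] # litter-to-soil transfer fraction
    lambda_lu: [0.5, 1] # clearing intensity
    p_atm: [0.4, 0.8]   # cleared-biomass fraction emitted directly
    cwd_frac: [0.3, 0.5] # reported CWD share of the litter stock
  flag_probs:
    has_litter: 0.9
    has_cwd: 0.25
    litter_in_soil: 0.1
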