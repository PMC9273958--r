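# shared fixtures: packaged parameter sets and small deterministic forcings

hairtail_deb <- deb_params()
hairtail_ibm <- ibm_params()

# constant, noise-free forcing for closed-form population checks
constant_forcing <- function(years = 1, temp = 20, food = 1, zf = 0,
                             dt = 0.5) {
  synthesize_forcings(
    years = years, seed = 1, dt = dt,
    temp_mean = temp, temp_amplitude = 1e-6, warming_slope = 0,
    anomaly_sd = 0, anomaly_phi = 0,
    food_profile = rep(food, 12), food_year_sd = 0,
    flow_sd = 0, rain_sd = 0, zf_annual = rep(zf, years)
  )
}

# an ibm parameter set with every mortality source switched off
no_mortality_ibm <- function(...) {
  ibm_params(M_egg = 0, M_d = 0, M_cm = 0, M_flow = 0, M_rain = 0,
             e_age = 0, Z_starve = 0, R_h = 1, cohort_floor = 0, ...)
}
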