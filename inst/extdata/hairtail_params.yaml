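# DEB (abj) and IBM parameter set for the East China Sea hairtail.
# Rates are given at the reference temperature T_ref = 293.15 K.
deb:
  z: 5.78            # zoom factor (-), relative to reference L_m = 1 cm
  v_dot: 0.0334      # energy conductance (cm/d)
  kappa: 0.968       # allocation fraction to soma (-)
  kappa_R: 0.95      # fraction of reproductive energy fixed in eggs (-)
  p_M_vol: 67.46     # volume-specific maintenance (J/cm^3/d)
  E_G: 5240          # volume-specific cost of structure (J/cm^3)
  k_J_dot: 0.002     # maturity maintenance rate coefficient (1/d)
  delta_M: 0.165     # shape coefficient (-)
  T_A: 8500          # Arrhenius temperature (K)
  T_H: 297           # upper boundary of tolerance range (K)
  T_L: 278           # lower boundary of tolerance range (K)
  T_AH: 29000        # Arrhenius temperature above T_H (K)
  T_AL: 11000        # Arrhenius temperature below T_L (K)
  T_ref: 293.15      # reference temperature (K)
  E_Hb: 1.38e-2      # maturity threshold at birth (J)
  E_Hj: 0.105        # maturity at metamorphosis (J)
  E_Hp: 5435         # maturity at puberty (J)
  h_a_ddot: 1.12e-8  # Weibull ageing acceleration (1/d^2)
  s_G: 1.84e-4       # Gompertz stress coefficient (-)
  e_j_content: 8500  # energy content of reserve (J/g)
  d_V: 1             # specific density of structure (g/cm^3)
  dry_wet: 1         # dry:wet weight conversion (-)
ibm:
  T_min: 10          # minimum temperature for hatching (degC)
  R_h: 0.90          # hatching success probability (-)
  DD_min: 51.5       # degree-day threshold for hatching (degC d)
  M_egg: 0.083       # maximum daily egg predation rate (1/d)
  B_eggh: 2.0e+3      # half-saturation density, egg mortality (kg/km^2)
  M_d: 0.007         # maximum density-dependent mortality (1/d)
  B_fh: 2.2e+3        # half-saturation density, density mortality (kg/km^2)
  M_cm: 9.73e-4      # climate-related background mortality (1/d)
  M_flow: 4.03e-4    # river-flow mortality coefficient (1/d)
  M_rain: 6.03e-5    # rainfall mortality coefficient (1/d)
  e_age: 2.0e-6      # effect of age on mortality (1/d^2)
  Age_min: 730       # age threshold for ageing mortality (d)
  area: 1000         # reference area (km^2)
  spawn_window: [105, 288]  # day-of-year spawning window
  spawn_T_min: 14    # minimum spawning temperature (degC)
  spawn_interval: 5  # days between spawning events in the window
  fish_sel_length: 10  # minimum preanal length (cm) recruited to the fishery
  B_food: 2.0e+3       # half-scale of food competition (kg/km^2)
  Z_starve: 0.02       # starvation hazard (1/d)
  spawn_frac: 0.1      # buffer fraction spawned per event (batch spawning)
  cohort_floor: 1.0e-3 # abundance below which a cohort is dropped
  ind_weight_g: 140  # survey abundance-to-biomass conversion (g/individual)
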