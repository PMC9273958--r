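# debibm

A coupled **D**ynamic **E**nergy **B**udget / **I**ndividual-**B**ased
**M**odel of the hairtail *Trichiurus lepturus*, the most important demersal
fishery species of the East China Sea. The package is for fisheries and
ecological modellers who want to explore how individual energetics,
environmental variability and fishing pressure combine into population-level
dynamics — and to rerun the published warming and fishing scenarios for this
stock on reproducible synthetic forcings.

## What is inside

**Individual level** — an abj-type DEB model with metabolic acceleration:
reserve dynamics under the κ-rule

    ṗ_C = E (  [E_G] v̇ s_M L² + [ṗ_M] L³ ) / ( κE + [E_G] L³ ),

assimilation {ṗ_Am} s_M f L², maturity thresholds E_H^b / E_H^j / E_H^p
triggering birth, metamorphosis and puberty, acceleration s_M = L_j/L_b, a
five-parameter Arrhenius temperature correction, an embryo initial-reserve
solver (e(birth) = f), and Weibull/Gompertz ageing for the life-span trait.

**Trait layer** — Add-my-Pet-style zero-variate trait prediction, the
multiplicative symmetric bounded loss
F = Σᵢ Σⱼ w_ij (d_ij − p_ij)² / (d̄ᵢ² + p̄ᵢ²), MRE/SMSE goodness of fit, and
Nelder–Mead calibration of chosen parameters.

**Population level** — super-individual cohorts on an hourly scheduler over
a 1000-km² reference area: degree-day egg hatching, five mortality sources
(fishing, environment-related background, density-dependent, egg predation,
ageing), batch spawning from the reproduction buffer, shared-food
competition, and N_{t+Δt} = N_t exp(−ΣZ Δt) survival.

**Forcing & scenarios** — a seeded synthetic-forcing generator (seasonal
temperature with warming trend and AR(1) anomalies, autumn-peaked food
index, annual flow/rain anomalies, piecewise fishing mortality), CSV I/O,
and one-variable-at-a-time scenario transforms (SSP warming offsets +1.4 /
+2.7 / +4.4 °C; fishing effort ±10%).

## Worked example

```r
library(debibm)

# 1. trait predictions from the packaged parameter set
rep <- predict_trait_report(deb_params())
print(rep, n = 3)
#> # Zero-variate trait report (abj DEB)
#> # A tibble: 11 x 5
#>   trait unit  observed predicted     re
#>   <chr> <chr>    <dbl>     <dbl>  <dbl>
#> 1 a_b   d         3.29      4.22 0.282
#> 2 t_p   d       183       204.   0.117
#> 3 a_m   d      5475      5636.   0.0294
#> # i 8 more rows
#> # MRE = 0.291  SMSE = 0.067  (s_M = 1.963, E_0 = 1.381 J)
```

The ultimate preanal length row reads 68.75 cm against an observation of
89.6 cm (relative error 0.23); length at puberty is 16.49 cm, ultimate
weight 5526 g. `s_M` is the metabolic acceleration factor the solver found,
and `E_0` the energy cost of one egg.

```r
# 2. a population run on synthetic forcings and the scenario battery
fc  <- synthesize_forcings(years = 20, seed = 1, dt = 1/6)
sim <- run_simulation(fc, spinup_years = 4, record_every = 10)
glance(sim)
#> # A tibble: 1 x 9
#>   label    seed years spinup_years mean_biomass_kg_km2 mean_biomass_sel_kg_km2
#> 1 baseline    1    20            4              19820.                   6828.
#>   mean_age_y mean_age_sel_y final_abundance
#>        0.369           1.44     3110540970.

run_scenarios(fc, spinup_years = 4, record_every = 10)
#> # A tibble: 6 x 5
#>   label    temperature_offset fishing_multiplier mean_biomass_kg_km2 pct_change
#> 1 baseline                0                  1                 6828.      0
#> 2 SSP1-1.9                1.4                1                 6516.     -4.57
#> 3 SSP2-4.5                2.7                1                 6284.     -7.97
#> 4 SSP5-8.5                4.4                1                 5576.    -18.3
#> 5 ZF+10%                  0                  1.1               6742.     -1.26
#> 6 ZF-10%                  0                  0.9               7106.      4.07
```

The scenario table compares the *surveyed* (gear-selected) stock biomass,
averaged over the post-spin-up window: warming lowers it monotonically (the
summer sea increasingly exceeds the upper thermal tolerance boundary, 297 K,
suppressing growth and reproduction), more fishing lowers it, less fishing
raises it. The time-averaged surveyed stock is dominated by one-year-old
fish with a mean age of about 1.4-1.6 years. `autoplot(sim)` and
`autoplot(fc)` give quick-look figures.

A shell front end wrapping the same functions lives at
`inst/scripts/debibm` (subcommands `predict-traits`, `simulate`,
`scenarios`, `synth-forcings`).

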