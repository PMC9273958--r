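---
title: "Methods: the coupled DEB-IBM for the East China Sea hairtail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coupled DEB-IBM for the East China Sea hairtail}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debibm)
```

`debibm` couples an individual-level dynamic energy budget (DEB) model of
the hairtail *Trichiurus lepturus* to a cohort-based population simulator,
so that population dynamics emerge from individual energetics, environmental
forcing, and density-dependent mortality. This vignette explains the model,
the numerical choices, and — importantly — which design decisions were open
and how the package resolved them.

## The individual model: abj DEB with metabolic acceleration

Each individual carries four energy state variables: structural length $L$
(cm), reserve $E$ (J), maturity $E_H$ (J) and a reproduction buffer $E_R$
(J). Assimilation from food is
$\dot p_A = \{\dot p_{Am}\}\, s_M\, f\, L^2$, where
$f \in [0,1]$ is the scaled functional response and
$\{\dot p_{Am}\} = z\,[\dot p_M]/\kappa$ follows from the zoom factor $z$
(the reference maximum length is 1 cm, so the maximum structural length is
$z$ cm). Reserve is mobilized at

$$\dot p_C \;=\; E\,
\frac{[E_G]\,\dot v\,s_M\,L^2 + [\dot p_M]\,L^3}{\kappa E + [E_G]\,L^3},$$

and split by the $\kappa$-rule: a fraction $\kappa$ pays somatic
maintenance $[\dot p_M]L^3$ with priority and funds growth; the remainder
pays maturity maintenance $\dot k_J E_H$ and then maturation (before
puberty, $E_H < E_H^p$) or the reproduction buffer (after). The model is of
the *abj* family: between birth ($E_H^b$) and metamorphosis ($E_H^j$) the
surface-linked parameters $\{\dot p_{Am}\}$ and $\dot v$ are multiplied by
the acceleration factor $s_M = L/L_b$, frozen afterwards at $L_j/L_b$.
With the packaged parameters the solver finds $s_M \approx 1.963$, which
fixes the asymptotic structural length at $s_M z$ and the ultimate preanal
length at $s_M z / \delta_M \approx 68.8$ cm.

All rates share one five-parameter Arrhenius temperature correction with
tolerance boundaries ($T_L$, $T_H$) and boundary rates ($T_{AL}$,
$T_{AH}$); the correction is 1 at $T_{ref} = 293.15$ K. The parameter table
omits a reference temperature, so the package adopts the Add-my-Pet
convention of reporting rates at 20 °C.

**Embryo and egg cost.** Embryos assimilate nothing. The egg energy
content $E_0$ is found by bisection so that the scaled reserve density at
birth equals the mother's $f$ (the Add-my-Pet initial-condition rule);
`initial_reserve()` returns $E_0 \approx 1.381$ J at $f = 1$, together with
the age and length at birth.

**Starvation rule.** When $\kappa \dot p_C$ cannot cover somatic
maintenance, the deficit is paid from the reproduction buffer; individuals
do not shrink. Once the buffer is exhausted, the individual is starving:
the solitary stepper flags it, and in the population model the cohort
receives an additional starvation hazard `Z_starve` (default 0.02 d⁻¹, an
e-folding time of 50 days — fish in energy deficit die within weeks to
months, larger fish surviving on their reserves). The source model is
silent on starvation; this is the package's rule.

**Weights.** A state converts to observables as preanal length
$L/\delta_M$ and weight $d_V L^3 + (E + E_R)/e_j$. The *trait layer*
evaluates weights with the reserve at its equilibrium density
$e = E \dot v /(L^3 \{\dot p_{Am}\} s_M) = f$, i.e.
$W = L^3\,(d_V + f\,s_M\{\dot p_{Am}\}/(\dot v\,e_j))$. This convention —
reserve capacity scaled by $s_M$ — is the one consistent with the published
weight predictions (which imply a constant reserve-to-structure mass ratio
of about 2.6); the canonical dynamic equilibrium $E = (\{\dot p_{Am}\}/\dot
v) L^3$ would give weights about a third lower. The simulator's cohort
weights use the actual dynamic reserve.

**Numerics.** Trait predictions use `deSolve::lsodar` (adaptive, with root
detection at the maturity thresholds; relative tolerance 1e-10). The
population scheduler uses fixed-step explicit Euler at the forcing step
(1 hour by default); a one-year Euler trajectory at 1 h stays within 1% of
the adaptive solution, and halving the step shrinks the one-step difference
quadratically, as expected for a first-order scheme. Ageing
(Weibull/Gompertz) is integrated only for the life-span trait; population
ageing mortality uses the linear age rule below, because the hazard-based
contribution is negligible at the population's low mean age.

## Trait prediction and calibration

`predict_traits()` derives the eleven zero-variate traits (ages, lengths,
weights, GSI, maximum reproduction rate) from a parameter vector. Lengths
and weights are temperature-invariant; ages and rates scale with the
Arrhenius correction. Two conventions were open and are resolved as:

* **GSI** — one year's reproduction-buffer output
  $\kappa_R \dot p_R \cdot 365$ (as mass) over body mass, evaluated at the
  mean adult size $(L_p + L_\infty)/2$.
* **Life span** — the age at which the Weibull/Gompertz survival drops to
  $e^{-1}$, at the evaluation temperature.
* The evaluation temperature of the published age-based traits is not
  stated; the package reports them at $T_{ref}$, where the predicted time
  to puberty (204 d) matches the published 205 d, while the age at birth
  (4.2 d vs 3.5 d) suggests the embryo trait was evaluated a few degrees
  warmer. Age-based traits are therefore reported but not treated as
  benchmarks.

The loss is the multiplicative symmetric bounded form
$F = \sum_i \sum_j w_{ij} (d_{ij}-p_{ij})^2/(\bar d_i^2 + \bar p_i^2)$,
with Add-my-Pet default weights $1/n_i$ per dataset; goodness of fit is
summarized by MRE (weighted mean of $|d-p|/|d|$) and SMSE (weighted mean of
$(d-p)^2/(d^2+p^2)$, bounded in $[0,1]$ for non-negative data).
`calibrate()` runs Nelder-Mead on log-parameters, which keeps them positive
and makes the search deterministic; a two-parameter synthetic-recovery test
returns the truth to better than 0.1%. The published MRE (0.128) and SMSE
(0.143) cannot be recomputed exactly because the univariate datasets and
weights behind them are not published; the package checks instead that the
zero-variate part of the arithmetic is reproduced.

## Environmental forcing

`synthesize_forcings()` generates seeded, reproducible forcing series with
the qualitative structure of the East China Sea record:

* **Temperature** — mean 19.5 °C, seasonal semi-amplitude 6.5 °C peaking in
  mid-August, a warming trend of 0.02 °C y⁻¹, and monthly AR(1) anomalies
  (sd 0.5 °C, lag-1 correlation 0.6). These are field-typical values for
  the stock's distribution area, chosen once.
* **Food index** — a 12-value monthly profile, autumn-peaked and
  winter-trough, with lognormal interannual variation (sd 0.10). The index
  maps to the functional response through a type-II form
  $f = X/(X + K_{food})$ with $K_{food} = 0.22$, chosen so the long-term
  mean maps to $f \approx 0.8$.
* **Annual series** — Yangtze flow (mean 9.2×10¹¹ m³, sd 8×10¹⁰) and
  rainfall (1.10 m, sd 0.15) converted to anomaly indices with the fixed
  correction factors 10¹² m³ and 1 m; and a piecewise fishing-mortality
  schedule (0.0012 d⁻¹ ramping to 0.0035 d⁻¹ by year 20, easing to
  0.0022 d⁻¹), a stylized exploitation history. Annual fishing mortality
  expands within years as a step function by default (linear interpolation
  between year midpoints is available).
* **Calendar** — 365-day years, 12 equal months, no leap days.

Scenarios add a uniform temperature offset and/or multiply fishing
mortality; nothing else changes. The presets encode the SSP warming offsets
for 2100 (+1.4, +2.7, +4.4 °C) and ±10% fishing effort.

What the generator does *not* emulate: the actual 1965–2007 survey series
(available only as figures in the source), spatial structure, and any
correlation between food and temperature anomalies. Tests passing on
synthetic forcing therefore demonstrate the model's mechanisms and
directional responses, not a hindcast of the historical series.

## The population model

Cohorts are real-valued super-individuals: all fish spawned in one event
share a DEB state, an abundance, a stage (egg-larva, juvenile, female,
male), accumulated degree days and a generation label. Hatching requires
both the degree-day threshold ($DD = \int (T - T_{min})^+ dt \ge
DD_{min}$) and the DEB birth threshold $E_H \ge E_H^b$; on hatching the
abundance is multiplied by the success probability $R_h$ and feeding
begins. Juveniles become adults (50:50 female:male split) at $E_H^p$.

**Mortality** is stage-dependent, applied as
$N_{t+\Delta t} = N_t e^{-\sum Z\,\Delta t}$:

| stage | sources |
|---|---|
| egg-larva | $Z_{egg}$ (type-II in fish density) + $Z_B$ |
| juvenile | $Z_B + Z_D$ (+ $Z_F$ above the selectivity length) |
| adult | $Z_B + Z_D + Z_{age} + Z_F$ |

with $Z_B = (M_{cm} - M_{flow}\,Flow_{idx} - M_{rain}\,Rain_{idx})^+$
(clamped: negative mortality would resurrect fish), $Z_D = M_d
B/(B+B_{fh})$, $Z_{egg} = M_{egg} B/(B+B_{eggh})$ and $Z_{age} =
e_{age}(Age - Age_{min})^+$. Fishing applies above a preanal length of
10 cm: the bottom-trawl fishery for this stock is strongly
juvenile-dominated, and restricting fishing to post-puberty fish would
leave most of the real catch unmodeled. The selectivity length is a knob
(`fish_sel_length`).

**Food competition.** The food index is treated as a shared resource:
per-capita food is $X/(1 + B/B_{food})$ before the type-II mapping, with
$B_{food} = 2000$ kg km⁻² (the same order as the printed mortality
half-saturations, i.e. competition becomes material at the densities where
cannibalism does). This feedback is essential: the printed mortality
coefficients saturate at rates far too small to balance DEB-level
fecundity, so without a food feedback the stock grows without bound. The
source frames food as shared equally among individuals; the NetLogo
framework it builds on regulates populations the same way.

**Reproduction.** Inside the spawning window (day-of-year 105–288, water
temperature ≥ 14 °C — config defaults, not claims about the stock) each
female converts a batch of her buffer into eggs every 5 days:
$\lfloor \rho\,\kappa_R E_R / E_0 \rfloor$ eggs per female with batch
fraction $\rho = 0.1$ (hairtail are batch spawners over a prolonged
season); the energy spent is $E_0/\kappa_R$ per egg. All eggs of one event
form one cohort.

**Scheduler order** (per step): DEB update of all cohorts (embryos at
$f = 0$) → degree days and hatching → puberty transitions → mortalities →
spawning (on event days) → pruning of cohorts below 10⁻³ individuals.
Everything is deterministic given the forcing; randomness lives only in the
forcing generator's seed.

**Initialization and spin-up.** `init_population()` grows reference
individuals at constant food and temperature and seeds four cohorts (ages
0.5–3.5 y, ~10⁷ fish in total, buffers spawned out). Doubling the seeding
changes the post-spin-up mean biomass by far less than 20%; runs flag their
spin-up years (default the first 5 in the experiment wrappers) so
statistics can discard the transient.

## Emergent behaviour, metrics and known limitations

Under default synthetic forcing the stock regulates at a few thousand
kg km⁻² of surveyed biomass with pronounced multi-year cohort cycles — an
overcompensating stock-recruitment loop (egg flood → food scarcity →
starvation and stunting → recovery) that the mortality caps cannot smooth.
The *surveyed* (gear-selected) component is dominated by one-year-old fish
with a time-averaged mean age near 1.5 y, close to the survey-derived
values reported for this stock; the full count including young-of-year
juveniles is necessarily younger.

Scenario comparisons are made on the gear-selected stock biomass averaged
over a multi-year post-spin-up window (the package's tests use 16 analysis
years, echoing the 38-year averaging of the source). Two reasons: the
historical biomass the model family is validated against is
survey-derived, hence gear-selected; and in a food-competition model,
culling large fish can marginally *raise* total biomass (thinning) while
depleting the harvestable stock, so the total is the wrong axis for
fishery-relevant statements. With this metric, warming offsets of +1.4,
+2.7 and +4.4 °C produce strictly decreasing mean biomass on every tested
seed (the mechanism: summer temperatures increasingly exceed the upper
tolerance boundary $T_H = 297$ K, suppressing assimilation and
reproduction in the growing season), and ±10% fishing moves biomass in the
expected directions in every paired run.

Limitations worth keeping in mind: no spatial structure or migration; no
ocean-acidification pathway; food seasonality is qualitative, not a
reconstructed prey series; the cohort cycles are stronger than anything in
the historical record, so quantitative scenario percentages from synthetic
forcing should be read as directions and orders of magnitude, not
forecasts; and the ~4–5% gap between the package's weight traits and the
published ones reflects an unrecoverable convention in the source (its
printed weights imply a reserve ratio of 2.62–2.65 against the 2.78
derivable from the printed parameters).

## Problem sizes used by the shipped checks

The test-suite experiments use 20-year forcings at a 4-hour step for the
scenario battery (five seeds, paired runs), an hourly step for a 5-year
run, and adaptive integrations for all trait work; the acceptance script
recomputes the five headline trait predictions (lengths at birth and
puberty, ultimate length, weights at puberty and ultimate) from the
packaged parameter file at $f = 1$. These sizes were chosen so a complete
check runs comfortably on a laptop while leaving every scientific claim
exercised by at least one test.
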