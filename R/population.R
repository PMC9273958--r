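STAGE_EGG <- 0L; STAGE_JUV <- 1L; STAGE_F <- 2L; STAGE_M <- 3L
stage_labels <- c("egg_larva", "juvenile", "female", "male")

new_population <- function(cohorts, t = 0) {
  structure(list(cohorts = cohorts, t = t), class = "debibm_population")
}

empty_cohorts <- function() {
  list(stage = integer(0), n = numeric(0), L = numeric(0), E = numeric(0),
       EH = numeric(0), ER = numeric(0), age = numeric(0), dd = numeric(0),
       sM = numeric(0), Lb = numeric(0), born = numeric(0), gen = integer(0))
}

#' Cohort table of a population
#'
#' @param x a `debibm_population`.
#' @param ... unused.
#' @return a tibble with one row per super-individual cohort.
#' @method as_tibble debibm_population
#' @export
as_tibble.debibm_population <- function(x, ...) {
  co <- x$cohorts
  tibble(stage = stage_labels[co$stage + 1L], n = co$n, L = co$L, E = co$E,
         E_H = co$EH, E_R = co$ER, age = co$age, dd = co$dd, s_M = co$sM,
         born = co$born, generation = co$gen)
}

#' @export
print.debibm_population <- function(x, ...) {
  co <- x$cohorts
  cat(sprintf("<debibm_population> t = %.2f d, %d cohort(s)\n",
              x$t, length(co$n)))
  for (s in 0:3) {
    sel <- co$stage == s
    if (any(sel)) {
      cat(sprintf("  %-10s %8.3g individuals in %d cohort(s)\n",
                  stage_labels[s + 1L], sum(co$n[sel]), sum(sel)))
    }
  }
  invisible(x)
}

#' Initialize a seed population
#'
#' Builds the starting cohorts by growing a reference individual at constant
#' food and temperature and taking snapshots at the requested ages. Cohorts
#' older than the age at puberty are split 50:50 into females and males.
#' Initialization details are forgotten after the spin-up period.
#'
#' @param deb_pars a [deb_params()] object.
#' @param ibm_pars an [ibm_params()] object.
#' @param ages_y cohort ages (years).
#' @param abundance individuals per cohort (recycled).
#' @param f constant functional response used to grow the reference states.
#' @param T_C constant temperature (degC).
#' @return a `debibm_population` at `t = 0`.
#' @examples
#' \donttest{
#' pop <- init_population(deb_params(), ibm_params())
#' pop
#' }
#' @export
init_population <- function(deb_pars, ibm_pars,
                            ages_y = c(0.5, 1.5, 2.5, 3.5),
                            abundance = c(6e6, 3e6, 8e5, 2e5),
                            f = 0.8, T_C = 20) {
  stopifnot(length(ages_y) >= 1, all(ages_y > 0))
  abundance <- rep_len(abundance, length(ages_y))
  birth <- initial_reserve(deb_pars, f = f)
  st <- deb_state(L = 1e-5, E = birth$E_0)
  dt <- 0.25
  targets <- sort(ages_y * 365)
  snaps <- vector("list", length(targets))
  k <- 1L
  T_K <- T_C + 273.15
  while (k <= length(targets)) {
    st <- step_individual(st, f = if (st$E_H >= deb_pars$E_Hb) f else 0,
                          T_K = T_K, dt = dt, pars = deb_pars)
    if (st$age >= targets[k]) {
      snaps[[k]] <- st
      k <- k + 1L
    }
  }
  ord <- order(ages_y * 365)
  co <- empty_cohorts()
  for (i in seq_along(targets)) {
    s <- snaps[[i]]
    nn <- abundance[ord[i]]
    adult <- s$E_H >= deb_pars$E_Hp
    stages <- if (adult) c(STAGE_F, STAGE_M) else STAGE_JUV
    ns <- if (adult) c(nn / 2, nn / 2) else nn
    for (j in seq_along(stages)) {
      co$stage <- c(co$stage, stages[j]); co$n <- c(co$n, ns[j])
      co$L <- c(co$L, s$L); co$E <- c(co$E, s$E)
      co$EH <- c(co$EH, s$E_H); co$ER <- c(co$ER, 0)
      co$age <- c(co$age, s$age); co$dd <- c(co$dd, 0)
      co$sM <- c(co$sM, s$s_M); co$Lb <- c(co$Lb, s$L_b)
      co$born <- c(co$born, -s$age); co$gen <- c(co$gen, 0L)
    }
  }
  new_population(co, t = 0)
}

#' Accumulate degree days of egg-larva cohorts
#'
#' `DD` grows by `(T - T_min) * dt` whenever the temperature exceeds the
#' hatching threshold `T_min`; it never decreases and only egg-larva cohorts
#' accumulate.
#'
#' @param pop a `debibm_population`.
#' @param T_C water temperature (degC).
#' @param dt step (d).
#' @param pars an [ibm_params()] object.
#' @return the updated population.
#' @export
update_degree_days <- function(pop, T_C, dt, pars) {
  egg <- pop$cohorts$stage == STAGE_EGG
  pop$cohorts$dd[egg] <- pop$cohorts$dd[egg] + max(T_C - pars$T_min, 0) * dt
  pop
}

#' Hatching of egg-larva cohorts
#'
#' A cohort hatches once its accumulated degree days reach `DD_min` and its
#' maturity has reached the birth threshold `E_Hb`: its abundance is
#' multiplied by the hatching success `R_h`, it becomes a feeding juvenile
#' cohort, and the rule is applied exactly once (the stage change makes the
#' operation idempotent).
#'
#' @inheritParams update_degree_days
#' @param deb_pars a [deb_params()] object.
#' @return the updated population.
#' @export
hatch <- function(pop, pars, deb_pars) {
  co <- pop$cohorts
  sel <- co$stage == STAGE_EGG & co$dd >= pars$DD_min & co$EH >= deb_pars$E_Hb
  if (any(sel)) {
    co$n[sel] <- co$n[sel] * pars$R_h
    co$stage[sel] <- STAGE_JUV
    pop$cohorts <- co
  }
  pop
}

#' Fish density over the reference area
#'
#' Total wet biomass of post-egg cohorts divided by the reference area
#' (kg/km^2); the density entering the density-dependent and egg-predation
#' mortalities.
#'
#' @param pop a `debibm_population`.
#' @param pars an [ibm_params()] object.
#' @param deb_pars a [deb_params()] object.
#' @return density in kg/km^2.
#' @export
fish_density <- function(pop, pars, deb_pars) {
  co <- pop$cohorts
  sel <- co$stage >= STAGE_JUV
  if (!any(sel)) return(0)
  w_g <- cohort_weight_g(co$L[sel], co$E[sel], co$ER[sel], deb_pars)
  sum(co$n[sel] * w_g) / 1000 / pars$area
}

cohort_weight_g <- function(L, E, ER, deb_pars) {
  (deb_pars$d_V * L^3 + (E + ER) / deb_pars$e_j_content) / deb_pars$dry_wet
}

#' Spawning
#'
#' Inside the spawning window and above the spawning temperature, each
#' female converts a batch of her reproduction buffer into eggs at the egg
#' cost `E_0 / kappa_R`: `floor(spawn_frac * kappa_R * E_R / E_0)` eggs per
#' female and event (hairtail are batch spawners over a prolonged season).
#' The buffer is reduced by the energy spent and all eggs of the event are
#' appended as one new egg-larva cohort sharing the embryo state.
#'
#' @inheritParams fish_density
#' @param T_C water temperature (degC).
#' @param E_0 initial reserve per egg (J), from [initial_reserve()].
#' @return the updated population.
#' @export
spawn <- function(pop, T_C, pars, deb_pars, E_0) {
  if (E_0 <= 0) abort("E_0 must be positive")
  doy <- pop$t %% 365
  if (doy < pars$spawn_window[1] || doy > pars$spawn_window[2] ||
      T_C < pars$spawn_T_min) {
    return(pop)
  }
  co <- pop$cohorts
  fem <- which(co$stage == STAGE_F & co$n > 0)
  if (!length(fem)) return(pop)
  eggs_pf <- floor(pars$spawn_frac * deb_pars$kappa_R * co$ER[fem] / E_0)
  has <- eggs_pf > 0
  if (!any(has)) return(pop)
  fem <- fem[has]; eggs_pf <- eggs_pf[has]
  co$ER[fem] <- co$ER[fem] - eggs_pf * E_0 / deb_pars$kappa_R
  n_new <- sum(eggs_pf * co$n[fem])
  co$stage <- c(co$stage, STAGE_EGG); co$n <- c(co$n, n_new)
  co$L <- c(co$L, 1e-5); co$E <- c(co$E, E_0)
  co$EH <- c(co$EH, 0); co$ER <- c(co$ER, 0)
  co$age <- c(co$age, 0); co$dd <- c(co$dd, 0)
  co$sM <- c(co$sM, 1); co$Lb <- c(co$Lb, NA_real_)
  co$born <- c(co$born, pop$t)
  co$gen <- c(co$gen, as.integer(floor(pop$t / 365)) + 1L)
  pop$cohorts <- co
  pop
}

# one scheduler step over the cohort vectors; `do_spawn` marks spawning-event
# steps. Order: DEB update -> degree days & hatching -> stage transitions ->
# mortalities -> spawning -> pruning.
step_cohorts <- function(co, t, T_C, TC, food, K_food, Z_F, Z_B, dt, deb, ibm,
                         E_0, do_spawn) {
  if (!length(co$n)) return(co)
  pAm <- deb$z * deb$p_M_vol / deb$kappa
  L <- co$L; E <- co$E; EH <- co$EH; ER <- co$ER; sM <- co$sM
  feeding <- co$stage >= STAGE_JUV

  # fish density at the start of the step: drives food competition and the
  # density-dependent mortalities
  B <- if (any(feeding)) {
    sum(co$n[feeding] *
          cohort_weight_g(L[feeding], E[feeding], ER[feeding], deb)) /
      1000 / ibm$area
  } else 0
  # the food index is a shared resource: per-capita availability declines
  # with stock biomass before the type-II mapping to f
  f_env <- functional_response(food / (1 + B / ibm$B_food), K_food)
  f <- ifelse(feeding, f_env, 0)

  pA <- TC * pAm * sM * f * L^2
  pC <- TC * E * (deb$E_G * deb$v_dot * sM * L^2 + deb$p_M_vol * L^3) /
    (deb$kappa * E + deb$E_G * L^3)
  pS <- TC * deb$p_M_vol * L^3
  growth <- deb$kappa * pC - pS
  deficit <- pmax(-growth, 0)
  growth <- pmax(growth, 0)
  pR <- (1 - deb$kappa) * pC - TC * deb$k_J_dot * EH
  adult <- EH >= deb$E_Hp

  L2 <- L + growth / (3 * L^2 * deb$E_G) * dt
  E2 <- pmax(E + (pA - pC) * dt, 0)
  EH2 <- ifelse(adult, EH, EH + pmax(pR, 0) * dt) # no rejuvenation
  ER2 <- ER + (ifelse(adult, pmax(pR, 0), 0) - deficit) * dt
  starved <- ER2 < 0 & deficit > 0
  ER2 <- pmax(ER2, 0)

  newborn <- is.na(co$Lb) & EH2 >= deb$E_Hb
  co$Lb[newborn] <- L2[newborn]
  accel <- !is.na(co$Lb) & EH < deb$E_Hj
  sM[accel] <- pmax(1, L2[accel] / co$Lb[accel])

  co$L <- L2; co$E <- E2; co$EH <- EH2; co$ER <- ER2; co$sM <- sM
  co$age <- co$age + dt

  # degree days and hatching
  egg <- co$stage == STAGE_EGG
  if (any(egg)) {
    co$dd[egg] <- co$dd[egg] + max(T_C - ibm$T_min, 0) * dt
    h <- egg & co$dd >= ibm$DD_min & co$EH >= deb$E_Hb
    if (any(h)) {
      co$n[h] <- co$n[h] * ibm$R_h
      co$stage[h] <- STAGE_JUV
    }
  }

  # puberty: split juveniles into females and males 50:50
  pub <- which(co$stage == STAGE_JUV & co$EH >= deb$E_Hp)
  if (length(pub)) {
    half <- co$n[pub] / 2
    co$stage[pub] <- STAGE_F
    co$n[pub] <- half
    for (fld in names(co)) {
      co[[fld]] <- c(co[[fld]], co[[fld]][pub])
    }
    starved <- c(starved, starved[pub])
    idx <- (length(co$n) - length(pub) + 1L):length(co$n)
    co$stage[idx] <- STAGE_M
  }

  # mortalities (stage-dependent)
  post <- co$stage >= STAGE_JUV
  Z_D <- ibm$M_d * B / (B + ibm$B_fh)
  Z_e <- ibm$M_egg * B / (B + ibm$B_eggh)
  Z_age <- ibm$e_age * pmax(co$age - ibm$Age_min, 0)
  fished <- post & (co$L / deb$delta_M) >= ibm$fish_sel_length
  Z <- ifelse(post, Z_B + Z_D + Z_age + Z_F * fished, Z_B + Z_e) +
    ibm$Z_starve * starved
  co$n <- co$n * exp(-Z * dt)

  # spawning event
  if (do_spawn) {
    fem <- which(co$stage == STAGE_F & co$n > 0)
    if (length(fem)) {
      eggs_pf <- floor(ibm$spawn_frac * deb$kappa_R * co$ER[fem] / E_0)
      has <- eggs_pf > 0
      if (any(has)) {
        fem <- fem[has]; eggs_pf <- eggs_pf[has]
        co$ER[fem] <- co$ER[fem] - eggs_pf * E_0 / deb$kappa_R
        n_new <- sum(eggs_pf * co$n[fem])
        co$stage <- c(co$stage, STAGE_EGG); co$n <- c(co$n, n_new)
        co$L <- c(co$L, 1e-5); co$E <- c(co$E, E_0)
        co$EH <- c(co$EH, 0); co$ER <- c(co$ER, 0)
        co$age <- c(co$age, 0); co$dd <- c(co$dd, 0)
        co$sM <- c(co$sM, 1); co$Lb <- c(co$Lb, NA_real_)
        co$born <- c(co$born, t)
        co$gen <- c(co$gen, as.integer(floor(t / 365)) + 1L)
      }
    }
  }

  # pruning
  keep <- co$n > ibm$cohort_floor
  if (!all(keep)) {
    for (fld in names(co)) co[[fld]] <- co[[fld]][keep]
  }
  co
}

#' Advance the population by one scheduler step
#'
#' Looks up the forcing at the population's current time and performs one
#' full scheduler step: DEB update of every cohort (embryos at `f = 0`),
#' degree-day accumulation and hatching, puberty transitions with a 50:50
#' sex split, stage-dependent mortalities (eggs: `Z_egg + Z_B`; juveniles:
#' `Z_B + Z_D` plus fishing above the selectivity length; adults:
#' `Z_B + Z_D + Z_age + Z_F`), spawning on event days, and pruning of
#' cohorts below the abundance floor.
#'
#' @param pop a `debibm_population`.
#' @param forcings a `debibm_forcing` covering `pop$t`.
#' @param deb_pars,ibm_pars parameter objects.
#' @param E_0 egg cost (J); computed from [initial_reserve()] when `NULL`.
#' @return the advanced population (time moved by the forcing step).
#' @export
step_population <- function(pop, forcings, deb_pars, ibm_pars, E_0 = NULL) {
  dt <- forcings$dt
  i <- round(pop$t / dt) + 1L
  if (i < 1L || i > nrow(forcings$steps)) {
    abort(sprintf("forcing gap: no forcing step covering t = %.3f d", pop$t))
  }
  if (is.null(E_0)) E_0 <- initial_reserve(deb_pars, f = 1)$E_0
  T_C <- forcings$steps$temperature_C[i]
  TC <- arrhenius_factor(T_C + 273.15, deb_pars)
  food <- forcings$steps$food_index[i]
  Z_F <- forcings$steps$Z_F[i]
  yr <- min(floor(pop$t / 365) + 1L, nrow(forcings$annual))
  Z_B <- background_mortality(forcings$annual$flow_index[yr],
                              forcings$annual$rain_index[yr], ibm_pars)
  doy <- pop$t %% 365
  do_spawn <- (pop$t %% 1) < dt / 2 &&
    floor(doy) %% ibm_pars$spawn_interval == 0 &&
    doy >= ibm_pars$spawn_window[1] && doy <= ibm_pars$spawn_window[2] &&
    T_C >= ibm_pars$spawn_T_min
  pop$cohorts <- step_cohorts(pop$cohorts, pop$t, T_C, TC, food,
                              forcings$K_food, Z_F, Z_B, dt, deb_pars,
                              ibm_pars, E_0, do_spawn)
  pop$t <- pop$t + dt
  pop
}

#' Population summary record
#'
#' @param pop a `debibm_population`.
#' @param deb_pars a [deb_params()] object.
#' @param ibm_pars an [ibm_params()] object (for the area scaling).
#' @return a one-row tibble: time, post-egg abundance, wet biomass density
#'   (kg/km^2), abundance-weighted mean age of post-egg cohorts (years) and
#'   per-stage abundances. An empty population yields zeros.
#' @export
summarize_population <- function(pop, deb_pars, ibm_pars) {
  co <- pop$cohorts
  post <- co$stage >= STAGE_JUV
  n_post <- sum(co$n[post])
  mean_age <- if (n_post > 0) {
    sum(co$n[post] * co$age[post]) / n_post / 365
  } else 0
  tibble(
    t_days = pop$t,
    total_abundance = n_post,
    biomass_kg_km2 = fish_density(pop, ibm_pars, deb_pars),
    mean_age_y = mean_age,
    n_egg = sum(co$n[co$stage == STAGE_EGG]),
    n_juv = sum(co$n[co$stage == STAGE_JUV]),
    n_f = sum(co$n[co$stage == STAGE_F]),
    n_m = sum(co$n[co$stage == STAGE_M])
  )
}

#' Run a population simulation
#'
#' Drives the cohort scheduler over a full forcing series, recording
#' population summaries at a fixed cadence. The first `spinup_years` are
#' flagged so that statistics can discard the initialization transient. The
#' run is fully deterministic given the forcing series (randomness lives
#' only in the forcing generator's seed).
#'
#' @param forcings a `debibm_forcing`.
#' @param deb_pars,ibm_pars parameter objects (defaults: the packaged
#'   hairtail set).
#' @param init a `debibm_population` (default [init_population()]).
#' @param spinup_years years flagged as spin-up in the output.
#' @param record_every cadence of summary records (d).
#' @return a `debibm_sim` tibble (one row per record) with columns `t_days`,
#'   `year`, `total_abundance`, `biomass_kg_km2`, `mean_age_y`, `n_egg`,
#'   `n_juv`, `n_f`, `n_m`, the gear-selected component
#'   (`biomass_sel_kg_km2`, `mean_age_sel_y`, `abundance_sel` plus its
#'   completed-year age-class abundances `n_sel_age0`..`n_sel_age3p`, i.e.
#'   fish above the selectivity length, the component surveys sample) and
#'   `spinup`; attributes carry the scenario label,
#'   seed and parameters. If the population goes extinct the run continues
#'   and records zeros, with one warning.
#' @examples
#' \donttest{
#' fc <- synthesize_forcings(years = 3, seed = 1, dt = 0.25)
#' sim <- run_simulation(fc, spinup_years = 1)
#' glance(sim)
#' }
#' @export
run_simulation <- function(forcings, deb_pars = deb_params(),
                           ibm_pars = ibm_params(), init = NULL,
                           spinup_years = 5, record_every = 1) {
  stopifnot(inherits(forcings, "debibm_forcing"))
  if (is.null(init)) init <- init_population(deb_pars, ibm_pars)
  birth <- initial_reserve(deb_pars, f = 1)
  E_0 <- birth$E_0

  st <- forcings$steps
  dt <- forcings$dt
  nstep <- nrow(st)
  t_grid <- st$t_days
  TC_all <- arrhenius_factor(st$temperature_C + 273.15, deb_pars)
  food_all <- st$food_index
  Zf_all <- st$Z_F
  T_all <- st$temperature_C
  yr_all <- pmin(floor(t_grid / 365) + 1L, nrow(forcings$annual))
  ZB_year <- background_mortality(forcings$annual$flow_index,
                                  forcings$annual$rain_index, ibm_pars)
  doy <- t_grid %% 365
  day_start <- (t_grid %% 1) < dt / 2
  spawn_step <- day_start &
    floor(doy) %% ibm_pars$spawn_interval == 0 &
    doy >= ibm_pars$spawn_window[1] & doy <= ibm_pars$spawn_window[2] &
    T_all >= ibm_pars$spawn_T_min
  record_step <- day_start & (floor(t_grid) %% record_every == 0)

  co <- init$cohorts
  recs <- matrix(0, nrow = sum(record_step), ncol = 14)
  rec_t <- t_grid[record_step]
  r <- 0L
  warned_extinct <- FALSE
  for (i in seq_len(nstep)) {
    if (record_step[i]) {
      r <- r + 1L
      recs[r, ] <- record_row(co, deb_pars, ibm_pars)
      if (!warned_extinct && recs[r, 1] == 0 && i > 1L) {
        warn(sprintf("population extinct at t = %.1f d; run continues", t_grid[i]))
        warned_extinct <- TRUE
      }
    }
    co <- step_cohorts(co, t_grid[i], T_all[i], TC_all[i], food_all[i],
                       forcings$K_food, Zf_all[i], ZB_year[yr_all[i]], dt,
                       deb_pars, ibm_pars, E_0, spawn_step[i])
  }
  out <- tibble(
    t_days = rec_t,
    year = floor(rec_t / 365) + 1L,
    total_abundance = recs[, 1], biomass_kg_km2 = recs[, 2],
    mean_age_y = recs[, 3], n_egg = recs[, 4], n_juv = recs[, 5],
    n_f = recs[, 6], n_m = recs[, 7],
    biomass_sel_kg_km2 = recs[, 8], mean_age_sel_y = recs[, 9],
    abundance_sel = recs[, 10],
    n_sel_age0 = recs[, 11], n_sel_age1 = recs[, 12],
    n_sel_age2 = recs[, 13], n_sel_age3p = recs[, 14],
    spinup = rec_t < spinup_years * 365
  )
  structure(out, class = c("debibm_sim", class(tibble())),
            label = forcings$label, seed = forcings$seed, dt = dt,
            spinup_years = spinup_years,
            deb_pars = deb_pars, ibm_pars = ibm_pars,
            final = new_population(co, t = nstep * dt))
}

record_row <- function(co, deb, ibm) {
  post <- co$stage >= STAGE_JUV
  n_post <- sum(co$n[post])
  w_g <- cohort_weight_g(co$L, co$E, co$ER, deb)
  B <- if (any(post)) sum(co$n[post] * w_g[post]) / 1000 / ibm$area else 0
  mean_age <- if (n_post > 0) sum(co$n[post] * co$age[post]) / n_post / 365 else 0
  # the component selected by the (survey/fishery) gear
  sel <- post & (co$L / deb$delta_M) >= ibm$fish_sel_length
  n_sel <- sum(co$n[sel])
  B_sel <- if (any(sel)) sum(co$n[sel] * w_g[sel]) / 1000 / ibm$area else 0
  age_sel <- if (n_sel > 0) sum(co$n[sel] * co$age[sel]) / n_sel / 365 else 0
  cls <- pmin(floor(co$age / 365), 3)
  n_cls <- vapply(0:3, function(k) sum(co$n[sel & cls == k]), 0)
  c(n_post, B, mean_age,
    sum(co$n[co$stage == STAGE_EGG]), sum(co$n[co$stage == STAGE_JUV]),
    sum(co$n[co$stage == STAGE_F]), sum(co$n[co$stage == STAGE_M]),
    B_sel, age_sel, n_sel, n_cls)
}

#' @export
print.debibm_sim <- function(x, ...) {
  cat(sprintf("# Population simulation '%s' (%d records, dt = %.4g d)\n",
              attr(x, "label"), nrow(x), attr(x, "dt")))
  NextMethod()
  invisible(x)
}

#' @method tidy debibm_sim
#' @export
tidy.debibm_sim <- function(x, ...) as_tibble(x)

#' @method glance debibm_sim
#' @export
glance.debibm_sim <- function(x, ...) {
  post <- x[!x$spinup, ]
  tibble(
    label = attr(x, "label") %||% NA_character_,
    seed = attr(x, "seed") %||% NA_integer_,
    years = max(x$year),
    spinup_years = attr(x, "spinup_years") %||% NA_real_,
    mean_biomass_kg_km2 = mean(post$biomass_kg_km2),
    mean_biomass_sel_kg_km2 = mean(post$biomass_sel_kg_km2),
    mean_age_y = with(post, sum(mean_age_y * total_abundance) /
                        sum(total_abundance)),
    mean_age_sel_y = with(post, sum(mean_age_sel_y * abundance_sel) /
                            max(sum(abundance_sel), 1e-300)),
    final_abundance = post$total_abundance[nrow(post)]
  )
}

#' Post-spin-up mean biomass of a run
#'
#' The `"selected"` component is the stock above the gear selectivity
#' length, i.e. the component that surveys and the fishery sample; it is the
#' quantity scenario comparisons are made on, because removing large fish
#' can slightly raise the total (eggs-to-adults) biomass through relaxed
#' food competition while depleting the surveyed stock.
#'
#' @param sim a `debibm_sim`.
#' @param component `"selected"` (default) or `"total"`.
#' @return mean wet biomass density (kg/km^2) over the non-spin-up records.
#' @export
mean_biomass <- function(sim, component = c("selected", "total")) {
  component <- match.arg(component)
  col <- if (component == "selected") "biomass_sel_kg_km2" else "biomass_kg_km2"
  mean(sim[[col]][!sim$spinup])
}
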