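# build a bare population from explicit cohort vectors
make_pop <- function(stage, n, L, E = 0, EH = 0, ER = 0, age = 0, dd = 0,
                     sM = 1, Lb = NA_real_, t = 0) {
  k <- length(stage)
  co <- list(stage = as.integer(stage), n = as.numeric(n),
             L = rep_len(L, k), E = rep_len(as.numeric(E), k),
             EH = rep_len(as.numeric(EH), k), ER = rep_len(as.numeric(ER), k),
             age = rep_len(as.numeric(age), k), dd = rep_len(as.numeric(dd), k),
             sM = rep_len(as.numeric(sM), k), Lb = rep_len(as.numeric(Lb), k),
             born = rep_len(0, k), gen = rep_len(0L, k))
  debibm:::new_population(co, t = t)
}

test_that("degree days accumulate only above the hatching threshold", {
  p <- hairtail_ibm
  egg <- make_pop(0, 1000, L = 1e-4)
  expect_equal(update_degree_days(egg, T_C = 10, dt = 5, p)$cohorts$dd, 0)
  expect_equal(update_degree_days(egg, T_C = 8, dt = 100, p)$cohorts$dd, 0)
  warm <- update_degree_days(egg, T_C = 20, dt = 5.15, p)
  expect_equal(warm$cohorts$dd, 51.5) # 51.5 / (20 - 10) = 5.15 d
})

test_that("hatching applies the success probability exactly once", {
  p <- hairtail_ibm; d <- hairtail_deb
  ready <- make_pop(0, 1000, L = 0.043, EH = d$E_Hb, dd = 51.5)
  h <- hatch(ready, p, d)
  expect_equal(h$cohorts$n, 900)
  expect_equal(h$cohorts$stage, 1L) # feeding begins: juvenile
  # idempotent: a second call changes nothing
  h2 <- hatch(h, p, d)
  expect_equal(h2$cohorts$n, 900)
  # strict threshold
  notyet <- make_pop(0, 1000, L = 0.043, EH = d$E_Hb, dd = 51.49)
  expect_equal(hatch(notyet, p, d)$cohorts$n, 1000)
  expect_equal(hatch(notyet, p, d)$cohorts$stage, 0L)
})

test_that("fish density sums post-egg wet biomass over the reference area", {
  p <- hairtail_ibm; d <- hairtail_deb
  expect_equal(fish_density(make_pop(integer(0), numeric(0), numeric(0)),
                            p, d), 0)
  # one cohort of 1e6 individuals of 140 g on 1000 km^2 -> 140 kg/km^2
  one <- make_pop(1, 1e6, L = 5, E = (140 - 125) * 8500)
  expect_equal(fish_density(one, p, d), 140)
  two <- make_pop(1, 2e6, L = 5, E = (140 - 125) * 8500)
  expect_equal(fish_density(two, p, d), 280) # linear in abundance
  # egg cohorts do not count
  eggs <- make_pop(c(1, 0), c(1e6, 1e9), L = c(5, 1e-4),
                   E = c((140 - 125) * 8500, 1.4))
  expect_equal(fish_density(eggs, p, d), 140)
})

test_that("spawning converts buffer batches into one egg cohort", {
  p <- hairtail_ibm; d <- hairtail_deb
  E_0 <- 1.381 # egg cost, J
  ER <- 100.5 * E_0 / (p$spawn_frac * d$kappa_R) # 100 eggs per female
  fem <- make_pop(2, 1e4, L = 3, E = 1e5, EH = d$E_Hp, ER = ER, t = 150)
  out <- spawn(fem, T_C = 20, p, d, E_0 = E_0)
  expect_equal(length(out$cohorts$n), 2L)
  expect_equal(out$cohorts$stage[2], 0L)
  expect_equal(out$cohorts$n[2], 100 * 1e4) # eggs per female times females
  expect_equal(out$cohorts$ER[1], ER - 100 * E_0 / d$kappa_R)
  # insufficient buffer: nothing happens
  poor <- make_pop(2, 1e4, L = 3, E = 1e5, EH = d$E_Hp,
                   ER = 0.5 * E_0 / (p$spawn_frac * d$kappa_R), t = 150)
  expect_equal(length(spawn(poor, 20, p, d, E_0)$cohorts$n), 1L)
  # outside the window or too cold: unchanged
  winter <- make_pop(2, 1e4, L = 3, E = 1e5, EH = d$E_Hp, ER = ER, t = 20)
  expect_equal(length(spawn(winter, 20, p, d, E_0)$cohorts$n), 1L)
  expect_equal(length(spawn(fem, 10, p, d, E_0)$cohorts$n), 1L)
  expect_error(spawn(fem, 20, p, d, E_0 = 0), "positive")
})

test_that("abundance is conserved without mortality and spawning", {
  d <- hairtail_deb
  ibm <- no_mortality_ibm(spawn_T_min = 99)
  fc <- constant_forcing(years = 1, temp = 20, food = 1, zf = 0, dt = 0.5)
  pop <- make_pop(1, 5e5, L = 1, E = 12000, EH = 100, sM = 1.9, Lb = 0.0428)
  for (i in 1:60) pop <- step_population(pop, fc, d, ibm, E_0 = 1.381)
  expect_equal(sum(pop$cohorts$n), 5e5, tolerance = 1e-12)
  expect_equal(pop$t, 30)
})

test_that("with only fishing on adults the decay is exactly exponential", {
  d <- hairtail_deb
  ibm <- no_mortality_ibm(spawn_T_min = 99)
  zf <- 0.002
  fc <- constant_forcing(years = 1, temp = 20, food = 1, zf = zf, dt = 0.5)
  pop <- make_pop(3, 1e6, L = 3.5, E = 3e5, EH = d$E_Hp, sM = 1.96,
                  Lb = 0.0428, age = 900)
  for (i in 1:100) pop <- step_population(pop, fc, d, ibm, E_0 = 1.381)
  expect_equal(pop$cohorts$n, 1e6 * exp(-zf * 50), tolerance = 1e-10)
})

test_that("cohort abundance never increases between spawning events", {
  d <- hairtail_deb
  fc <- synthesize_forcings(years = 1, seed = 2, dt = 0.5)
  pop <- make_pop(c(1, 2), c(1e6, 1e5), L = c(1, 3), E = c(12000, 3e5),
                  EH = c(100, d$E_Hp), ER = c(0, 50), sM = 1.9, Lb = 0.0428,
                  age = c(100, 400))
  ibm <- ibm_params(spawn_T_min = 99) # mortality on, reproduction off
  n_prev <- pop$cohorts$n
  for (i in 1:200) {
    pop <- step_population(pop, fc, d, ibm, E_0 = 1.381)
    expect_true(all(pop$cohorts$n <= n_prev + 1e-12))
    n_prev <- pop$cohorts$n
  }
})

test_that("population summaries weight ages by abundance", {
  p <- hairtail_ibm; d <- hairtail_deb
  empty <- make_pop(integer(0), numeric(0), numeric(0))
  z <- summarize_population(empty, d, p)
  expect_equal(z$total_abundance, 0)
  expect_equal(z$mean_age_y, 0)
  pop <- make_pop(c(1, 1), c(100, 300), L = 2, E = 1e5,
                  age = c(365, 730))
  s <- summarize_population(pop, d, p)
  expect_equal(s$mean_age_y, 1.75) # (100*1 + 300*2) / 400
  expect_equal(s$total_abundance, 400)
  expect_equal(s$biomass_kg_km2, fish_density(pop, p, d))
  expect_equal(s$n_juv, 400)
})

test_that("simulations are bit-reproducible for identical forcing seeds", {
  fc <- synthesize_forcings(years = 2, seed = 3, dt = 0.5)
  init <- init_population(hairtail_deb, hairtail_ibm, ages_y = c(0.6, 1.6),
                          abundance = c(2e6, 1e6))
  a <- run_simulation(fc, init = init, spinup_years = 1, record_every = 5)
  b <- run_simulation(fc, init = init, spinup_years = 1, record_every = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$spinup == (a$t_days < 365)))
})

test_that("extinction under extreme fishing warns but still writes full output", {
  fc <- synthesize_forcings(years = 2, seed = 4, dt = 0.5,
                            zf_annual = rep(0.5, 2))
  init <- init_population(hairtail_deb, hairtail_ibm, ages_y = 0.6,
                          abundance = 1e5)
  expect_warning(
    sim <- run_simulation(fc, init = init, spinup_years = 0, record_every = 5),
    "extinct")
  expect_equal(nrow(sim), length(seq(0, 730 - 1, by = 5)))
  expect_equal(sim$total_abundance[nrow(sim)], 0)
})

test_that("stepping past the forcing window names the gap", {
  fc <- constant_forcing(years = 1, dt = 0.5)
  pop <- make_pop(1, 10, L = 1, E = 1e4, t = 400)
  expect_error(step_population(pop, fc, hairtail_deb, hairtail_ibm,
                               E_0 = 1.4), "forcing gap")
})

test_that("equilibrium biomass declines along a fishing-mortality gradient", {
  zf_grid <- c(0, 0.0015, 0.003, 0.006)
  init <- init_population(hairtail_deb, hairtail_ibm)
  B <- vapply(zf_grid, function(zf) {
    fc <- constant_forcing(years = 8, temp = 20, food = 0.9, zf = zf,
                           dt = 1 / 6)
    mean_biomass(run_simulation(fc, init = init, spinup_years = 4,
                                record_every = 10))
  }, 0)
  expect_true(all(diff(B) < 0))
})

test_that("initial seeding is forgotten after spin-up (density regulation)", {
  fc <- synthesize_forcings(years = 8, seed = 1, dt = 1 / 6)
  a <- run_simulation(fc, init = init_population(hairtail_deb, hairtail_ibm),
                      spinup_years = 4, record_every = 10)
  big <- init_population(hairtail_deb, hairtail_ibm,
                         abundance = 2 * c(6e6, 3e6, 8e5, 2e5))
  b <- run_simulation(fc, init = big, spinup_years = 4, record_every = 10)
  expect_lt(abs(mean_biomass(b) - mean_biomass(a)) / mean_biomass(a), 0.2)
})

test_that("the cohort table view exposes the population state", {
  pop <- make_pop(c(0, 1, 2), c(10, 20, 30), L = c(1e-4, 1, 3))
  tab <- as_tibble(pop)
  expect_equal(tab$stage, c("egg_larva", "juvenile", "female"))
  expect_equal(tab$n, c(10, 20, 30))
})
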