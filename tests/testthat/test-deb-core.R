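test_that("Arrhenius correction equals 1 at T_ref and is suppressed at the boundaries", {
  p <- hairtail_deb
  expect_equal(arrhenius_factor(p$T_ref, p), 1)
  pure <- function(T_K) exp(p$T_A / p$T_ref - p$T_A / T_K)
  # at the tolerance boundaries the 5-parameter form lies strictly below the
  # pure Arrhenius curve
  expect_lt(arrhenius_factor(p$T_L, p), pure(p$T_L))
  expect_lt(arrhenius_factor(p$T_H, p), pure(p$T_H))
  # frozen value from an arbitrary-precision transcription of the formula
  expect_equal(arrhenius_factor(288.15, p), 0.65531673996607, tolerance = 1e-12)
  # vectorized
  expect_length(arrhenius_factor(c(280, 290, 300), p), 3L)
  expect_error(arrhenius_factor(NaN, p), "non-finite")
  expect_error(arrhenius_factor(450, p), "outside")
})

test_that("somatic maintenance and the kappa-rule balance hold in deb_rates", {
  p <- hairtail_deb
  st <- deb_state(L = 1, E = 8000, E_H = 50, s_M = 1.5, L_b = 0.0428)
  fl <- debibm:::deb_fluxes(st$L, st$E, st$E_H, st$s_M, f = 1, TC = 1, p)
  expect_equal(fl$pS, 67.46) # [p_M] * L^3 at L = 1 cm, T_ref
  r <- deb_rates(st, f = 1, T_K = p$T_ref, p)
  # kappa share: growth commitment + somatic maintenance
  expect_equal(3 * st$L^2 * p$E_G * r[["dL"]] + fl$pS, p$kappa * fl$pC,
               tolerance = 1e-12)
  # 1 - kappa share: maturity maintenance + maturation
  expect_equal(r[["dE_H"]] + fl$pJ, (1 - p$kappa) * fl$pC, tolerance = 1e-12)
  # reserve balance closes the budget
  expect_equal(r[["dE"]], fl$pA - fl$pC, tolerance = 1e-12)
})

test_that("embryos do not assimilate and starvation never yields negative reserve", {
  p <- hairtail_deb
  emb <- deb_state(L = 0.02, E = 0.5, E_H = 0.005) # below E_Hb
  r <- deb_rates(emb, f = 1, T_K = p$T_ref, p)
  expect_equal(r[["dE"]], -debibm:::deb_fluxes(emb$L, emb$E, emb$E_H, 1, 1, 1, p)$pC)
  # starving adult: kappa share cannot pay maintenance, buffer empty
  ad <- deb_state(L = 4, E = 100, E_H = p$E_Hp, E_R = 0, s_M = 1.96, L_b = 0.0428)
  r2 <- deb_rates(ad, f = 0, T_K = p$T_ref, p)
  expect_true(attr(r2, "starving"))
  expect_equal(r2[["dL"]], 0) # no shrinking
  st2 <- step_individual(ad, f = 0, T_K = p$T_ref, dt = 1 / 24, p)
  expect_gte(st2$E_R, 0)
  expect_gte(st2$E, 0)
})

test_that("Euler stepping is first-order consistent and rejects destructive steps", {
  p <- hairtail_deb
  st <- deb_state(L = 1, E = 12000, E_H = 100, s_M = 1.9, L_b = 0.0428)
  err_at <- function(dt) {
    one <- step_individual(st, 1, p$T_ref, dt, p)
    half <- step_individual(step_individual(st, 1, p$T_ref, dt / 2, p),
                            1, p$T_ref, dt / 2, p)
    abs(one$L - half$L)
  }
  e1 <- err_at(0.2); e2 <- err_at(0.1); e3 <- err_at(0.05)
  expect_lt(e2, e1); expect_lt(e3, e2)
  # one-step difference of a first-order scheme shrinks ~quadratically
  expect_equal(e1 / e2, 4, tolerance = 0.3)
  expect_equal(e2 / e3, 4, tolerance = 0.3)
  # f = 0 with no reserve: length cannot increase
  starveling <- deb_state(L = 0.5, E = 0, E_H = 1)
  expect_lte(step_individual(starveling, 0, p$T_ref, 1 / 24, p)$L,
             starveling$L + 1e-12)
  # destructive step: reserve would go negative
  tiny <- deb_state(L = 0.5, E = 10, E_H = 1)
  expect_error(step_individual(tiny, 0, p$T_ref, 1e4, p), "smaller dt")
})

test_that("a year of Euler at the hourly step tracks the adaptive oracle within 1%", {
  p <- hairtail_deb
  birth <- initial_reserve(p, f = 1)
  juv <- debibm:::integrate_juvenile(birth, p, f = 1)
  # oracle: adaptive integration of the same abj system for 365 d post birth
  rhs <- function(t, y, parms) {
    L <- y[1]; E <- y[2]; EH <- y[3]
    s_M <- min(max(1, L / birth$L_b), juv$s_M)
    pC <- E * (p$E_G * p$v_dot * s_M * L^2 + p$p_M_vol * L^3) /
      (p$kappa * E + p$E_G * L^3)
    pA <- p_Am(p) * s_M * L^2
    dL <- max(p$kappa * pC - p$p_M_vol * L^3, 0) / (3 * L^2 * p$E_G)
    dEH <- if (EH < p$E_Hp) (1 - p$kappa) * pC - p$k_J_dot * EH else 0
    list(c(dL, pA - pC, dEH))
  }
  oracle <- deSolve::lsoda(c(L = birth$L_b, E = birth$E_b, EH = p$E_Hb),
                           c(0, 365), rhs, NULL, rtol = 1e-10, atol = 1e-10)
  st <- deb_state(L = birth$L_b, E = birth$E_b, E_H = p$E_Hb,
                  s_M = 1, L_b = birth$L_b)
  for (i in 1:(365 * 24)) st <- step_individual(st, 1, p$T_ref, 1 / 24, p)
  expect_equal(st$L, unname(oracle[2, "L"]), tolerance = 0.01)
})

test_that("initial reserve: monotone in f, matches a secant shooting oracle, and L_b is right", {
  p <- hairtail_deb
  b1 <- initial_reserve(p, f = 1)
  b05 <- initial_reserve(p, f = 0.5)
  expect_gt(b1$E_0, b05$E_0)
  # physical length at birth (Table-value scale: 0.26 cm)
  expect_equal(b1$L_b / p$delta_M, 0.26, tolerance = 0.02)
  # independent oracle: secant iteration on e(birth) - f over embryo shots
  E_m0 <- p_Am(p) / p$v_dot
  g <- function(E0) {
    s <- debibm:::integrate_embryo(E0, p)
    s$E_b / (s$L_b^3 * E_m0) - 1
  }
  x0 <- 0.5; x1 <- 3
  for (i in 1:60) {
    f0 <- g(x0); f1 <- g(x1)
    x2 <- x1 - f1 * (x1 - x0) / (f1 - f0)
    x0 <- x1; x1 <- x2
    if (abs(f1) < 1e-11) break
  }
  expect_equal(b1$E_0, x1, tolerance = 1e-5)
})

test_that("lengths at the maturity thresholds are temperature-invariant, times are not", {
  p <- hairtail_deb
  bA <- initial_reserve(p, f = 1, T_K = p$T_ref)
  bB <- initial_reserve(p, f = 1, T_K = 288.15)
  expect_equal(bA$L_b, bB$L_b, tolerance = 1e-5)
  TC <- arrhenius_factor(288.15, p)
  expect_equal(bB$a_b, bA$a_b / TC, tolerance = 1e-4)
  jA <- debibm:::integrate_juvenile(bA, p, f = 1, T_K = p$T_ref)
  jB <- debibm:::integrate_juvenile(bB, p, f = 1, T_K = 288.15)
  expect_equal(jA$L_j, jB$L_j, tolerance = 1e-5)
  expect_equal(jA$L_p, jB$L_p, tolerance = 1e-5)
  expect_equal(jB$t_p, jA$t_p / TC, tolerance = 1e-3)
})

test_that("observables convert states to lengths and weights correctly", {
  p <- hairtail_deb
  ob <- observables(deb_state(L = 1, E = 0), p)
  expect_equal(ob$dry_weight, 1) # structure only, d_V = 1
  ob2 <- observables(deb_state(L = 5.78, E = 0), p)
  expect_equal(ob2$physical_length, 5.78 / 0.165, tolerance = 1e-12)
  # weights never fall below the structure-only weight
  expect_gte(observables(deb_state(L = 2, E = 500, E_R = 100), p)$dry_weight,
             p$d_V * 2^3)
})
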