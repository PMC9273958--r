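#' Five-parameter Arrhenius temperature correction
#'
#' Multiplicative correction applied to every physiological rate (assimilation,
#' energy conductance, maintenance, ageing). The correction equals 1 at the
#' reference temperature and is suppressed outside the tolerance range
#' bounded by `T_L` and `T_H`:
#' \deqn{TC(T) = e^{T_A/T_{ref} - T_A/T}\;
#'   \frac{1 + e^{T_{AL}/T_{ref} - T_{AL}/T_L} + e^{T_{AH}/T_H - T_{AH}/T_{ref}}}
#'        {1 + e^{T_{AL}/T - T_{AL}/T_L} + e^{T_{AH}/T_H - T_{AH}/T}}}
#'
#' @param T_K temperature in kelvin (vectorized).
#' @param pars a [deb_params()] object.
#' @return positive correction factor(s), 1 at `T_ref`.
#' @examples
#' arrhenius_factor(293.15, deb_params()) # 1
#' arrhenius_factor(288.15, deb_params()) # suppressed below T_ref
#' @export
arrhenius_factor <- function(T_K, pars) {
  if (any(!is.finite(T_K))) abort("non-finite temperature in forcing")
  if (any(T_K <= 0 | T_K >= 400)) abort("temperature outside (0, 400) K")
  with(pars, {
    num <- 1 + exp(T_AL / T_ref - T_AL / T_L) + exp(T_AH / T_H - T_AH / T_ref)
    den <- 1 + exp(T_AL / T_K  - T_AL / T_L) + exp(T_AH / T_H - T_AH / T_K)
    exp(T_A / T_ref - T_A / T_K) * num / den
  })
}

#' Individual DEB state
#'
#' One individual's (or one cohort's shared) physiological state.
#'
#' @param L structural length (cm).
#' @param E reserve energy (J).
#' @param E_H maturity level (J).
#' @param E_R reproduction buffer (J).
#' @param age time since fertilization (d).
#' @param s_M acceleration factor (-), 1 before birth, `L/L_b` between birth
#'   and metamorphosis, frozen at `L_j/L_b` after.
#' @param L_b structural length at birth (cm), `NA` before birth; needed to
#'   carry the acceleration factor.
#' @param q_acc ageing acceleration (1/d^2).
#' @param h_haz ageing hazard (1/d).
#' @return a `deb_state` object (named list).
#' @export
deb_state <- function(L, E, E_H = 0, E_R = 0, age = 0, s_M = 1, L_b = NA_real_,
                      q_acc = 0, h_haz = 0) {
  stopifnot(L >= 0, E >= 0, E_H >= 0, E_R >= 0, s_M >= 1)
  structure(list(L = L, E = E, E_H = E_H, E_R = E_R, age = age,
                 s_M = s_M, L_b = L_b, q_acc = q_acc, h_haz = h_haz),
            class = "deb_state")
}

#' @export
print.deb_state <- function(x, ...) {
  cat(sprintf(
    "<deb_state> L=%.4g cm  E=%.4g J  E_H=%.4g J  E_R=%.4g J  age=%.4g d  s_M=%.3f\n",
    x$L, x$E, x$E_H, x$E_R, x$age, x$s_M))
  invisible(x)
}

# Energy fluxes of the abj model (J/d), vectorized over the state vectors.
# Both {p_Am} and v_dot are accelerated by s_M between birth and
# metamorphosis; embryos (E_H < E_Hb) do not assimilate.
deb_fluxes <- function(L, E, E_H, s_M, f, TC, pars) {
  pAm <- p_Am(pars)
  v   <- pars$v_dot * s_M
  pA  <- ifelse(E_H < pars$E_Hb, 0, TC * pAm * s_M * f * L^2)
  pC  <- TC * E * (pars$E_G * v * L^2 + pars$p_M_vol * L^3) /
    (pars$kappa * E + pars$E_G * L^3)
  pS  <- TC * pars$p_M_vol * L^3
  pJ  <- TC * pars$k_J_dot * E_H
  list(pA = pA, pC = pC, pS = pS, pJ = pJ)
}

#' Instantaneous DEB rates
#'
#' Right-hand side of the abj DEB dynamics under the kappa-rule: mobilized
#' reserve `p_C` is split into a fraction `kappa` for somatic maintenance
#' plus growth and `1 - kappa` for maturity maintenance plus maturation
#' (before puberty) or reproduction (after). Somatic maintenance has
#' priority; when the `kappa` share cannot cover it the deficit is paid from
#' the reproduction buffer (no shrinking), and the rate of buffer drain is
#' reported in `dE_R`. An individual whose buffer is exhausted under such a
#' deficit is starving (see [step_individual()]).
#'
#' @param state a [deb_state()].
#' @param f scaled functional response in `[0, 1]`.
#' @param T_K temperature (K).
#' @param pars a [deb_params()] object.
#' @return named numeric vector of rates
#'   `(dL, dE, dE_H, dE_R, dq, dh)` in (cm/d, J/d, J/d, J/d, 1/d^3, 1/d^2),
#'   with attribute `starving` (logical).
#' @examples
#' pars <- deb_params()
#' st <- deb_state(L = 1, E = 5000, E_H = 10, s_M = 1.5, L_b = 0.043)
#' deb_rates(st, f = 1, T_K = 293.15, pars)
#' @export
deb_rates <- function(state, f, T_K, pars) {
  stopifnot(f >= 0, f <= 1)
  TC <- arrhenius_factor(T_K, pars)
  fl <- deb_fluxes(state$L, state$E, state$E_H, state$s_M, f, TC, pars)
  growth_num <- pars$kappa * fl$pC - fl$pS
  starving <- FALSE
  dE_R_starve <- 0
  if (growth_num < 0) {
    # somatic maintenance priority: pay deficit from the reproduction buffer
    dE_R_starve <- growth_num            # negative drain, J/d
    starving <- state$E_R <= 0
    growth_num <- 0
  }
  dL <- growth_num / (3 * state$L^2 * pars$E_G)
  dE <- fl$pA - fl$pC
  pR <- (1 - pars$kappa) * fl$pC - fl$pJ # maturation / reproduction flux
  if (state$E_H < pars$E_Hp) {
    dE_H <- pR
    dE_R <- dE_R_starve
  } else {
    dE_H <- 0
    dE_R <- pR + dE_R_starve
  }
  # Weibull/Gompertz ageing (used for the life-span trait only)
  L_m <- pars$z * state$s_M
  e_scaled <- state$E * pars$v_dot / (state$L^3 * p_Am(pars))
  r <- 3 * dL / state$L
  dq <- (state$q_acc * (state$L / L_m)^3 * pars$s_G + pars$h_a_ddot) *
    e_scaled * (TC * pars$v_dot * state$s_M / state$L - r) - r * state$q_acc
  dh <- state$q_acc - r * state$h_haz
  out <- c(dL = dL, dE = dE, dE_H = dE_H, dE_R = dE_R, dq = dq, dh = dh)
  attr(out, "starving") <- starving
  out
}

#' Advance one individual by one Euler step
#'
#' Explicit-Euler update of a [deb_state()] at step `dt` (default one hour,
#' the population scheduler's step). Stage thresholds (`E_Hb`, `E_Hj`,
#' `E_Hp`) are crossed at most once per step; the acceleration factor is
#' updated from the recorded length at birth and frozen at metamorphosis.
#'
#' @inheritParams deb_rates
#' @param dt step length (d).
#' @return the updated `deb_state`, with attribute `starving = TRUE` when the
#'   kappa share cannot pay somatic maintenance and the reproduction buffer
#'   is exhausted.
#' @export
step_individual <- function(state, f, T_K, dt, pars) {
  stopifnot(dt > 0)
  r <- deb_rates(state, f, T_K, pars)
  L  <- state$L + r[["dL"]] * dt
  E  <- state$E + r[["dE"]] * dt
  EH <- state$E_H + r[["dE_H"]] * dt
  ER <- max(0, state$E_R + r[["dE_R"]] * dt)
  if (E < 0 || L < state$L - 1e-12) {
    abort("Euler step produced a negative reserve or length; use a smaller dt")
  }
  st <- state
  st$L <- L; st$E <- E; st$E_H <- EH; st$E_R <- ER
  st$age <- state$age + dt
  st$q_acc <- state$q_acc + r[["dq"]] * dt
  st$h_haz <- state$h_haz + r[["dh"]] * dt
  if (is.na(st$L_b) && EH >= pars$E_Hb) st$L_b <- L
  if (!is.na(st$L_b) && EH < pars$E_Hj) st$s_M <- max(1, L / st$L_b)
  if (state$E_H < pars$E_Hj && EH >= pars$E_Hj) st$s_M <- max(1, L / st$L_b)
  attr(st, "starving") <- attr(r, "starving")
  st
}

# ---- adaptive reference integrations (deSolve) ------------------------------

# RHS in deSolve form for a fixed acceleration regime:
# regime "embryo": f = 0, s_M = 1; "accel": s_M = L/L_b; "post": s_M = s_M_j.
deb_ode <- function(regime, f, pars, L_b = NA, s_M_j = NA, TC = 1) {
  pAm <- p_Am(pars)
  function(t, y, parms) {
    L <- y[1]; E <- y[2]; EH <- y[3]
    s_M <- switch(regime, embryo = 1, accel = max(1, L / L_b), post = s_M_j)
    v <- pars$v_dot * s_M
    pC <- TC * E * (pars$E_G * v * L^2 + pars$p_M_vol * L^3) /
      (pars$kappa * E + pars$E_G * L^3)
    pA <- if (regime == "embryo") 0 else TC * pAm * s_M * f * L^2
    dL <- max(pars$kappa * pC - TC * pars$p_M_vol * L^3, 0) /
      (3 * L^2 * pars$E_G)
    dEH <- if (EH < pars$E_Hp) (1 - pars$kappa) * pC - TC * pars$k_J_dot * EH else 0
    list(c(dL, pA - pC, dEH))
  }
}

# integrate an embryo from a near-zero length until E_H = E_Hb (or failure)
integrate_embryo <- function(E_0, pars, TC = 1, L_0 = 1e-5, t_max = 200) {
  root <- function(t, y, parms) y[3] - pars$E_Hb
  out <- deSolve::lsodar(
    y = c(L = L_0, E = E_0, EH = 0),
    times = c(0, t_max / TC),
    func = deb_ode("embryo", 0, pars, TC = TC),
    parms = NULL, rootfunc = root,
    rtol = 1e-10, atol = c(1e-14, 1e-12, 1e-14)
  )
  n <- nrow(out)
  reached <- n > 0 && out[n, "EH"] >= pars$E_Hb - 1e-9 && out[n, "E"] > 0
  list(reached = reached, a_b = unname(out[n, 1]),
       L_b = unname(out[n, "L"]), E_b = unname(out[n, "E"]))
}

#' Initial reserve of an egg
#'
#' Solves for the egg energy content `E_0` such that the scaled reserve
#' density at birth equals the functional response `f` experienced by the
#' mother (the Add-my-Pet convention), by bisection on embryo integrations.
#' The embryo feeds on nothing, so its reserve only drains until the
#' maturity-at-birth threshold is reached.
#'
#' @param pars a [deb_params()] object.
#' @param f scaled functional response in `(0, 1]`.
#' @param T_K temperature (K) at which the embryo develops; affects the age
#'   at birth but not the length or reserve at birth.
#' @param tol relative tolerance on the reserve density at birth.
#' @return a list with `E_0` (J), `a_b` (age at birth, d), `L_b` (structural
#'   length at birth, cm) and `E_b` (reserve at birth, J).
#' @examples
#' initial_reserve(deb_params(), f = 1)$E_0
#' @export
initial_reserve <- function(pars, f = 1, T_K = pars$T_ref, tol = 1e-9) {
  stopifnot(f > 0, f <= 1)
  TC <- arrhenius_factor(T_K, pars)
  E_m0 <- p_Am(pars) / pars$v_dot # reserve capacity before acceleration
  e_at_birth <- function(E_0) {
    s <- integrate_embryo(E_0, pars, TC = TC)
    if (!s$reached) return(-1)
    s$E_b / (s$L_b^3 * E_m0)
  }
  lo <- 1e-6; hi <- 1
  while (e_at_birth(hi) < f) {
    hi <- hi * 4
    if (hi > 1e8) abort("initial_reserve: bisection bracket not found (upper)")
  }
  if (e_at_birth(lo) > f) {
    abort("initial_reserve: bisection bracket not found (lower)")
  }
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (e_at_birth(mid) < f) lo <- mid else hi <- mid
    if ((hi - lo) / hi < tol) break
  }
  E_0 <- sqrt(lo * hi)
  s <- integrate_embryo(E_0, pars, TC = TC)
  list(E_0 = E_0, a_b = s$a_b, L_b = s$L_b, E_b = s$E_b)
}

# Integrate from birth through metamorphosis to puberty at constant f and
# temperature, with adaptive stepping and root detection. Returns the
# stage landmarks used by the trait layer.
integrate_juvenile <- function(birth, pars, f = 1, T_K = pars$T_ref) {
  TC <- arrhenius_factor(T_K, pars)
  L_b <- birth$L_b
  # phase 1: acceleration, birth -> metamorphosis
  o1 <- deSolve::lsodar(
    y = c(L = L_b, E = birth$E_b, EH = pars$E_Hb),
    times = c(0, 2000 / TC),
    func = deb_ode("accel", f, pars, L_b = L_b, TC = TC), parms = NULL,
    rootfunc = function(t, y, parms) y[3] - pars$E_Hj,
    rtol = 1e-10, atol = c(1e-12, 1e-10, 1e-12)
  )
  n1 <- nrow(o1)
  if (o1[n1, "EH"] < pars$E_Hj - 1e-9) {
    abort("metamorphosis threshold E_Hj unreachable at this f")
  }
  L_j <- unname(o1[n1, "L"]); t_j <- unname(o1[n1, 1])
  s_M <- L_j / L_b
  # phase 2: metamorphosis -> puberty
  o2 <- deSolve::lsodar(
    y = c(L = L_j, E = unname(o1[n1, "E"]), EH = pars$E_Hj),
    times = c(0, 30000 / TC),
    func = deb_ode("post", f, pars, s_M_j = s_M, TC = TC), parms = NULL,
    rootfunc = function(t, y, parms) y[3] - pars$E_Hp,
    rtol = 1e-10, atol = c(1e-10, 1e-6, 1e-8)
  )
  n2 <- nrow(o2)
  if (o2[n2, "EH"] < pars$E_Hp - 1e-6) {
    abort("puberty threshold E_Hp unreachable at this f")
  }
  list(L_b = L_b, L_j = L_j, s_M = s_M, t_j = t_j,
       L_p = unname(o2[n2, "L"]), E_p = unname(o2[n2, "E"]),
       t_p = unname(t_j + o2[n2, 1]), # time since birth at puberty
       L_i = s_M * pars$z * f)
}

#' Observable quantities of a DEB state
#'
#' Converts the hidden DEB state into measurable quantities: preanal
#' (physical) length via the shape coefficient, and body weight as structure
#' plus reserve and reproduction-buffer mass,
#' `W = d_V L^3 + (E + E_R) / e_j`.
#'
#' @param state a [deb_state()] (or list with `L`, `E`, `E_R`).
#' @param pars a [deb_params()] object.
#' @return a tibble with `physical_length` (cm), `dry_weight` (g) and
#'   `wet_weight` (g, via the `dry_wet` factor).
#' @examples
#' observables(deb_state(L = 1, E = 0), deb_params())
#' @export
observables <- function(state, pars) {
  dw <- pars$d_V * state$L^3 + (state$E + state$E_R) / pars$e_j_content
  tibble(
    physical_length = state$L / pars$delta_M,
    dry_weight = dw,
    wet_weight = dw / pars$dry_wet
  )
}
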