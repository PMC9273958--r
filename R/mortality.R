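#' Mortality sources of the population model
#'
#' The five mortality rates (all in 1/d) acting on the cohorts:
#' \describe{
#'   \item{`background_mortality()`}{environment-related background
#'     mortality, inversely correlated with the Yangtze River flow and
#'     rainfall anomaly indices:
#'     `Z_B = M_cm - M_flow * flow_index - M_rain * rain_index`, clamped at
#'     zero from below (a negative mortality would resurrect fish).}
#'   \item{`density_mortality()`}{density-dependent (cannibalism-driven)
#'     mortality, a saturating function of fish density:
#'     `Z_D = M_d * B_fish / (B_fish + B_fh)`.}
#'   \item{`egg_mortality()`}{egg predation by the stock, a type-II
#'     functional response: `Z_egg = M_egg * B_fish / (B_fish + B_eggh)`.}
#'   \item{`ageing_mortality()`}{mortality proportional to age above a
#'     threshold: `Z_age = e_age * max(age - Age_min, 0)`.}
#' }
#' Fishing mortality `Z_F` is an external forcing. All are vectorized.
#'
#' @param flow_idx,rain_idx dimensionless anomaly indices (see
#'   [flow_index()]).
#' @param B_fish fish density (kg/km^2, non-negative).
#' @param age age since fertilization (d).
#' @param pars an [ibm_params()] object.
#' @return mortality rate(s), 1/d.
#' @examples
#' p <- ibm_params()
#' background_mortality(0, 0, p)  # M_cm
#' density_mortality(p$B_fh, p)   # M_d / 2
#' egg_mortality(p$B_eggh, p)     # M_egg / 2
#' ageing_mortality(1095, p)      # e_age * 365
#' @export
background_mortality <- function(flow_idx, rain_idx, pars) {
  stopifnot(all(is.finite(flow_idx)), all(is.finite(rain_idx)))
  pmax(0, pars$M_cm - pars$M_flow * flow_idx - pars$M_rain * rain_idx)
}

#' @rdname background_mortality
#' @export
density_mortality <- function(B_fish, pars) {
  stopifnot(all(B_fish >= 0))
  pars$M_d * B_fish / (B_fish + pars$B_fh)
}

#' @rdname background_mortality
#' @export
egg_mortality <- function(B_fish, pars) {
  stopifnot(all(B_fish >= 0))
  pars$M_egg * B_fish / (B_fish + pars$B_eggh)
}

#' @rdname background_mortality
#' @export
ageing_mortality <- function(age, pars) {
  stopifnot(all(age >= 0))
  pars$e_age * pmax(age - pars$Age_min, 0)
}

#' Exponential survival update
#'
#' Abundance after one step under the summed mortality rates:
#' `n * exp(-(Z_F + Z_B + Z_D + Z_age + Z_egg) * dt)`. Egg-stage cohorts
#' receive `Z_egg`; post-egg cohorts the other terms (the caller selects the
#' stage-appropriate rates, see [step_population()]).
#'
#' @param n abundance (individuals, vectorized).
#' @param Z_F,Z_B,Z_D,Z_age,Z_egg mortality rates (1/d, each >= 0).
#' @param dt step length (d).
#' @return surviving abundance.
#' @examples
#' apply_survival(1000, Z_B = 0.001, dt = 1) # 1000 * exp(-0.001)
#' @export
apply_survival <- function(n, Z_F = 0, Z_B = 0, Z_D = 0, Z_age = 0,
                           Z_egg = 0, dt) {
  Z <- Z_F + Z_B + Z_D + Z_age + Z_egg
  stopifnot(all(Z >= 0), dt > 0)
  n * exp(-Z * dt)
}
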