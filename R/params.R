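#' DEB parameter set for the hairtail
#'
#' Constructs the parameter vector of the abj dynamic energy budget model
#' (metabolic acceleration between birth and metamorphosis). Defaults are the
#' published estimates for the East China Sea hairtail stock; any subset can
#' be overridden by name.
#'
#' The derived maximum structural length is `L_m = z` cm because the zoom
#' factor is expressed relative to a reference `L_m` of 1 cm, so the
#' surface-area-specific maximum assimilation rate is
#' `{p_Am} = z * p_M_vol / kappa`.
#'
#' @param ... named overrides of the defaults, e.g. `z = 6`, `kappa = 0.95`.
#'
#' @return An object of class `deb_params`: a named list with fields
#'   \describe{
#'     \item{z}{zoom factor (-), maximum structural length in cm}
#'     \item{v_dot}{energy conductance (cm/d)}
#'     \item{kappa}{allocation fraction to soma (-)}
#'     \item{kappa_R}{fraction of reproductive energy fixed in eggs (-)}
#'     \item{p_M_vol}{volume-specific somatic maintenance (J/cm^3/d)}
#'     \item{E_G}{volume-specific cost of structure (J/cm^3)}
#'     \item{k_J_dot}{maturity maintenance rate coefficient (1/d)}
#'     \item{delta_M}{shape coefficient, structural/preanal length (-)}
#'     \item{T_A, T_L, T_H, T_AL, T_AH}{five-parameter Arrhenius correction (K)}
#'     \item{T_ref}{reference temperature (K) at which rates are reported}
#'     \item{E_Hb, E_Hj, E_Hp}{maturity thresholds at birth, metamorphosis and
#'       puberty (J)}
#'     \item{h_a_ddot}{Weibull ageing acceleration (1/d^2)}
#'     \item{s_G}{Gompertz stress coefficient (-)}
#'     \item{e_j_content}{energy content of reserve (J/g)}
#'     \item{d_V}{specific density of structure (g/cm^3)}
#'     \item{dry_wet}{dry:wet weight conversion factor (-), default 1 so model
#'       weight and survey weight are on the same basis}
#'   }
#' @examples
#' pars <- deb_params()
#' pars$z # 5.78, so L_m = 5.78 cm structural
#' @export
deb_params <- function(...) {
  defaults <- list(
    z         = 5.78,
    v_dot     = 0.0334,
    kappa     = 0.968,
    kappa_R   = 0.95,
    p_M_vol   = 67.46,
    E_G       = 5240,
    k_J_dot   = 0.002,
    delta_M   = 0.165,
    T_A       = 8500,
    T_H       = 297,
    T_L       = 278,
    T_AH      = 29000,
    T_AL      = 11000,
    T_ref     = 293.15,
    E_Hb      = 1.38e-2,
    E_Hj      = 0.105,
    E_Hp      = 5435,
    h_a_ddot  = 1.12e-8,
    s_G       = 1.84e-4,
    e_j_content = 8500,
    d_V       = 1,
    dry_wet   = 1
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    abort(paste0("unknown DEB parameter(s): ", paste(bad, collapse = ", ")))
  }
  p <- modifyList(defaults, over)
  validate_deb_params(p)
  structure(p, class = "deb_params")
}

validate_deb_params <- function(p) {
  stopifnot(
    p$kappa > 0, p$kappa <= 1,
    p$kappa_R > 0, p$kappa_R <= 1,
    p$z > 0, p$v_dot > 0, p$p_M_vol > 0, p$E_G > 0, p$k_J_dot > 0,
    p$delta_M > 0, p$e_j_content > 0, p$d_V > 0,
    p$E_Hb > 0, p$E_Hj > p$E_Hb, p$E_Hp > p$E_Hj,
    p$T_L < p$T_ref, p$T_ref < p$T_H,
    p$h_a_ddot >= 0, p$s_G >= 0
  )
  invisible(p)
}

#' Surface-area-specific maximum assimilation rate
#'
#' `{p_Am} = z * p_M_vol / kappa` (J/cm^2/d), from the definition of the zoom
#' factor relative to a 1-cm reference maximum length.
#'
#' @param pars a [deb_params()] object.
#' @return assimilation rate in J/cm^2/d.
#' @export
p_Am <- function(pars) pars$z * pars$p_M_vol / pars$kappa

#' @export
print.deb_params <- function(x, ...) {
  cat("<deb_params> abj DEB parameter set\n")
  flat <- unlist(x)
  cat(paste0("  ", format(names(flat), width = 12), " ",
             format(flat, digits = 6)), sep = "\n")
  invisible(x)
}

#' IBM (population-level) parameter set
#'
#' Parameters of the cohort-based population module: degree-day hatching,
#' the mortality sources, spawning and the reference-area scaling. Defaults
#' are the published values for the East China Sea hairtail plus documented
#' scheduling choices (spawning window, selectivity) that the source
#' literature leaves open.
#'
#' @param ... named overrides of the defaults.
#'
#' @return An object of class `ibm_params` with fields
#'   \describe{
#'     \item{T_min}{minimum temperature for hatching (degC)}
#'     \item{R_h}{hatching success probability (-)}
#'     \item{DD_min}{degree-day threshold for hatching (degC d)}
#'     \item{M_egg}{maximum daily egg predation rate (1/d)}
#'     \item{B_eggh}{half-saturation fish density for egg mortality (kg/km^2)}
#'     \item{M_d}{maximum density-dependent mortality (1/d)}
#'     \item{B_fh}{half-saturation fish density for density mortality (kg/km^2)}
#'     \item{M_cm}{climate-related background mortality coefficient (1/d)}
#'     \item{M_flow}{river-flow mortality coefficient (1/d per flow index)}
#'     \item{M_rain}{rainfall mortality coefficient (1/d per rain index)}
#'     \item{e_age}{effect of age on mortality (1/d^2)}
#'     \item{Age_min}{age threshold for ageing mortality (d)}
#'     \item{area}{reference area over which the population is scaled (km^2)}
#'     \item{spawn_window}{day-of-year window (start, end) in which spawning
#'       can occur}
#'     \item{spawn_T_min}{minimum temperature for spawning (degC)}
#'     \item{spawn_interval}{days between spawning events inside the window;
#'       all eggs of one event form one cohort}
#'     \item{fish_sel_length}{minimum preanal length (cm) recruited to the
#'       fishery; the bottom-trawl catch includes late juveniles}
#'     \item{B_food}{half-scale of food competition (kg/km^2): the food
#'       index is shared by the stock, so per-capita food is divided by
#'       `1 + B_fish/B_food`}
#'     \item{Z_starve}{starvation hazard (1/d) applied while a cohort cannot
#'       pay somatic maintenance from the kappa share or its reproduction
#'       buffer}
#'     \item{spawn_frac}{fraction of the reproduction buffer a female can
#'       convert to eggs per spawning event (batch spawning)}
#'     \item{cohort_floor}{abundance below which a cohort is dropped}
#'     \item{ind_weight_g}{average individual weight (g) used to convert
#'       survey abundance to biomass}
#'   }
#' @examples
#' ibm_params(area = 500)$area
#' @export
ibm_params <- function(...) {
  defaults <- list(
    T_min    = 10,
    R_h      = 0.90,
    DD_min   = 51.5,
    M_egg    = 0.083,
    B_eggh   = 2.0e3,
    M_d      = 0.007,
    B_fh     = 2.2e3,
    M_cm     = 9.73e-4,
    M_flow   = 4.03e-4,
    M_rain   = 6.03e-5,
    e_age    = 2.0e-6,
    Age_min  = 730,
    area     = 1000,
    spawn_window = c(105, 288),
    spawn_T_min  = 14,
    spawn_interval = 5,
    fish_sel_length = 10,
    B_food   = 2.0e3,
    Z_starve = 0.02,
    spawn_frac = 0.1,
    cohort_floor = 1e-3,
    ind_weight_g = 140
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    abort(paste0("unknown IBM parameter(s): ", paste(bad, collapse = ", ")))
  }
  p <- modifyList(defaults, over)
  stopifnot(
    p$R_h >= 0, p$R_h <= 1, p$area > 0, p$DD_min > 0,
    p$M_egg >= 0, p$M_d >= 0, p$M_cm >= 0, p$M_flow >= 0, p$M_rain >= 0,
    p$e_age >= 0, p$Age_min >= 0, p$B_eggh > 0, p$B_fh > 0,
    length(p$spawn_window) == 2L, p$spawn_interval > 0, p$cohort_floor >= 0
  )
  structure(p, class = "ibm_params")
}

#' @export
print.ibm_params <- function(x, ...) {
  cat("<ibm_params> population (IBM) parameter set\n")
  flat <- unlist(x)
  cat(paste0("  ", format(names(flat), width = 16), " ",
             format(flat, digits = 6)), sep = "\n")
  invisible(x)
}

#' Read or write parameter files
#'
#' Parameter files are flat key/value YAML with the field names used by
#' [deb_params()] and [ibm_params()]. The packaged default
#' (`system.file("extdata", "hairtail_params.yaml", package = "debibm")`)
#' reproduces the published hairtail parameter set exactly.
#'
#' @param path file path.
#' @return `read_deb_params()` a [deb_params()] object; `read_ibm_params()`
#'   an [ibm_params()] object.
#' @examples
#' path <- system.file("extdata", "hairtail_params.yaml", package = "debibm")
#' pars <- read_deb_params(path)
#' @export
read_deb_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$deb)) raw <- raw$deb
  keep <- intersect(names(raw), names(deb_params()))
  miss <- setdiff(names(deb_params()), names(raw))
  if (length(keep) == 0L) {
    abort(paste0("no DEB parameter keys found in ", path,
                 "; missing e.g. ", paste(head(miss, 5), collapse = ", ")))
  }
  deb_params(raw[keep])
}

#' @rdname read_deb_params
#' @export
read_ibm_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$ibm)) raw <- raw$ibm
  keep <- intersect(names(raw), names(ibm_params()))
  if (length(keep) == 0L) {
    abort(paste0("no IBM parameter keys found in ", path))
  }
  ibm_params(raw[keep])
}

#' @rdname read_deb_params
#' @param deb,ibm parameter objects to serialize.
#' @export
write_params <- function(path, deb = deb_params(), ibm = ibm_params()) {
  yaml::write_yaml(list(deb = unclass(deb), ibm = unclass(ibm)), path)
  invisible(path)
}
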