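#' Yangtze River flow and rainfall anomaly indices
#'
#' Dimensionless anomaly indices entering the background-mortality relation:
#' the difference between the annual value and the long-term mean, divided
#' by a fixed correction factor (`1e12` m^3 for flow, 1 m for rain).
#'
#' @param flow_i,flow_mean annual and long-term mean river flow (m^3/y).
#' @param rain_i,rain_mean annual and long-term mean precipitation (m/y).
#' @return dimensionless index, zero at the long-term mean, sign-preserving.
#' @examples
#' flow_index(1.05e12, 0.95e12) # 0.1
#' rain_index(1.35, 1.10)       # 0.25
#' @export
flow_index <- function(flow_i, flow_mean) {
  (flow_i - flow_mean) / 1e12
}

#' @rdname flow_index
#' @export
rain_index <- function(rain_i, rain_mean) {
  (rain_i - rain_mean) / 1
}

#' Expand an annual series to the step grid
#'
#' @param values one value per simulation year (year 1 first).
#' @param grid step timestamps in days from the start (365-day calendar).
#' @param mode `"step"` for piecewise-constant within each year, `"linear"`
#'   to interpolate between year midpoints (constant beyond the first/last
#'   midpoint).
#' @return one value per grid point.
#' @examples
#' expand_annual(c(0.002, 0.004), grid = 365, mode = "linear") # 0.003
#' @export
expand_annual <- function(values, grid, mode = c("step", "linear")) {
  mode <- match.arg(mode)
  yr <- floor(grid / 365) + 1L
  if (any(yr < 1L | yr > length(values))) {
    abort(sprintf("annual series (%d years) does not cover the grid (needs year %d)",
                  length(values), max(yr)))
  }
  if (mode == "step") {
    values[yr]
  } else {
    mid <- (seq_along(values) - 0.5) * 365
    approx(mid, values, xout = grid, rule = 2)$y
  }
}

#' Map food index to the scaled functional response
#'
#' `f = food / (food + K_food)`, a type-II saturating response. The default
#' half-saturation is chosen so that the long-term mean of the default
#' synthetic food index maps to `f` of roughly 0.8.
#'
#' @param food_index non-negative food index.
#' @param K_food half-saturation constant (same units as the index).
#' @return `f` in `[0, 1)`.
#' @export
functional_response <- function(food_index, K_food = 0.22) {
  stopifnot(K_food > 0)
  food_index / (food_index + K_food)
}

default_zf_schedule <- function(years) {
  # stylized exploitation history: moderate effort, a ramp to a peak around
  # year 20, then a decline to an intermediate level (management controls)
  yrs <- seq_len(years)
  zf <- numeric(years)
  zf[yrs <= 5] <- 0.0012
  ramp <- yrs > 5 & yrs <= 20
  zf[ramp] <- 0.0012 + (0.0035 - 0.0012) * (yrs[ramp] - 5) / 15
  fall <- yrs > 20 & yrs <= 28
  zf[fall] <- 0.0035 - (0.0035 - 0.0022) * (yrs[fall] - 20) / 8
  zf[yrs > 28] <- 0.0022
  zf
}

default_food_profile <- function() {
  # monthly (Jan..Dec) relative prey availability: autumn peak, winter trough
  c(0.50, 0.45, 0.55, 0.70, 0.85, 0.95, 1.00, 1.05, 1.20, 1.30, 1.15, 0.70)
}

#' Synthesize environmental and fishing forcings
#'
#' Generates a seeded, reproducible forcing series emulating the qualitative
#' features of the East China Sea record: a sinusoidal seasonal temperature
#' cycle with an interannual warming trend and AR(1) monthly anomalies; an
#' autumn-peaked, winter-trough food index with mild interannual variation;
#' annual river-flow and rainfall values drawn around long-term means; and a
#' piecewise annual fishing-mortality schedule. The calendar has 365-day
#' years and 12 equal months.
#'
#' @param years number of simulated years (> 0).
#' @param seed integer seed; the same seed always yields the same series.
#' @param dt step length in days (default 1/24, i.e. hourly).
#' @param temp_mean long-term mean temperature (degC).
#' @param temp_amplitude seasonal semi-amplitude (degC, > 0).
#' @param temp_peak_doy day-of-year of the seasonal maximum.
#' @param warming_slope linear warming trend (degC per year).
#' @param anomaly_sd,anomaly_phi innovation SD (degC) and lag-1
#'   autocorrelation of the monthly temperature anomalies.
#' @param food_profile 12 monthly food-index values (Jan..Dec).
#' @param food_year_sd lognormal SD of the annual food-level multiplier.
#' @param flow_mean,flow_sd annual Yangtze flow mean and SD (m^3/y).
#' @param rain_mean,rain_sd annual precipitation mean and SD (m/y).
#' @param zf_annual fishing mortality per year (1/d); default a stylized
#'   piecewise exploitation history.
#' @param zf_mode `"step"` or `"linear"` expansion of the annual fishing
#'   mortality within years.
#' @param K_food half-saturation of the food-to-functional-response map.
#' @return a `debibm_forcing` object: list with tibbles `steps`
#'   (`t_days`, `temperature_C`, `food_index`, `Z_F`) and `annual`
#'   (`year`, `flow_m3`, `rain_m`, `flow_index`, `rain_index`, `Z_F`), plus
#'   `dt`, `years`, `K_food`, `seed` and the scenario `label`.
#' @examples
#' fc <- synthesize_forcings(years = 2, seed = 1, dt = 0.5)
#' head(fc$steps)
#' @export
synthesize_forcings <- function(years, seed, dt = 1 / 24,
                                temp_mean = 19.5, temp_amplitude = 6.5,
                                temp_peak_doy = 225, warming_slope = 0.02,
                                anomaly_sd = 0.5, anomaly_phi = 0.6,
                                food_profile = default_food_profile(),
                                food_year_sd = 0.10,
                                flow_mean = 9.2e11, flow_sd = 8e10,
                                rain_mean = 1.10, rain_sd = 0.15,
                                zf_annual = NULL,
                                zf_mode = c("step", "linear"),
                                K_food = 0.22) {
  if (years <= 0) abort("years must be positive")
  if (temp_amplitude <= 0) abort("temp_amplitude must be positive")
  stopifnot(length(food_profile) == 12L, all(food_profile >= 0), dt > 0)
  zf_mode <- match.arg(zf_mode)
  years <- as.integer(years)
  set.seed(as.integer(seed))

  t <- seq(0, years * 365 - dt, by = dt)
  doy <- t %% 365
  month <- pmin(floor(doy / (365 / 12)) + 1L, 12L)
  gmonth <- floor(t / (365 / 12)) + 1L # global month index

  n_m <- years * 12L
  anom <- numeric(n_m)
  innov <- rnorm(n_m, 0, anomaly_sd)
  for (m in seq_len(n_m)) {
    anom[m] <- if (m == 1L) innov[1] else anomaly_phi * anom[m - 1L] + innov[m]
  }
  temperature <- temp_mean +
    temp_amplitude * cos(2 * pi * (doy - temp_peak_doy) / 365) +
    warming_slope * t / 365 +
    anom[gmonth]

  food_year <- exp(rnorm(years, 0, food_year_sd))
  food <- food_profile[month] * food_year[floor(t / 365) + 1L]

  flow <- rnorm(years, flow_mean, flow_sd)
  rain <- rnorm(years, rain_mean, rain_sd)
  zf <- zf_annual %||% default_zf_schedule(years)
  if (length(zf) == 1L) zf <- rep(zf, years)
  stopifnot(length(zf) == years, all(zf >= 0))

  annual <- tibble(
    year = seq_len(years),
    flow_m3 = flow, rain_m = rain,
    flow_index = flow_index(flow, flow_mean),
    rain_index = rain_index(rain, rain_mean),
    Z_F = zf
  )
  steps <- tibble(
    t_days = t,
    temperature_C = temperature,
    food_index = food,
    Z_F = expand_annual(zf, t, mode = zf_mode)
  )
  structure(list(steps = steps, annual = annual, dt = dt, years = years,
                 K_food = K_food, seed = as.integer(seed), label = "baseline"),
            class = "debibm_forcing")
}

#' @export
print.debibm_forcing <- function(x, ...) {
  cat(sprintf(
    "<debibm_forcing> %d year(s) at dt = %.4g d (%d steps), scenario '%s'\n",
    x$years, x$dt, nrow(x$steps), x$label))
  cat(sprintf("  temperature %.1f-%.1f degC, food %.2f-%.2f, annual Z_F %.2g-%.2g 1/d\n",
              min(x$steps$temperature_C), max(x$steps$temperature_C),
              min(x$steps$food_index), max(x$steps$food_index),
              min(x$annual$Z_F), max(x$annual$Z_F)))
  invisible(x)
}

#' Climate / fishing scenario
#'
#' A scenario is a uniform temperature offset plus a uniform fishing
#' multiplier; [apply_scenario()] changes only those fields of a forcing
#' series and leaves everything else bit-identical.
#'
#' @param temperature_offset additive offset (degC).
#' @param fishing_multiplier multiplier on fishing mortality (>= 0).
#' @param label scenario name.
#' @return a `debibm_scenario` object.
#' @examples
#' scenario_presets() # the five standard scenarios
#' @export
scenario <- function(temperature_offset = 0, fishing_multiplier = 1,
                     label = "scenario") {
  stopifnot(fishing_multiplier >= 0)
  structure(list(temperature_offset = temperature_offset,
                 fishing_multiplier = fishing_multiplier, label = label),
            class = "debibm_scenario")
}

#' @rdname scenario
#' @details The presets encode the SSP warming offsets projected for 2100
#'   (+1.4, +2.7 and +4.4 degC for SSP1-1.9, SSP2-4.5 and SSP5-8.5) and
#'   +/-10% fishing effort.
#' @export
scenario_presets <- function() {
  list(
    `SSP1-1.9` = scenario(1.4, 1, "SSP1-1.9"),
    `SSP2-4.5` = scenario(2.7, 1, "SSP2-4.5"),
    `SSP5-8.5` = scenario(4.4, 1, "SSP5-8.5"),
    `ZF+10%`   = scenario(0, 1.1, "ZF+10%"),
    `ZF-10%`   = scenario(0, 0.9, "ZF-10%")
  )
}

#' @rdname scenario
#' @param forcings a `debibm_forcing` object.
#' @param scn a `debibm_scenario`.
#' @export
apply_scenario <- function(forcings, scn) {
  stopifnot(inherits(forcings, "debibm_forcing"),
            inherits(scn, "debibm_scenario"))
  out <- forcings
  out$steps$temperature_C <- out$steps$temperature_C + scn$temperature_offset
  out$steps$Z_F <- out$steps$Z_F * scn$fishing_multiplier
  out$annual$Z_F <- out$annual$Z_F * scn$fishing_multiplier
  out$label <- scn$label
  out
}

#' Read or write forcing files
#'
#' Two CSVs: a step file with columns `t_days`, `temperature_C`,
#' `food_index` (and optionally `Z_F`), and an annual file with columns
#' `year`, `flow_m3`, `rain_m`, `Z_F` (fishing mortality in 1/d).
#'
#' @param steps_path,annual_path file paths.
#' @param K_food half-saturation for the food-to-f mapping.
#' @param zf_mode expansion mode for annual fishing mortality.
#' @return a `debibm_forcing` object.
#' @export
read_forcings <- function(steps_path, annual_path, K_food = 0.22,
                          zf_mode = c("step", "linear")) {
  zf_mode <- match.arg(zf_mode)
  steps <- readr::read_csv(steps_path, show_col_types = FALSE)
  annual <- readr::read_csv(annual_path, show_col_types = FALSE)
  stopifnot(all(c("t_days", "temperature_C", "food_index") %in% names(steps)),
            all(c("year", "flow_m3", "rain_m", "Z_F") %in% names(annual)))
  if (!all(is.finite(steps$temperature_C))) abort("non-finite temperature")
  if (any(steps$food_index < 0)) abort("negative food index")
  if (any(annual$Z_F < 0)) abort("negative fishing mortality")
  dt <- diff(steps$t_days[1:2])
  years <- nrow(annual)
  if (max(steps$t_days) >= years * 365) {
    abort("annual series does not cover the step grid")
  }
  annual$flow_index <- flow_index(annual$flow_m3, mean(annual$flow_m3))
  annual$rain_index <- rain_index(annual$rain_m, mean(annual$rain_m))
  if (!"Z_F" %in% names(steps)) {
    steps$Z_F <- expand_annual(annual$Z_F, steps$t_days, mode = zf_mode)
  }
  structure(list(steps = steps, annual = annual, dt = dt, years = years,
                 K_food = K_food, seed = NA_integer_, label = "file"),
            class = "debibm_forcing")
}

#' @rdname read_forcings
#' @param forcings object to write.
#' @export
write_forcings <- function(forcings, steps_path, annual_path) {
  readr::write_csv(forcings$steps, steps_path)
  readr::write_csv(select(forcings$annual, "year", "flow_m3", "rain_m", "Z_F"),
                   annual_path)
  invisible(c(steps_path, annual_path))
}
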