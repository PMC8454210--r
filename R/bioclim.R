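#' Atmospheric pressure from elevation
#'
#' Standard barometric formula with an isothermal lapse-rate atmosphere:
#' sea-level pressure 101.325 kPa, lapse rate 0.0065 K m^-1, reference
#' temperature 288.15 K. Monotone decreasing in elevation.
#'
#' @param elevation Elevation above sea level (m); vectorised.
#' @return Air pressure (kPa).
#' @examples
#' air_pressure(c(0, 1143, 4361))
#' @export
air_pressure <- function(elevation) {
  if (any(elevation < -500, na.rm = TRUE)) {
    abort("`elevation` must be >= -500 m.")
  }
  g <- 9.80665   # m s^-2
  m_air <- 0.0289644  # kg mol^-1
  rg <- 8.3145
  lapse <- 0.0065
  t0 <- 288.15
  101.325 * (1 - lapse * elevation / t0)^(g * m_air / (rg * lapse))
}

#' Ambient CO2 partial pressure at site pressure
#'
#' @param patm Air pressure (kPa).
#' @param co2_ppm CO2 dry-air mole fraction (ppm).
#' @return CO2 partial pressure (Pa).
#' @export
co2_partial_pressure <- function(patm, co2_ppm = 400) {
  co2_ppm * 1e-6 * patm * 1000
}

#' Mean daytime temperature from the diurnal cycle
#'
#' Approximates the daily temperature cycle with a sine curve between the
#' daily maximum and minimum and integrates over the daylight period, which
#' is set by the sunrise/sunset geometry `x = -tan(latitude) *
#' tan(declination)`. The daytime mean is a weighted combination
#' `Tmax * (1/2 + w) + Tmin * (1/2 - w)` with
#' `w = sqrt(1 - x^2) / (2 * acos(x))`.
#'
#' @param tmax,tmin Mean daily maximum / minimum air temperature (degrees C).
#' @param latitude Site latitude (degrees).
#' @param solar_declination Mean solar declination for the period
#'   (degrees); about 21.2 for July.
#' @return Daytime mean temperature (degrees C), between `tmin` and `tmax`.
#' @examples
#' daytime_temperature(18, 8, latitude = 29.6, solar_declination = 21.2)
#' @export
daytime_temperature <- function(tmax, tmin, latitude, solar_declination) {
  if (any(tmax < tmin)) {
    abort("`tmax` must be >= `tmin`.")
  }
  x <- -tanpi(latitude / 180) * tanpi(solar_declination / 180)
  if (any(abs(x) >= 1)) {
    abort(paste0(
      "Polar day or night: |tan(latitude) * tan(declination)| >= 1, ",
      "the daytime mean is undefined."
    ))
  }
  w <- sqrt(1 - x^2) / (2 * acos(x))
  tmax * (0.5 + w) + tmin * (0.5 - w)
}

#' Growing-season bioclimate from a daily series
#'
#' Aggregates a daily weather series to the growing-season means the trait
#' models need. The growing season is the set of days with temperature above
#' `tbase` (0 degrees C by default); `f` is its length as a fraction of the
#' series length.
#'
#' @param daily A data frame with one row per day and columns `temp`
#'   (degrees C), and optionally `vpd` (kPa) and `par`
#'   (micromol photon m^-2 s^-1).
#' @param tbase Growing-season temperature baseline (degrees C).
#' @return A one-row tibble with `tg`, `d0`, `r0` (NA when the input column
#'   is absent), `f` and `n_days`.
#' @examples
#' growing_season_stats(data.frame(temp = c(-5, 5, 10), vpd = 1, par = 500))
#' @export
growing_season_stats <- function(daily, tbase = 0) {
  daily <- as_tibble(daily)
  if (!"temp" %in% names(daily)) abort("`daily` must have a `temp` column.")
  if (!all(is.finite(daily$temp))) abort("`daily$temp` must be finite.")
  grow <- daily$temp > tbase
  if (!any(grow)) {
    abort("Degenerate site: no day with temperature above the baseline.")
  }
  mean_or_na <- function(col) {
    if (col %in% names(daily)) mean(daily[[col]][grow]) else NA_real_
  }
  tibble(
    tg = mean(daily$temp[grow]),
    d0 = mean_or_na("vpd"),
    r0 = mean_or_na("par"),
    f = sum(grow) / nrow(daily),
    n_days = nrow(daily)
  )
}

#' Canopy-averaged daily photon dose
#'
#' Converts the growing-season mean PAR flux to a daily photon dose using a
#' fixed daylight period, then averages over the canopy with a Beer-Lambert
#' extinction profile: the mean light absorbed per unit leaf area in a
#' canopy of leaf area index `LAI` is `(1 - exp(-k * LAI)) / (k * LAI)`
#' times the top-of-canopy dose, which tends to 1 as `LAI -> 0`.
#'
#' @param r0 Growing-season mean PAR (micromol photon m^-2 s^-1).
#' @param lai Leaf area index (m^2 m^-2).
#' @param extinction_k Canopy light-extinction coefficient (> 0).
#' @param daylight_hours Day length used for the flux-to-dose conversion (h).
#' @return LAI-weighted PAR, `R_LAI` (mol photon m^-2 day^-1).
#' @examples
#' canopy_light(800, lai = 3)
#' @export
canopy_light <- function(r0, lai, extinction_k = 0.5, daylight_hours = 12) {
  if (any(lai < 0)) abort("`lai` must be >= 0.")
  if (extinction_k <= 0) abort("`extinction_k` must be > 0.")
  r_daily <- r0 * 1e-6 * daylight_hours * 3600
  x <- extinction_k * lai
  atten <- ifelse(x < 1e-10, 1, (1 - exp(-x)) / x)
  r_daily * atten
}

## Arrhenius scaling factor relative to 25 degrees C
arrhenius <- function(dha, temp, rgas = 8.3145) {
  tk <- temp + 273.15
  exp(dha * (tk - 298.15) / (298.15 * rgas * tk))
}

## dynamic viscosity of water (Pa s), Vogel empirical equation
water_viscosity <- function(temp, constants = leaf_constants()) {
  constants$visc_a * 10^(constants$visc_b / (temp + 273.15 - constants$visc_c))
}

#' Temperature- and pressure-dependent Rubisco kinetics
#'
#' Computes the photorespiratory compensation point, the effective
#' Michaelis-Menten coefficient of Rubisco and the relative viscosity of
#' water at a given temperature and air pressure. Kc and Ko follow
#' Arrhenius scaling from their 25 degree C reference values; the
#' compensation point additionally scales linearly with pressure, as does
#' the O2 partial pressure entering `K = Kc * (1 + Po / Ko)`.
#'
#' @param temp Air temperature (degrees C); values outside -10..45 trigger
#'   an extrapolation warning.
#' @param patm Air pressure (kPa).
#' @param constants A [leaf_constants()] list.
#' @return A tibble with columns `gamma_star` (Pa), `kc` (Pa), `ko` (Pa),
#'   `po` (Pa), `kmm` (Pa) and `eta_rel` (unitless, 1 at 25 degrees C).
#' @examples
#' rubisco_kinetics(25, 101.325)
#' @export
rubisco_kinetics <- function(temp, patm, constants = leaf_constants()) {
  cst <- as_constants(constants)
  if (any(patm <= 0)) abort("`patm` must be > 0.")
  if (any(temp < -10 | temp > 45)) {
    warn("`temp` outside -10..45 degrees C: Rubisco kinetics extrapolated.")
  }
  kc <- cst$kc25 * arrhenius(cst$ha_kc, temp, cst$rgas)
  ko <- cst$ko25 * arrhenius(cst$ha_ko, temp, cst$rgas)
  po <- cst$o2_frac * patm * 1000
  gamma_star <- cst$gammastar25 * (patm / 101.325) *
    arrhenius(cst$ha_gammastar, temp, cst$rgas)
  tibble(
    gamma_star = gamma_star,
    kc = kc,
    ko = ko,
    po = po,
    kmm = kc * (1 + po / ko),
    eta_rel = water_viscosity(temp, cst) / water_viscosity(25, cst)
  )
}

#' Add derived pressure-dependent drivers to a site table
#'
#' Completes a site table with air pressure, ambient CO2 partial pressure
#' and (when `lai` is present and `r_lai` is not) the LAI-weighted daily
#' photon dose. Existing columns are never overwritten.
#'
#' @param sites A data frame with at least `elevation_m`; optionally `r0`
#'   and `lai`.
#' @param constants A [leaf_constants()] list.
#' @return The input as a tibble with `patm` (kPa), `ca` (Pa) and possibly
#'   `r_lai` (mol m^-2 day^-1) added.
#' @export
derive_bioclim <- function(sites, constants = leaf_constants()) {
  cst <- as_constants(constants)
  sites <- as_tibble(sites)
  if (!"elevation_m" %in% names(sites)) {
    abort("`sites` must have an `elevation_m` column.")
  }
  if (!"patm" %in% names(sites)) {
    sites$patm <- air_pressure(sites$elevation_m)
  }
  if (!"ca" %in% names(sites)) {
    sites$ca <- co2_partial_pressure(sites$patm, cst$co2_ppm)
  }
  if (!"r_lai" %in% names(sites) && all(c("r0", "lai") %in% names(sites))) {
    sites$r_lai <- canopy_light(sites$r0, sites$lai,
                                extinction_k = cst$extinction_k,
                                daylight_hours = cst$daylight_hours)
  }
  sites
}
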