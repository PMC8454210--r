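#' Physiological and physical constants for the optimality trait models
#'
#' Returns the full set of fixed parameters used by the trait models,
#' bioclimate derivations and calibration routines, with literature default
#' values. Any constant can be overridden by name, so a configuration file
#' can be spliced in with `do.call(leaf_constants, config$constants)`.
#'
#' The defaults are:
#' \describe{
#'   \item{beta}{Ratio at 25 degrees C of the unit costs of maintaining
#'     carboxylation vs. transpiration capacity (146, unitless).}
#'   \item{c_cost}{Unit carbon cost for maintenance of electron-transport
#'     capacity (0.41, unitless).}
#'   \item{phi0}{Intrinsic quantum efficiency of photosynthesis
#'     (0.085 mol C mol^-1 photon).}
#'   \item{kc25, ko25}{Michaelis-Menten coefficients of Rubisco for
#'     carboxylation / oxygenation at 25 degrees C (39.97 Pa, 27480 Pa).}
#'   \item{ha_kc, ha_ko}{Activation energies for the Arrhenius temperature
#'     scaling of Kc and Ko (79430, 36380 J mol^-1).}
#'   \item{gammastar25, ha_gammastar}{Photorespiratory CO2 compensation
#'     point at 25 degrees C and sea-level pressure (4.332 Pa) and its
#'     activation energy (37830 J mol^-1).}
#'   \item{ha_v, hd_v}{Activation / deactivation energy of the peaked
#'     Arrhenius response of Vcmax (71513, 200000 J mol^-1).}
#'   \item{ds_slope, ds_intercept}{Linear acclimation of the entropy term
#'     to growth temperature in degrees C: dS = ds_intercept -
#'     ds_slope * Tg (1.07 J mol^-1 K^-2, 668.39 J mol^-1 K^-1).}
#'   \item{u}{Dimensionless proportionality between potential leaf lifespan
#'     and Ma/Vcmax25 (8889).}
#'   \item{k_scale}{Mass-to-carbon scaling factor (30 g biomass mol^-1 C).}
#'   \item{cc}{Leaf construction cost per unit leaf carbon
#'     (1.5 gC gC^-1); enters only the uncalibrated theoretical LMA model.}
#'   \item{a_s, b_prime, f_prime}{Carbon-isotope fractionations from
#'     diffusion in air, Rubisco carboxylation and photorespiration
#'     (4.4, 30, 16 permil).}
#'   \item{d13c_air}{delta 13C of atmospheric CO2 (-8 permil).}
#'   \item{lma_coeffs}{Calibrated deciduous-LMA regression coefficients on
#'     (ln R_LAI, ln f, Tg, ln alpha_p, intercept):
#'     1.22, 0.78, -0.06, -0.60, 1.70.}
#'   \item{narea_coeffs}{Direct Narea regression coefficients on
#'     (Ma, Vcmax25): 0.02 g m^-2 per g m^-2,
#'     0.003 g m^-2 per micromol m^-2 s^-1.}
#'   \item{nstruct_coef, nstruct_exp}{Structural-nitrogen allometry
#'     N_structure = nstruct_coef * Ma^nstruct_exp (10^-2.67, 0.99).}
#'   \item{nrub_slope}{N in Rubisco per unit Vcmax25
#'     (0.003135 g m^-2 per micromol m^-2 s^-1).}
#'   \item{rubisco_alloc, rubisco_alloc_original}{Allocation multiplier of
#'     Rubisco nitrogen in the two-step Narea model: locally refitted value
#'     7.2 and original literature value 9.5.}
#'   \item{extinction_k}{Canopy light-extinction coefficient for the
#'     Beer-Lambert LAI averaging of PAR (0.5, unitless).}
#'   \item{daylight_hours}{Day length used to convert mean daytime PAR flux
#'     to a daily photon dose (12 h).}
#'   \item{co2_ppm}{Ambient CO2 dry-air mole fraction (400 ppm).}
#'   \item{o2_frac}{O2 dry-air mole fraction (0.2095).}
#'   \item{tbase}{Growing-season temperature baseline (0 degrees C).}
#'   \item{visc_a, visc_b, visc_c}{Vogel-equation coefficients for the
#'     dynamic viscosity of water,
#'     eta(T) = visc_a * 10^(visc_b / (T_K - visc_c)) Pa s.}
#'   \item{rgas}{Universal gas constant (8.3145 J mol^-1 K^-1).}
#' }
#'
#' @param ... Named overrides of any default listed above.
#'
#' @return A named list of constants with class `"leaf_constants"`.
#' @examples
#' cst <- leaf_constants(beta = 120)
#' cst$beta
#' @export
leaf_constants <- function(...) {
  defaults <- list(
    beta = 146,
    c_cost = 0.41,
    phi0 = 0.085,
    kc25 = 39.97,
    ko25 = 27.48e3,
    ha_kc = 79430,
    ha_ko = 36380,
    gammastar25 = 4.332,
    ha_gammastar = 37830,
    ha_v = 71513,
    hd_v = 200000,
    ds_slope = 1.07,
    ds_intercept = 668.39,
    u = 8889,
    k_scale = 30,
    cc = 1.5,
    a_s = 4.4,
    b_prime = 30,
    f_prime = 16,
    d13c_air = -8.0,
    lma_coeffs = c(ln_r_lai = 1.22, ln_f = 0.78, tg = -0.06,
                   ln_alpha_p = -0.60, intercept = 1.70),
    narea_coeffs = c(ma = 0.02, vcmax25 = 0.003),
    nstruct_coef = 10^-2.67,
    nstruct_exp = 0.99,
    nrub_slope = 0.003135,
    rubisco_alloc = 7.2,
    rubisco_alloc_original = 9.5,
    extinction_k = 0.5,
    daylight_hours = 12,
    co2_ppm = 400,
    o2_frac = 0.2095,
    tbase = 0,
    visc_a = 2.414e-5,
    visc_b = 247.8,
    visc_c = 140,
    rgas = 8.3145
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      abort(paste0("Unknown constant(s): ", paste(bad, collapse = ", ")))
    }
    defaults <- modifyList(defaults, overrides)
  }
  structure(defaults, class = "leaf_constants")
}

#' @export
print.leaf_constants <- function(x, ...) {
  cat("<leaf_constants> ", length(x), " parameters\n", sep = "")
  scalars <- x[vapply(x, function(v) length(v) == 1L, logical(1))]
  cat(paste0("  ", format(names(scalars)), " = ",
             vapply(scalars, format, character(1))), sep = "\n")
  invisible(x)
}

as_constants <- function(constants) {
  if (is.null(constants)) return(leaf_constants())
  if (inherits(constants, "leaf_constants")) return(constants)
  do.call(leaf_constants, as.list(constants))
}
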