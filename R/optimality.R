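#' Optimal ratio of leaf-internal to ambient CO2 (least-cost model)
#'
#' The least-cost hypothesis states that leaves minimise the combined unit
#' costs of maintaining transpiration and carboxylation capacity. At the
#' optimum,
#' `chi = Gamma*/ca + xi * (1 - Gamma*/ca) / (xi + sqrt(D))`, with
#' `xi = sqrt(beta * (K + Gamma*) / (1.6 * eta))` where `K` is the
#' effective Michaelis-Menten coefficient of Rubisco, `Gamma*` the
#' photorespiratory compensation point, `eta` the viscosity of water
#' relative to 25 degrees C and `D` the vapour pressure deficit in Pa
#' (the `d0` argument is in kPa, following the bioclimate convention,
#' and is converted internally).
#'
#' @param temp Air temperature (degrees C).
#' @param d0 Vapour pressure deficit (kPa, > 0).
#' @param patm Air pressure (kPa).
#' @param ca Ambient CO2 partial pressure (Pa); must exceed `Gamma*`.
#' @param constants A [leaf_constants()] list.
#' @return chi (Pa Pa^-1), strictly between `Gamma*/ca` and 1 and strictly
#'   decreasing in `d0`.
#' @examples
#' chi_optimal(25, d0 = 1, patm = 101.325, ca = 40)
#' @export
chi_optimal <- function(temp, d0, patm, ca, constants = leaf_constants()) {
  cst <- as_constants(constants)
  if (any(d0 <= 0)) abort("`d0` must be > 0 kPa.")
  kin <- rubisco_kinetics(temp, patm, cst)
  if (any(ca <= kin$gamma_star)) {
    abort(paste0(
      "Physically inconsistent site: `ca` must exceed the ",
      "photorespiratory compensation point Gamma*."
    ))
  }
  xi <- sqrt(cst$beta * (kin$kmm + kin$gamma_star) / (1.6 * kin$eta_rel))
  gc <- kin$gamma_star / ca
  gc + xi * (1 - gc) / (xi + sqrt(d0 * 1000))
}

#' chi from leaf carbon-isotope composition
#'
#' Converts a leaf delta 13C value to chi via the simplified discrimination
#' model including stomatal diffusion, carboxylation and photorespiration:
#' `Delta = (d13c_air - d13c_leaf) / (1 + d13c_leaf / 1000)` and
#' `chi = (Delta + f' * Gamma*/ca - a_s) / (b' - a_s)`.
#' Values outside the plausible interval (0, 1.2) are returned as-is with
#' `flag = TRUE`, so that any filtering is an explicit downstream step.
#'
#' @param d13c_leaf Leaf delta 13C (permil).
#' @param temp Air temperature (degrees C), for `Gamma*`.
#' @param patm Air pressure (kPa).
#' @param ca Ambient CO2 partial pressure (Pa).
#' @param d13c_air delta 13C of atmospheric CO2 (permil).
#' @param constants A [leaf_constants()] list.
#' @return A tibble with columns `chi`, `delta` (the discrimination,
#'   permil) and `flag` (TRUE when chi falls outside (0, 1.2)).
#' @examples
#' chi_from_isotope(-28, temp = 25, patm = 101.325, ca = 40.53)
#' @export
chi_from_isotope <- function(d13c_leaf, temp, patm, ca,
                             d13c_air = NULL,
                             constants = leaf_constants()) {
  cst <- as_constants(constants)
  d13c_air <- d13c_air %||% cst$d13c_air
  stopifnot(cst$b_prime > cst$a_s)
  kin <- rubisco_kinetics(temp, patm, cst)
  delta <- (d13c_air - d13c_leaf) / (1 + d13c_leaf / 1000)
  chi <- (delta + cst$f_prime * kin$gamma_star / ca - cst$a_s) /
    (cst$b_prime - cst$a_s)
  tibble(chi = chi, delta = delta, flag = chi <= 0 | chi >= 1.2)
}

## inverse of chi_from_isotope: leaf d13C implied by a chi value
isotope_from_chi <- function(chi, temp, patm, ca, d13c_air = NULL,
                             constants = leaf_constants()) {
  cst <- as_constants(constants)
  d13c_air <- d13c_air %||% cst$d13c_air
  kin <- rubisco_kinetics(temp, patm, cst)
  delta <- cst$a_s + (cst$b_prime - cst$a_s) * chi -
    cst$f_prime * kin$gamma_star / ca
  (d13c_air - delta) / (1 + delta / 1000)
}

#' Carboxylation capacity at growth temperature (coordination model)
#'
#' Under the coordination hypothesis the Rubisco-limited and light-limited
#' photosynthesis rates are equal under average daytime conditions, so
#' `Vcmax = phi0 * R0 * (ci + K) / (ci + 2 Gamma*) *
#' sqrt(1 - (c/m)^(2/3))` with `m = (ci - Gamma*) / (ci + 2 Gamma*)`.
#' Vcmax is proportional to absorbed light.
#'
#' @param temp Air temperature (degrees C).
#' @param r0 Mean absorbed PAR (micromol photon m^-2 s^-1).
#' @param chi Ratio of leaf-internal to ambient CO2 partial pressure.
#' @param ca Ambient CO2 partial pressure (Pa).
#' @param patm Air pressure (kPa).
#' @param constants A [leaf_constants()] list.
#' @return Vcmax at growth temperature (micromol C m^-2 s^-1).
#' @examples
#' vcmax_coordination(25, r0 = 800, chi = 0.8, ca = 40, patm = 101.325)
#' @export
vcmax_coordination <- function(temp, r0, chi, ca, patm,
                               constants = leaf_constants()) {
  cst <- as_constants(constants)
  kin <- rubisco_kinetics(temp, patm, cst)
  ci <- chi * ca
  if (any(ci <= kin$gamma_star)) {
    abort("`ci` = chi * ca must exceed the compensation point Gamma*.")
  }
  m <- (ci - kin$gamma_star) / (ci + 2 * kin$gamma_star)
  if (any(m <= cst$c_cost)) {
    abort(paste0(
      "Light-limited rate too low: m = (ci - Gamma*)/(ci + 2 Gamma*) must ",
      "exceed the electron-transport cost constant c (", cst$c_cost, ")."
    ))
  }
  cst$phi0 * r0 * (ci + kin$kmm) / (ci + 2 * kin$gamma_star) *
    sqrt(1 - (cst$c_cost / m)^(2 / 3))
}

#' Instantaneous temperature-response factor of Vcmax
#'
#' Peaked Arrhenius response of Rubisco activity relative to 25 degrees C:
#' `Vcmax = Vcmax25 * fv(T)`. The entropy term acclimates linearly to
#' growth temperature, `dS = ds_intercept - ds_slope * Tg` with Tg in
#' degrees C, while the exponentials use absolute temperature. By
#' construction `fv(25) = 1` exactly.
#'
#' @param tg Growth temperature (degrees C), in -10..45.
#' @param constants A [leaf_constants()] list.
#' @return fv (unitless).
#' @examples
#' fv_instantaneous(c(10, 25, 30))
#' @export
fv_instantaneous <- function(tg, constants = leaf_constants()) {
  cst <- as_constants(constants)
  if (any(tg < -10 | tg > 45)) {
    warn("`tg` outside -10..45 degrees C: temperature response extrapolated.")
  }
  tk <- tg + 273.15
  tref <- 298.15
  rgas <- cst$rgas
  ds <- cst$ds_intercept - cst$ds_slope * tg
  exp(cst$ha_v * (tk - tref) / (tref * rgas * tk)) *
    (1 + exp((tref * ds - cst$hd_v) / (tref * rgas))) /
    (1 + exp((tk * ds - cst$hd_v) / (tk * rgas)))
}

#' Carboxylation capacity standardised to 25 degrees C
#'
#' Combines the coordination prediction of Vcmax at growth temperature with
#' the instantaneous temperature response: `Vcmax25 = Vcmax / fv(T)`.
#'
#' @inheritParams vcmax_coordination
#' @return Vcmax25 (micromol C m^-2 s^-1).
#' @examples
#' vcmax25_predicted(15, r0 = 600, chi = 0.8, ca = 38, patm = 80)
#' @export
vcmax25_predicted <- function(temp, r0, chi, ca, patm,
                              constants = leaf_constants()) {
  cst <- as_constants(constants)
  vcmax_coordination(temp, r0, chi, ca, patm, cst) /
    fv_instantaneous(temp, cst)
}

#' Theoretical leaf mass per area from optimal leaf economics
#'
#' Combines the optimal LMA-longevity trade-off, the proportionality of
#' potential leaf lifespan to Ma/Vcmax25 and the coordination prediction of
#' Vcmax into a closed-form LMA:
#' `Ma = phi0 * I_abs * LL * k * sqrt((ci - Gamma*)(ci + K) /
#' (2 u CC fv * (ci + 2 Gamma*)^2))`.
#' Ma is proportional to absorbed light and to leaf longevity. This
#' uncalibrated form is used for elasticity and sensitivity work; site
#' prediction uses the calibrated [lma_deciduous()].
#'
#' @param i_abs Daily absorbed PAR (mol photon m^-2 day^-1).
#' @param ll Leaf longevity (days).
#' @param temp Air temperature (degrees C).
#' @param ca Ambient CO2 partial pressure (Pa).
#' @param chi Ratio of leaf-internal to ambient CO2 partial pressure.
#' @param patm Air pressure (kPa).
#' @param cc Construction cost per unit leaf carbon (gC gC^-1); defaults
#'   to the value in `constants`.
#' @param constants A [leaf_constants()] list.
#' @return Ma (g biomass m^-2).
#' @examples
#' lma_theoretical(20, ll = 180, temp = 25, ca = 40, chi = 0.75,
#'                 patm = 101.325)
#' @export
lma_theoretical <- function(i_abs, ll, temp, ca, chi, patm, cc = NULL,
                            constants = leaf_constants()) {
  cst <- as_constants(constants)
  cc <- cc %||% cst$cc
  if (any(ll <= 0)) abort("`ll` must be > 0.")
  if (cc <= 0) abort("`cc` must be > 0.")
  kin <- rubisco_kinetics(temp, patm, cst)
  ci <- chi * ca
  if (any(ci <= kin$gamma_star)) {
    abort("`ci` = chi * ca must exceed the compensation point Gamma*.")
  }
  fv <- fv_instantaneous(temp, cst)
  cst$phi0 * i_abs * ll * cst$k_scale *
    sqrt((ci - kin$gamma_star) * (ci + kin$kmm) /
           ((2 * cst$u * cc * fv) * (ci + 2 * kin$gamma_star)^2))
}

#' Calibrated leaf mass per area for deciduous species
#'
#' The linearised, empirically calibrated deciduous-LMA model:
#' `ln(Ma) = 1.22 ln(R_LAI) + 0.78 ln(f) - 0.06 Tg - 0.60 ln(alpha_p)
#' + 1.70`, with coefficients estimated on an independent continental
#' trait data set. Growing-season length stands in for the leaf longevity
#' of deciduous species.
#'
#' @param r_lai LAI-weighted daily PAR (mol photon m^-2 day^-1, > 0).
#' @param f Growing-season fraction of the year (0 < f <= 1).
#' @param tg Growing-season mean temperature (degrees C).
#' @param alpha_p Moisture index, AET/PET (> 0).
#' @param coeffs Named coefficient vector as in
#'   `leaf_constants()$lma_coeffs`.
#' @return Ma (g biomass m^-2).
#' @examples
#' lma_deciduous(20, f = 0.6, tg = 12, alpha_p = 0.8)
#' @export
lma_deciduous <- function(r_lai, f, tg, alpha_p,
                          coeffs = leaf_constants()$lma_coeffs) {
  if (any(r_lai <= 0) || any(f <= 0) || any(alpha_p <= 0)) {
    abort("`r_lai`, `f` and `alpha_p` must be > 0 (log-transformed model).")
  }
  exp(coeffs[["ln_r_lai"]] * log(r_lai) + coeffs[["ln_f"]] * log(f) +
        coeffs[["tg"]] * tg + coeffs[["ln_alpha_p"]] * log(alpha_p) +
        coeffs[["intercept"]])
}

#' Leaf nitrogen per area: direct linear model
#'
#' Narea as a zero-intercept linear combination of Ma and Vcmax25,
#' `Narea = 0.02 Ma + 0.003 Vcmax25`, with an optional additive offset for
#' nitrogen-fixing species.
#'
#' @param ma Leaf mass per area (g m^-2).
#' @param vcmax25 Carboxylation capacity at 25 degrees C
#'   (micromol C m^-2 s^-1).
#' @param n_fixer Logical; is the species a nitrogen fixer?
#' @param n_fixer_offset Additive Narea offset for nitrogen fixers
#'   (g m^-2), typically estimated by [fit_narea_coefficients()].
#' @param coeffs Named coefficient vector `c(ma = , vcmax25 = )`.
#' @return Narea (g m^-2).
#' @examples
#' narea_simple(100, 50)
#' @export
narea_simple <- function(ma, vcmax25, n_fixer = FALSE, n_fixer_offset = 0,
                         coeffs = leaf_constants()$narea_coeffs) {
  if (any(ma < 0) || any(vcmax25 < 0)) {
    abort("`ma` and `vcmax25` must be >= 0.")
  }
  coeffs[["ma"]] * ma + coeffs[["vcmax25"]] * vcmax25 +
    ifelse(n_fixer, n_fixer_offset, 0)
}

#' Leaf nitrogen per area: two-step structural + metabolic model
#'
#' Narea as the sum of structural nitrogen, allometrically related to Ma
#' (`N_structure = 10^-2.67 * Ma^0.99`), and metabolic nitrogen,
#' proportional to the nitrogen bound in Rubisco
#' (`N_rubisco = 0.003135 * Vcmax25`) scaled by an allocation multiplier:
#' `Narea = alloc * N_rubisco + N_structure`.
#'
#' @inheritParams narea_simple
#' @param alloc Allocation multiplier of Rubisco nitrogen; the locally
#'   refitted value 7.2 by default, 9.5 in the original formulation.
#' @param constants A [leaf_constants()] list.
#' @return Narea (g m^-2).
#' @examples
#' narea_two_step(80, 60)
#' @export
narea_two_step <- function(ma, vcmax25, alloc = NULL,
                           constants = leaf_constants()) {
  cst <- as_constants(constants)
  alloc <- alloc %||% cst$rubisco_alloc
  if (any(ma < 0) || any(vcmax25 < 0)) {
    abort("`ma` and `vcmax25` must be >= 0.")
  }
  alloc * cst$nrub_slope * vcmax25 + cst$nstruct_coef * ma^cst$nstruct_exp
}

#' Predict all four leaf traits for a site table
#'
#' Runs the full optimality pipeline for every site: chi from the
#' least-cost model, Vcmax25 from the coordination model, deciduous Ma from
#' the calibrated light/temperature/season/moisture model and Narea from
#' predicted Ma and Vcmax25. chi and Vcmax25 are driven by July daytime
#' temperature and Ma by growing-season temperature by default (the
#' acclimation timescales differ between traits); both are selectable.
#'
#' @param sites A data frame with columns `site_id`, `elevation_m`, `tg`,
#'   `tdj`, `d0` (kPa), `r0` (micromol m^-2 s^-1), `r_lai`
#'   (mol m^-2 day^-1; derived from `r0` and `lai` when absent), `f` and
#'   `alpha_p`. `patm` and `ca` are derived from elevation when absent.
#' @param constants A [leaf_constants()] list.
#' @param temperature_basis Named character vector choosing `"tdj"` or
#'   `"tg"` per trait, for `chi`, `vcmax25` and `ma`.
#' @return A tibble with one row per site: `site_id`, `chi`, `vcmax25`
#'   (micromol C m^-2 s^-1), `ma` (g m^-2), `narea` (g m^-2).
#' @examples
#' sites <- generate_sites(transect_scenario(seed = 1))
#' predict_traits(sites)
#' @export
predict_traits <- function(sites, constants = leaf_constants(),
                           temperature_basis = c(chi = "tdj",
                                                 vcmax25 = "tdj",
                                                 ma = "tg")) {
  cst <- as_constants(constants)
  basis <- temperature_basis
  stopifnot(all(basis %in% c("tg", "tdj")))
  sites <- derive_bioclim(sites, cst)
  needed <- c("site_id", "tg", "tdj", "d0", "r0", "r_lai", "f", "alpha_p")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols)) {
    abort(paste0("`sites` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  t_chi <- sites[[basis[["chi"]]]]
  t_v <- sites[[basis[["vcmax25"]]]]
  chi <- chi_optimal(t_chi, sites$d0, sites$patm, sites$ca, cst)
  vcmax25 <- vcmax25_predicted(t_v, sites$r0, chi, sites$ca, sites$patm, cst)
  ma <- lma_deciduous(sites$r_lai, sites$f, sites[[basis[["ma"]]]],
                      sites$alpha_p, cst$lma_coeffs)
  tibble(
    site_id = sites$site_id,
    chi = chi,
    vcmax25 = vcmax25,
    ma = ma,
    narea = narea_simple(ma, vcmax25, coeffs = cst$narea_coeffs)
  )
}
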