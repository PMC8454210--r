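#' Scenario for a synthetic mountain transect
#'
#' Defines the statistical structure of a synthetic elevation transect in
#' the style of a deep subtropical mountain gradient: 18 sites from 1143 to
#' 4361 m, temperature declining monotonically with elevation, a
#' hump-shaped moisture profile (the lowest and uppermost sites drier than
#' mid-elevations), vapour pressure deficit following temperature and
#' relative humidity, growing season shortening with elevation, radiation
#' increasing and canopy leaf area decreasing with elevation, and
#' species-level lognormal trait noise around the model predictions.
#'
#' @param n_sites Number of sites (>= 2).
#' @param elevation_range Range of site elevations (m).
#' @param latitude Site latitude (degrees).
#' @param lapse Temperature lapse rate (K km^-1).
#' @param tdj_low Mean July daytime temperature at the lowest site
#'   (degrees C).
#' @param tg_offset Tg is `tdj - tg_offset` (growing-season mean runs
#'   cooler than July daytime, degrees C).
#' @param alpha_range Moisture index at the transect edges and the hump
#'   maximum, `c(edge, peak)`.
#' @param rh_base Baseline relative humidity used to derive `d0` from
#'   saturation vapour pressure (fraction); the hump in moisture adds up to
#'   0.1 at mid-elevations.
#' @param r0_range Growing-season mean PAR at the lowest / highest site
#'   (micromol m^-2 s^-1).
#' @param lai_range Leaf area index at the lowest / highest site.
#' @param f_range Growing-season fraction at the lowest / highest site.
#' @param species_per_site Species sampled per site.
#' @param deciduous_frac Fraction of species that are deciduous.
#' @param n_fixer_frac Fraction of species that fix nitrogen.
#' @param n_fixer_offset Additive Narea offset for nitrogen fixers
#'   (g m^-2).
#' @param sd_ln_ma,sd_ln_vcmax25,sd_ln_narea Species-level lognormal
#'   (log-scale) residual sd of Ma, Vcmax25, Narea.
#' @param sd_chi Species-level additive residual sd of chi.
#' @param seed Integer seed; mandatory, every generated artefact is
#'   deterministic given the scenario.
#' @return A list of class `"transect_scenario"`.
#' @examples
#' transect_scenario(seed = 42)
#' @export
transect_scenario <- function(n_sites = 18,
                              elevation_range = c(1143, 4361),
                              latitude = 29.6,
                              lapse = 5.5,
                              tdj_low = 22,
                              tg_offset = 3,
                              alpha_range = c(0.55, 0.95),
                              rh_base = 0.55,
                              r0_range = c(500, 800),
                              lai_range = c(4.5, 1.2),
                              f_range = c(0.75, 0.35),
                              species_per_site = 15,
                              deciduous_frac = 0.8,
                              n_fixer_frac = 0.1,
                              n_fixer_offset = 0.3,
                              sd_ln_ma = 0.2,
                              sd_ln_vcmax25 = 0.2,
                              sd_ln_narea = 0.1,
                              sd_chi = 0.04,
                              seed) {
  if (missing(seed)) abort("`seed` is required.")
  if (n_sites < 2) abort("`n_sites` must be >= 2.")
  sds <- c(sd_ln_ma, sd_ln_vcmax25, sd_ln_narea, sd_chi)
  if (any(sds < 0)) abort("Residual sds must be >= 0.")
  structure(as.list(environment()), class = "transect_scenario")
}

#' @export
print.transect_scenario <- function(x, ...) {
  cat("<transect_scenario> ", x$n_sites, " sites, ",
      x$elevation_range[1], "-", x$elevation_range[2], " m, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

## saturation vapour pressure (kPa), Magnus form
svp <- function(temp) 0.6108 * exp(17.27 * temp / (temp + 237.3))

#' Generate the site environments of a synthetic transect
#'
#' Deterministic given the scenario: temperatures decline linearly with
#' elevation at the lapse rate, the moisture index follows a parabolic hump
#' peaking at mid-elevation, vapour pressure deficit is derived from the
#' saturation vapour pressure at the daytime temperature and a humidity
#' profile that tracks the moisture hump, and growing-season fraction,
#' radiation and leaf area interpolate linearly along the gradient.
#' Pressure, ambient CO2 and the LAI-weighted photon dose are derived with
#' the bioclimate routines.
#'
#' @param scenario A [transect_scenario()].
#' @param constants A [leaf_constants()] list.
#' @return A site tibble as accepted by [predict_traits()].
#' @examples
#' generate_sites(transect_scenario(seed = 1))
#' @export
generate_sites <- function(scenario, constants = leaf_constants()) {
  stopifnot(inherits(scenario, "transect_scenario"))
  cst <- as_constants(constants)
  s <- scenario
  elev <- seq(s$elevation_range[1], s$elevation_range[2],
              length.out = s$n_sites)
  rel <- (elev - elev[1]) / diff(range(elev))      # 0 at bottom, 1 at top
  hump <- 1 - (2 * rel - 1)^2                      # 0 at edges, 1 mid
  tdj <- s$tdj_low - s$lapse * (elev - elev[1]) / 1000
  tg <- tdj - s$tg_offset
  alpha_p <- s$alpha_range[1] + (s$alpha_range[2] - s$alpha_range[1]) * hump
  rh <- pmin(s$rh_base + 0.1 * hump, 0.95)
  d0 <- pmax(svp(tdj) * (1 - rh), 0.05)
  sites <- tibble(
    site_id = sprintf("site_%02d", seq_len(s$n_sites)),
    elevation_m = elev,
    latitude_deg = s$latitude,
    tg = tg,
    tdj = tdj,
    d0 = d0,
    r0 = s$r0_range[1] + (s$r0_range[2] - s$r0_range[1]) * rel,
    lai = s$lai_range[1] + (s$lai_range[2] - s$lai_range[1]) * rel,
    f = s$f_range[1] + (s$f_range[2] - s$f_range[1]) * rel,
    alpha_p = alpha_p
  )
  derive_bioclim(sites, cst)
}

#' Generate a species-level trait table around the model predictions
#'
#' Species-level traits are the site-level optimality predictions with
#' independent lognormal noise (additive normal noise for chi), so that a
#' noise-free scenario reproduces the model exactly and calibration
#' routines can be validated by parameter recovery. Nitrogen-fixing
#' species receive an additive Narea offset. Leaf delta 13C is
#' back-computed from each species' generated chi by inverting the
#' discrimination model, making the isotope pathway testable end to end.
#'
#' @param sites A site table from [generate_sites()].
#' @param scenario The same [transect_scenario()] used for the sites.
#' @param constants A [leaf_constants()] list.
#' @param temperature_basis As in [predict_traits()].
#' @return A species-level tibble with columns `site_id`, `species`,
#'   `growth_form`, `leaf_habit`, `n_fixer`, `ma`, `narea`, `vcmax25`,
#'   `vcmax`, `chi`, `d13c`, plus the site drivers (`r_lai`, `f`, `tg`,
#'   `alpha_p`) repeated per record for direct use in calibration.
#' @examples
#' sc <- transect_scenario(seed = 7)
#' traits <- generate_traits(generate_sites(sc), sc)
#' @export
generate_traits <- function(sites, scenario,
                            constants = leaf_constants(),
                            temperature_basis = c(chi = "tdj",
                                                  vcmax25 = "tdj",
                                                  ma = "tg")) {
  stopifnot(inherits(scenario, "transect_scenario"))
  cst <- as_constants(constants)
  s <- scenario
  sites <- derive_bioclim(sites, cst)
  pred <- predict_traits(sites, cst, temperature_basis)

  withr::with_seed(s$seed, {
    rows <- purrr::map(seq_len(nrow(sites)), function(i) {
      site <- sites[i, ]
      p <- pred[i, ]
      n <- s$species_per_site
      forms <- sample(c("tree", "shrub", "forb"), n, replace = TRUE,
                      prob = c(0.4, 0.35, 0.25))
      habit <- ifelse(runif(n) < s$deciduous_frac, "deciduous",
                      "evergreen")
      n_fixer <- runif(n) < s$n_fixer_frac
      chi_sp <- pmin(pmax(p$chi + rnorm(n, 0, s$sd_chi), 0.05), 1.15)
      vcmax25_sp <- p$vcmax25 * exp(rnorm(n, 0, s$sd_ln_vcmax25))
      ma_sp <- p$ma * exp(rnorm(n, 0, s$sd_ln_ma))
      narea_sp <- narea_simple(ma_sp, vcmax25_sp, n_fixer,
                               n_fixer_offset = s$n_fixer_offset,
                               coeffs = cst$narea_coeffs) *
        exp(rnorm(n, 0, s$sd_ln_narea))
      t_basis <- site[[temperature_basis[["chi"]]]]
      tibble(
        site_id = site$site_id,
        species = sprintf("%s_sp%02d", site$site_id, seq_len(n)),
        growth_form = forms,
        leaf_habit = habit,
        n_fixer = n_fixer,
        ma = ma_sp,
        narea = narea_sp,
        vcmax25 = vcmax25_sp,
        vcmax = vcmax25_sp * fv_instantaneous(t_basis, cst),
        chi = chi_sp,
        d13c = isotope_from_chi(chi_sp, t_basis, site$patm, site$ca,
                                constants = cst),
        r_lai = site$r_lai,
        f = site$f,
        tg = site$tg,
        alpha_p = site$alpha_p
      )
    })
    dplyr::bind_rows(rows)
  })
}
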