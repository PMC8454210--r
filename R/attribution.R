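## driver sets used for both the contribution decomposition and the
## statistical benchmark regressions; names are site-table columns except
## "pressure" (patm + its dependants) and "chi" (the chi input to Vcmax25)
trait_drivers <- function(trait) {
  switch(trait,
    chi = c(pressure = "pressure", temperature = "tdj", d0 = "d0"),
    vcmax25 = c(pressure = "pressure", temperature = "tdj", r0 = "r0",
                chi = "chi"),
    ma = c(temperature = "tg", r_lai = "r_lai", f = "f",
           alpha_p = "alpha_p"),
    abort(paste0("No driver set defined for trait `", trait, "`."))
  )
}

#' Average-site baseline for the contribution decomposition
#'
#' Builds the baseline "average site" by taking the arithmetic mean of
#' every environmental driver across sites. Pressure-derived quantities
#' (air pressure, ambient CO2, and through them the Rubisco kinetics) are
#' recomputed from the mean elevation rather than averaged, so the baseline
#' is internally consistent. Because the barometric formula is convex, the
#' pressure at the mean elevation differs slightly from the mean of the
#' site pressures.
#'
#' @param sites A site table as accepted by [predict_traits()]
#'   (>= 2 rows).
#' @param constants A [leaf_constants()] list.
#' @return A one-row tibble with `site_id = "baseline"` and the averaged
#'   drivers plus recomputed `patm` and `ca`.
#' @export
average_site <- function(sites, constants = leaf_constants()) {
  cst <- as_constants(constants)
  sites <- as_tibble(sites)
  if (nrow(sites) < 2) abort("`sites` must contain at least 2 sites.")
  driver_cols <- intersect(
    c("elevation_m", "latitude_deg", "tg", "tdj", "d0", "r0", "lai",
      "r_lai", "f", "alpha_p"),
    names(sites)
  )
  out <- dplyr::summarise(sites,
                          dplyr::across(dplyr::all_of(driver_cols), mean))
  out$site_id <- "baseline"
  ## derived fields recomputed from averaged drivers, never averaged
  out$patm <- NULL
  out$ca <- NULL
  derive_bioclim(out, cst)
}

## evaluate one trait model on a single-row site environment, optionally
## with the chi input pinned (used when "chi" is itself a driver)
eval_trait <- function(site, trait, cst, basis, chi_input = NULL) {
  site <- derive_bioclim(site, cst)
  switch(trait,
    chi = chi_optimal(site[[basis[["chi"]]]], site$d0, site$patm,
                      site$ca, cst),
    vcmax25 = {
      chi <- chi_input %||%
        chi_optimal(site[[basis[["chi"]]]], site$d0, site$patm,
                    site$ca, cst)
      vcmax25_predicted(site[[basis[["vcmax25"]]]], site$r0, chi,
                        site$ca, site$patm, cst)
    },
    ma = lma_deciduous(site$r_lai, site$f, site[[basis[["ma"]]]],
                       site$alpha_p, cst$lma_coeffs),
    abort(paste0("Unknown trait `", trait, "`."))
  )
}

## replace one driver of the baseline with the site's value
perturb_site <- function(baseline, site, driver_col) {
  out <- baseline
  if (driver_col == "pressure") {
    ## pressure moves with elevation; patm, ca and the kinetics follow
    out$elevation_m <- site$elevation_m
    out$patm <- NULL
    out$ca <- NULL
  } else {
    out[[driver_col]] <- site[[driver_col]]
  }
  out
}

#' Attribute between-site trait differences to individual drivers
#'
#' Three-step one-at-a-time decomposition: (1) predict each trait at the
#' average-site baseline; (2) change one driver at a time from its baseline
#' value to the site's actual value and re-predict; (3) report the
#' difference from the baseline as that driver's contribution. The driver
#' sets are pressure/elevation, July daytime temperature and vapour
#' pressure deficit for chi; pressure/elevation, temperature, radiation and
#' chi itself for Vcmax25; and growing-season temperature, canopy light,
#' season length and moisture for Ma. For models that are not additive in
#' the (transformed) drivers the contributions do not sum exactly to the
#' total site-minus-baseline difference; the difference is reported in the
#' `interaction` column rather than folded into any driver.
#'
#' @param sites A site table as accepted by [predict_traits()].
#' @param traits Traits to decompose (subset of `"chi"`, `"vcmax25"`,
#'   `"ma"`).
#' @param constants A [leaf_constants()] list.
#' @param temperature_basis As in [predict_traits()].
#' @param baseline Optional pre-computed baseline row (from
#'   [average_site()]); computed from `sites` when `NULL`.
#' @return A tibble of class `"contribution_table"` in long format:
#'   `site_id`, `trait`, `driver`, `baseline` (trait value at the average
#'   site), `perturbed` (trait value with that one driver moved to the
#'   site), `delta = perturbed - baseline`, `total_delta` (full site minus
#'   baseline) and `interaction = total_delta - sum(delta)` (repeated on
#'   each driver row of a site-trait block).
#' @examples
#' sites <- generate_sites(transect_scenario(seed = 1))
#' decompose_contributions(sites, traits = "chi")
#' @export
decompose_contributions <- function(sites,
                                    traits = c("chi", "vcmax25", "ma"),
                                    constants = leaf_constants(),
                                    temperature_basis = c(chi = "tdj",
                                                          vcmax25 = "tdj",
                                                          ma = "tg"),
                                    baseline = NULL) {
  cst <- as_constants(constants)
  sites <- derive_bioclim(sites, cst)
  baseline <- baseline %||% average_site(sites, cst)
  traits <- match.arg(traits, several.ok = TRUE)

  rows <- purrr::map(traits, function(trait) {
    drivers <- trait_drivers(trait)
    base_val <- eval_trait(baseline, trait, cst, temperature_basis)
    purrr::map(seq_len(nrow(sites)), function(i) {
      site <- sites[i, ]
      total <- eval_trait(site, trait, cst, temperature_basis)
      per_driver <- purrr::imap_dbl(drivers, function(col, name) {
        if (name == "chi") {
          ## the chi input itself moves to the site's predicted chi
          site_chi <- eval_trait(site, "chi", cst, temperature_basis)
          eval_trait(baseline, trait, cst, temperature_basis,
                     chi_input = site_chi)
        } else {
          eval_trait(perturb_site(baseline, site, col), trait, cst,
                     temperature_basis)
        }
      })
      tibble(
        site_id = site$site_id,
        trait = trait,
        driver = names(drivers),
        baseline = base_val,
        perturbed = unname(per_driver),
        delta = unname(per_driver) - base_val,
        total_delta = total - base_val,
        interaction = (total - base_val) - sum(per_driver - base_val)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("contribution_table", class(out))
  out
}

#' Bar-chart of driver contributions per site
#'
#' One panel per trait; bars show each driver's contribution to the
#' predicted trait difference between the site and the average-site
#' baseline, with the interaction residual drawn as a separate bar so it is
#' never hidden inside a driver.
#'
#' @param object A `"contribution_table"` from
#'   [decompose_contributions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.contribution_table <- function(object, ...) {
  resid <- dplyr::distinct(object, .data$site_id, .data$trait,
                           .data$interaction)
  resid <- dplyr::mutate(resid, driver = "interaction",
                         delta = .data$interaction)
  bars <- dplyr::bind_rows(
    dplyr::select(object, "site_id", "trait", "driver", "delta"),
    dplyr::select(resid, "site_id", "trait", "driver", "delta")
  )
  ggplot2::ggplot(bars, ggplot2::aes(x = .data$site_id, y = .data$delta,
                                     fill = .data$driver)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~trait, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "site", y = "contribution (trait units)",
                  fill = "driver") +
    ggplot2::theme_minimal()
}
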