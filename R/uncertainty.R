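#' First-order propagation of parameter uncertainty
#'
#' Propagates independent parameter uncertainties through a trait model by
#' the standard first-order (Gaussian) formula
#' `u^2(y) = sum_i (dm/dn_i)^2 u^2(n_i)`, with sensitivities obtained by
#' central finite differences. The resulting budget decomposes the
#' prediction variance parameter by parameter; the shares sum to the total
#' variance by construction.
#'
#' @param model A function taking a named list of inputs (spliced as
#'   arguments) and returning a single numeric value. Typically a closure
#'   around one of the trait models fixing the site environment.
#' @param inputs Named list of all arguments of `model`, at their central
#'   values.
#' @param uncertainties Named numeric vector of standard uncertainties for
#'   the subset of `inputs` treated as uncertain parameters (all >= 0).
#' @param rel_step Relative step of the central difference (default 1e-4
#'   of the parameter magnitude).
#' @return A tibble of class `"uncertainty_budget"` with one row per
#'   uncertain parameter: `parameter`, `value`, `uncertainty`,
#'   `sensitivity`, `contribution` (its variance share) and `share`
#'   (fraction of total variance). The central model value and total sd
#'   are in attributes `value` and `total_sd` and in [glance()].
#' @examples
#' budget <- propagate_uncertainty(
#'   function(x) 2 * x, inputs = list(x = 3), uncertainties = c(x = 0.5)
#' )
#' attr(budget, "total_sd")  # 1.0
#' @export
propagate_uncertainty <- function(model, inputs, uncertainties,
                                  rel_step = 1e-4) {
  if (is.null(names(uncertainties)) || any(!nzchar(names(uncertainties)))) {
    abort("`uncertainties` must be a named numeric vector.")
  }
  if (any(uncertainties < 0)) abort("`uncertainties` must be >= 0.")
  unknown <- setdiff(names(uncertainties), names(inputs))
  if (length(unknown)) {
    abort(paste0("Uncertain parameter(s) not in `inputs`: ",
                 paste(unknown, collapse = ", ")))
  }
  f <- function(args) do.call(model, args)
  central <- f(inputs)

  inputs <- purrr::map(inputs, unname)
  sens <- purrr::imap_dbl(as.list(uncertainties), function(u, par) {
    x <- inputs[[par]]
    h <- rel_step * max(abs(x), rel_step)
    up <- inputs; up[[par]] <- x + h
    dn <- inputs; dn[[par]] <- x - h
    s <- (f(up) - f(dn)) / (2 * h)
    if (!is.finite(s)) {
      abort(paste0("Non-finite sensitivity for parameter `", par, "`."))
    }
    s
  })
  contribution <- sens^2 * uncertainties^2
  total_var <- sum(contribution)
  out <- tibble(
    parameter = names(uncertainties),
    value = purrr::map_dbl(names(uncertainties), ~ inputs[[.x]]),
    uncertainty = unname(uncertainties),
    sensitivity = unname(sens),
    contribution = unname(contribution),
    share = if (total_var > 0) unname(contribution) / total_var else
      rep(NA_real_, length(contribution))
  )
  attr(out, "value") <- central
  attr(out, "total_sd") <- sqrt(total_var)
  class(out) <- c("uncertainty_budget", class(out))
  out
}

#' @export
glance.uncertainty_budget <- function(x, ...) {
  tibble(value = attr(x, "value"), total_sd = attr(x, "total_sd"),
         n_parameters = nrow(x))
}

#' Monte-Carlo propagation of parameter uncertainty
#'
#' Verification oracle for [propagate_uncertainty()]: draws each uncertain
#' parameter independently from a normal distribution centred on its input
#' value and summarises the spread of the model output. Deterministic under
#' a fixed seed. For linear models the empirical sd matches the first-order
#' result up to Monte-Carlo error; for strongly curved models the two
#' diverge, which is the point of running both.
#'
#' @inheritParams propagate_uncertainty
#' @param n_draws Number of draws (>= 100).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return A one-row tibble: `mean`, `sd`, `q025`, `q50`, `q975`,
#'   `n_draws`, `n_failed` (draws where the model signalled an error,
#'   excluded from the summaries).
#' @export
mc_propagate <- function(model, inputs, uncertainties, n_draws = 10000,
                         seed) {
  if (missing(seed)) abort("`seed` is required.")
  if (n_draws < 100) abort("`n_draws` must be >= 100.")
  if (any(uncertainties < 0)) abort("`uncertainties` must be >= 0.")
  f <- function(args) do.call(model, args)
  inputs <- purrr::map(inputs, unname)
  pars <- names(uncertainties)
  draws <- withr::with_seed(seed, {
    mat <- vapply(pars, function(par) {
      rnorm(n_draws, mean = inputs[[par]], sd = uncertainties[[par]])
    }, numeric(n_draws))
    vapply(seq_len(n_draws), function(i) {
      args <- inputs
      for (j in seq_along(pars)) args[[pars[j]]] <- unname(mat[i, j])
      tryCatch(f(args), error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- draws[is.finite(draws)]
  tibble(
    mean = mean(ok),
    sd = sd(ok),
    q025 = unname(quantile(ok, 0.025)),
    q50 = unname(quantile(ok, 0.5)),
    q975 = unname(quantile(ok, 0.975)),
    n_draws = n_draws,
    n_failed = n_draws - length(ok)
  )
}

#' Uncertainty budgets for the four trait predictions at a site
#'
#' Convenience wrapper running [propagate_uncertainty()] for chi, Vcmax25,
#' Ma and Narea at one site environment, using a configurable set of
#' parameter uncertainties.
#'
#' @param site A one-row site table (as in [predict_traits()]).
#' @param uncertainties A named list with elements `beta`, `c_cost`,
#'   `lma_coeffs` (named vector over the deciduous-LMA coefficients) and
#'   `narea_coeffs` (named vector over `ma`, `vcmax25`); any element can
#'   be omitted to skip that parameter.
#' @param constants A [leaf_constants()] list.
#' @param temperature_basis As in [predict_traits()].
#' @return A tibble with one row per trait: `site_id`, `trait`, `value`,
#'   `total_sd`, plus a list-column `budget` of per-parameter budgets.
#' @examples
#' site <- generate_sites(transect_scenario(seed = 1))[9, ]
#' site_uncertainty(site)
#' @export
site_uncertainty <- function(site,
                             uncertainties = default_uncertainties(),
                             constants = leaf_constants(),
                             temperature_basis = c(chi = "tdj",
                                                   vcmax25 = "tdj",
                                                   ma = "tg")) {
  cst <- as_constants(constants)
  site <- derive_bioclim(site, cst)
  if (nrow(site) != 1) abort("`site` must be a single-row table.")
  basis <- temperature_basis
  pred <- predict_traits(site, cst, basis)

  chi_model <- function(beta) {
    chi_optimal(site[[basis[["chi"]]]], site$d0, site$patm, site$ca,
                as_constants(modifyList(unclass(cst), list(beta = beta))))
  }
  vcmax_model <- function(beta, c_cost) {
    cc <- as_constants(modifyList(unclass(cst),
                                  list(beta = beta, c_cost = c_cost)))
    chi <- chi_optimal(site[[basis[["chi"]]]], site$d0, site$patm,
                       site$ca, cc)
    vcmax25_predicted(site[[basis[["vcmax25"]]]], site$r0, chi, site$ca,
                      site$patm, cc)
  }
  ma_model <- function(ln_r_lai, ln_f, tg, ln_alpha_p, intercept) {
    lma_deciduous(site$r_lai, site$f, site[[basis[["ma"]]]], site$alpha_p,
                  coeffs = c(ln_r_lai = ln_r_lai, ln_f = ln_f, tg = tg,
                             ln_alpha_p = ln_alpha_p,
                             intercept = intercept))
  }
  narea_model <- function(ma_coef, vcmax25_coef) {
    narea_simple(pred$ma, pred$vcmax25,
                 coeffs = c(ma = ma_coef, vcmax25 = vcmax25_coef))
  }

  budgets <- list()
  if (!is.null(uncertainties$beta)) {
    budgets$chi <- propagate_uncertainty(
      chi_model, list(beta = cst$beta), c(beta = uncertainties$beta))
    vc_unc <- c(beta = uncertainties$beta)
    if (!is.null(uncertainties$c_cost)) {
      vc_unc <- c(vc_unc, c_cost = uncertainties$c_cost)
    }
    budgets$vcmax25 <- propagate_uncertainty(
      vcmax_model, list(beta = cst$beta, c_cost = cst$c_cost), vc_unc)
  }
  if (!is.null(uncertainties$lma_coeffs)) {
    u <- uncertainties$lma_coeffs
    budgets$ma <- propagate_uncertainty(
      ma_model, as.list(cst$lma_coeffs), u)
  }
  if (!is.null(uncertainties$narea_coeffs)) {
    u <- uncertainties$narea_coeffs
    names(u) <- paste0(names(u), "_coef")
    budgets$narea <- propagate_uncertainty(
      narea_model,
      list(ma_coef = cst$narea_coeffs[["ma"]],
           vcmax25_coef = cst$narea_coeffs[["vcmax25"]]),
      u)
  }
  purrr::imap_dfr(budgets, function(b, trait) {
    tibble(site_id = site$site_id, trait = trait,
           value = attr(b, "value"), total_sd = attr(b, "total_sd"),
           budget = list(b))
  })
}

#' Default parameter standard uncertainties
#'
#' Plausible standard uncertainties for the uncertain parameters of the
#' trait models: the carboxylation/transpiration cost ratio beta, the
#' electron-transport cost constant c, and the regression coefficients of
#' the calibrated LMA and Narea models. These are package defaults for
#' exploratory budgets; for a faithful replication of a particular
#' calibration they should be replaced by the standard errors from
#' [fit_lma_coefficients()] and [fit_narea_coefficients()].
#'
#' @return A named list as expected by [site_uncertainty()].
#' @export
default_uncertainties <- function() {
  list(
    beta = 30,
    c_cost = 0.04,
    lma_coeffs = c(ln_r_lai = 0.08, ln_f = 0.10, tg = 0.01,
                   ln_alpha_p = 0.10, intercept = 0.15),
    narea_coeffs = c(ma = 0.002, vcmax25 = 0.0005)
  )
}
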